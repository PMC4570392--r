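#' Scenario for a synthetic row-crop field
#'
#' Describes a sunflower-like field: parallel crop rows at a given
#' orientation and spacing, a patchy broadleaved weed infestation confined to
#' the inter-row space, bare-soil background, square ground-truth sampling
#' frames in four infestation categories, and surveyed control-point markers.
#' All stochastic choices downstream are driven by `seed` through a single
#' pseudo-random stream consumed in documented order (row phase, crop
#' presence pattern, control points, frames, frame weed discs, background
#' weed discs).
#'
#' @param field_size Field width and height in m (default `c(24, 24)`).
#' @param row_orientation Crop-row direction in degrees from the world
#'   x-axis, in \[0, 180).
#' @param row_spacing Distance between row centrelines in m (default 0.7,
#'   typical for sunflower).
#' @param row_plant_width Width of the planted band around each centreline
#'   in m (default 0.2).
#' @param crop_coverage_along_row Fraction of each row length actually
#'   carrying plants (default 0.85); gaps emulate emergence failures.
#' @param weed_patch_count Number of cluster centres around which the
#'   background infestation aggregates (default 12).
#' @param weed_patch_radius Radius in m of individual background weed discs
#'   (default 0.2).
#' @param weed_cover_target Target fraction of the field covered by weeds
#'   (default 0.08). Must be positive: a weed-free field cannot satisfy the
#'   four-category frame design.
#' @param category_targets Per-category target frame weed cover in percent
#'   (length 4, default `c(0, 4.5, 11.25, 21)`). Categories are banded as
#'   0 = exactly 0, 1 in (0, 7.5], 2 in (7.5, 17.5], 3 above 17.5.
#' @param n_frames_per_category Frames per category (default 8, giving the
#'   32-frame design).
#' @param frame_side Side of the square sampling frames in m (default 1).
#' @param n_control_points Number of control-point markers (default 20,
#'   the minimum for the ASPRS test).
#' @param control_min_sep Minimum pairwise marker separation in m (default 5).
#' @param marker_size Side of the rendered square markers in m (default 0.3).
#' @param spectra List with elements `soil`, `crop`, `weed`, each a named
#'   vector of per-band mean digital numbers over `R`, `G`, `B`, `NIR`.
#' @param noise_sd Per-pixel, per-band Gaussian DN noise sd (default 8).
#' @param gsd Base ground sample distance (cm/pixel) of the stored
#'   ground-truth label raster (default 1.6).
#' @param seed Integer seed.
#' @return An object of class `field_scenario`.
#' @export
field_scenario <- function(field_size = c(24, 24),
                           row_orientation = 0,
                           row_spacing = 0.7,
                           row_plant_width = 0.2,
                           crop_coverage_along_row = 0.85,
                           weed_patch_count = 12,
                           weed_patch_radius = 0.2,
                           weed_cover_target = 0.08,
                           category_targets = c(0, 4.5, 11.25, 21),
                           n_frames_per_category = 8,
                           frame_side = 1,
                           n_control_points = 20,
                           control_min_sep = 5,
                           marker_size = 0.3,
                           spectra = list(
                             soil = c(R = 161, G = 122, B = 87, NIR = 120),
                             crop = c(R = 60, G = 110, B = 50, NIR = 180),
                             weed = c(R = 70, G = 120, B = 55, NIR = 170)),
                           noise_sd = 8,
                           gsd = 1.6,
                           seed = 42) {
  sc <- list(field_size = as.numeric(field_size),
             row_orientation = row_orientation %% 180,
             row_spacing = row_spacing,
             row_plant_width = row_plant_width,
             crop_coverage_along_row = crop_coverage_along_row,
             weed_patch_count = weed_patch_count,
             weed_patch_radius = weed_patch_radius,
             weed_cover_target = weed_cover_target,
             category_targets = as.numeric(category_targets),
             n_frames_per_category = n_frames_per_category,
             frame_side = frame_side,
             n_control_points = n_control_points,
             control_min_sep = control_min_sep,
             marker_size = marker_size,
             spectra = spectra,
             noise_sd = noise_sd,
             gsd = gsd,
             seed = as.integer(seed))
  validate_scenario(sc)
  structure(sc, class = "field_scenario")
}

validate_scenario <- function(sc) {
  if (length(sc$field_size) != 2 || any(sc$field_size <= 0)) {
    stop("field_size must be two positive lengths (m)", call. = FALSE)
  }
  if (sc$row_spacing <= sc$row_plant_width) {
    stop("row_spacing must exceed row_plant_width", call. = FALSE)
  }
  fr <- c(sc$crop_coverage_along_row, sc$weed_cover_target)
  if (any(fr < 0) || any(fr > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  for (cls in c("soil", "crop", "weed")) {
    v <- sc$spectra[[cls]]
    if (is.null(v) || is.null(names(v)) ||
        !all(c("R", "G", "B", "NIR") %in% names(v)) ||
        any(v < 0) || any(v > 255)) {
      stop(sprintf("spectra$%s must name bands R,G,B,NIR with means in [0, 255]", cls),
           call. = FALSE)
    }
  }
  if (length(sc$category_targets) != 4 || sc$category_targets[1] != 0 ||
      any(diff(sc$category_targets) <= 0)) {
    stop("category_targets must be 4 increasing percentages starting at 0",
         call. = FALSE)
  }
  invisible(sc)
}

# evaluate code under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Generate the ground truth of a synthetic field
#'
#' Lays out crop-row geometry, the along-row planting pattern, control
#' points, sampling frames and weed patches for a [field_scenario()], and
#' rasterises the soil/crop/weed labels at the scenario's base GSD. Frames
#' receive deliberately sized circular weed patches on the inter-row
#' centrelines so that each infestation category's frames achieve their
#' target cover; category-0 frames are kept strictly weed-free by an
#' exclusion buffer. The remaining infestation is placed as clustered
#' non-overlapping discs between the rows.
#'
#' @param scenario A [field_scenario()].
#' @return An object of class `ground_truth` with elements `rows` (angle,
#'   spacing, phase, centreline offsets), `slots` (planting pattern),
#'   `discs` (weed patch table), `frames`, `control_points`, `labels`
#'   (integer raster, 0 soil / 1 crop / 2 weed, at `scenario$gsd`),
#'   `gsd`, `field_size` and `scenario`.
#' @export
generate_scene <- function(scenario) {
  stopifnot(inherits(scenario, "field_scenario"))
  sc <- scenario
  if (sc$weed_cover_target <= 0) {
    stop(paste("configuration error: weed_cover_target must be positive;",
               "a weed-free field cannot realise the four-category frame design"),
         call. = FALSE)
  }
  with_seed(sc$seed, {
    geom <- scene_geometry(sc)
    geom$control_points <- place_control_points(sc)
    geom$frames <- place_frames(sc, geom)
    frame_discs <- place_all_frame_discs(sc, geom)
    bg_discs <- place_background_discs(sc, geom, frame_discs)
    geom$discs <- rbind(frame_discs, bg_discs)
    truth <- structure(c(geom,
                         list(gsd = sc$gsd, field_size = sc$field_size,
                              scenario = sc)),
                       class = "ground_truth")
    truth$labels <- rasterize_labels(truth, sc$gsd)
    truth$frames$true_cover <- vapply(seq_len(nrow(truth$frames)), function(i) {
      frame_cover_from_labels(truth$labels, sc$gsd, sc$field_size,
                              truth$frames[i, ])
    }, 0)
    truth
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> field %.3g x %.3g m, %d rows at %.3g deg / %.3g m spacing\n",
              x$field_size[1], x$field_size[2], length(x$rows$offsets),
              x$rows$orientation, x$rows$spacing))
  cat(sprintf("  %d weed discs, %d frames, %d control points, labels %d x %d px at %.3g cm\n",
              nrow(x$discs), nrow(x$frames), nrow(x$control_points),
              nrow(x$labels), ncol(x$labels), x$gsd))
  invisible(x)
}

# --- geometry ---------------------------------------------------------------

# row/along unit vectors: u along rows, v across rows
row_uv <- function(theta_deg) {
  th <- theta_deg * pi / 180
  list(d = c(cos(th), sin(th)), n = c(-sin(th), cos(th)))
}

scene_geometry <- function(sc) {
  W <- sc$field_size[1]; H <- sc$field_size[2]
  uv <- row_uv(sc$row_orientation)
  corners <- rbind(c(0, 0), c(W, 0), c(0, H), c(W, H))
  v_rng <- range(corners %*% uv$n)
  u_rng <- range(corners %*% uv$d)
  phase <- runif(1, 0, sc$row_spacing)            # RNG draw 1
  kmin <- ceiling((v_rng[1] - phase) / sc$row_spacing)
  kmax <- floor((v_rng[2] - phase) / sc$row_spacing)
  offsets <- phase + (kmin:kmax) * sc$row_spacing
  slot_len <- 0.25                                # plant slot along the row, m
  n_slots <- max(1L, ceiling((u_rng[2] - u_rng[1]) / slot_len))
  on <- matrix(runif(length(offsets) * n_slots) < sc$crop_coverage_along_row,
               nrow = length(offsets))            # RNG draws 2
  list(rows = list(orientation = sc$row_orientation, spacing = sc$row_spacing,
                   phase = phase, offsets = offsets, kmin = kmin,
                   halfwidth = sc$row_plant_width / 2),
       slots = list(u0 = u_rng[1], slot_len = slot_len, on = on),
       u_rng = u_rng, v_rng = v_rng)
}

place_control_points <- function(sc) {
  W <- sc$field_size[1]; H <- sc$field_size[2]
  n <- sc$n_control_points
  sep <- sc$control_min_sep
  jit <- 0.1
  step <- sep + 3 * jit
  margin <- sc$marker_size / 2 + 0.8
  nx <- floor((W - 2 * margin) / step) + 1
  ny <- ceiling(n / nx)
  if (nx < 1 || (ny - 1) * step > H - 2 * margin) {
    stop("configuration error: field too small to host the control-point design",
         call. = FALSE)
  }
  gx <- margin + (seq_len(nx) - 1) * step
  gy <- margin + (seq_len(ny) - 1) * step
  pts <- expand.grid(x = gx, y = gy)[seq_len(n), ]
  pts$x <- pts$x + runif(n, -jit, jit)            # RNG draws 3
  pts$y <- pts$y + runif(n, -jit, jit)
  data.frame(id = seq_len(n), x = pts$x, y = pts$y, row.names = NULL)
}

place_frames <- function(sc, geom) {
  W <- sc$field_size[1]; H <- sc$field_size[2]
  side <- sc$frame_side
  n <- 4 * sc$n_frames_per_category
  gap <- 0.4
  if (n * (side + gap)^2 > 0.5 * W * H) {
    stop("configuration error: field too small for the disjoint sampling-frame design",
         call. = FALSE)
  }
  uv <- row_uv(sc$row_orientation)
  cp <- geom$control_points
  placed <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(placed) < n) {
    tries <- tries + 1L
    if (tries > 20000L * n) {
      stop("configuration error: could not place the disjoint sampling frames",
           call. = FALSE)
    }
    x0 <- runif(1, 0.5, W - side - 0.5)           # RNG draws 4
    y0 <- runif(1, 0.5, H - side - 0.5)
    ctr <- c(x0 + side / 2, y0 + side / 2)
    # an inter-row centreline must pass close to the frame centre so that
    # target weed discs of any category fit inside the frame
    v_ctr <- sum(ctr * uv$n)
    dmid <- v_ctr - geom$rows$phase - sc$row_spacing / 2
    mid_d <- abs(dmid - round(dmid / sc$row_spacing) * sc$row_spacing)
    if (mid_d > 0.1) next
    if (nrow(placed) > 0 &&
        any(abs(placed[, 1] - x0) < side + gap &
            abs(placed[, 2] - y0) < side + gap)) next
    # keep markers out of frames (with a buffer)
    buf <- sc$marker_size / 2 + 0.3
    if (any(cp$x > x0 - buf & cp$x < x0 + side + buf &
            cp$y > y0 - buf & cp$y < y0 + side + buf)) next
    placed <- rbind(placed, c(x0, y0))
  }
  cat_assign <- sample(rep(0:3, each = sc$n_frames_per_category))  # RNG draw 5
  data.frame(id = seq_len(n), x = placed[, 1], y = placed[, 2],
             side = side, category = cat_assign,
             true_cover = NA_real_, row.names = NULL)
}

# intersection of line {p : <p, n> = v0} with an axis-aligned box, as the
# u-interval (coordinates along the row direction); NULL if empty
line_box_chord <- function(v0, box, uv) {
  lo <- -Inf; hi <- Inf
  for (axis in 1:2) {
    dir <- uv$d[axis]; off <- v0 * uv$n[axis]
    b0 <- box[axis]; b1 <- box[axis + 2]
    if (abs(dir) < 1e-12) {
      if (off < b0 - 1e-9 || off > b1 + 1e-9) return(NULL)
    } else {
      t0 <- (b0 - off) / dir; t1 <- (b1 - off) / dir
      lo <- max(lo, min(t0, t1)); hi <- min(hi, max(t0, t1))
    }
  }
  if (hi <= lo) return(NULL)
  c(lo, hi)
}

# place n equal discs of radius r on inter-row centreline chords inside a
# frame; returns x,y matrix or NULL if the layout does not fit
frame_disc_layout <- function(frame, sc, geom, n, r) {
  uv <- row_uv(sc$row_orientation)
  m <- r + 0.02
  box <- c(frame$x + m, frame$y + m,
           frame$x + frame$side - m, frame$y + frame$side - m)
  if (box[3] <= box[1] || box[4] <= box[2]) return(NULL)
  mids <- geom$rows$offsets + sc$row_spacing / 2
  v_box <- range(rbind(c(box[1], box[2]), c(box[3], box[2]),
                       c(box[1], box[4]), c(box[3], box[4])) %*% uv$n)
  mids <- mids[mids > v_box[1] - 1e-9 & mids < v_box[2] + 1e-9]
  chords <- list()
  for (v0 in mids) {
    ch <- line_box_chord(v0, box, uv)
    if (!is.null(ch)) chords[[length(chords) + 1]] <- list(v = v0, u = ch)
  }
  if (!length(chords)) return(NULL)
  lens <- vapply(chords, function(ch) diff(ch$u), 0)
  chords <- chords[order(lens, decreasing = TRUE)]
  sep <- 2 * r + 0.03
  pts <- matrix(numeric(0), ncol = 2)
  for (ch in chords) {
    if (nrow(pts) >= n) break
    L <- diff(ch$u)
    fit <- min(n - nrow(pts), 1L + floor(L / sep))
    ctr <- mean(ch$u)
    us <- ctr + (seq_len(fit) - (fit + 1) / 2) * sep
    pts <- rbind(pts, cbind(us * uv$d[1] + ch$v * uv$n[1],
                            us * uv$d[2] + ch$v * uv$n[2]))
  }
  if (nrow(pts) < n) return(NULL)
  pts
}

place_all_frame_discs <- function(sc, geom) {
  free_half <- (sc$row_spacing - sc$row_plant_width) / 2
  out <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0),
                    frame_id = integer(0))
  for (i in seq_len(nrow(geom$frames))) {
    fr <- geom$frames[i, ]
    tgt <- sc$category_targets[fr$category + 1]
    if (tgt <= 0) next
    area <- tgt / 100 * fr$side^2
    placed <- NULL
    for (n in 1:6) {
      r <- sqrt(area / (n * pi))
      if (r > free_half - 0.03) next
      placed <- frame_disc_layout(fr, sc, geom, n, r)
      if (!is.null(placed)) {
        out <- rbind(out, data.frame(x = placed[, 1], y = placed[, 2],
                                     r = r, frame_id = fr$id))
        break
      }
    }
    if (is.null(placed)) {
      stop(sprintf("configuration error: cannot fit a %.3g%% weed patch into frame %d",
                   tgt, fr$id), call. = FALSE)
    }
  }
  out
}

place_background_discs <- function(sc, geom, frame_discs) {
  W <- sc$field_size[1]; H <- sc$field_size[2]
  r <- sc$weed_patch_radius
  free_half <- (sc$row_spacing - sc$row_plant_width) / 2
  if (r > free_half - 0.02) {
    stop("weed_patch_radius too large for the inter-row space", call. = FALSE)
  }
  target_area <- sc$weed_cover_target * W * H -
    sum(pi * frame_discs$r^2)
  out <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0),
                    frame_id = integer(0))
  if (target_area <= 0) return(out)
  centres <- cbind(runif(sc$weed_patch_count, 1, W - 1),  # RNG draws 6
                   runif(sc$weed_patch_count, 1, H - 1))
  uv <- row_uv(sc$row_orientation)
  fr <- geom$frames
  cp <- geom$control_points
  all_x <- frame_discs$x; all_y <- frame_discs$y; all_r <- frame_discs$r
  acc_area <- 0
  sd_cluster <- 2
  tries <- 0L; fails <- 0L
  jit_v <- max(0, free_half - r - 0.02)
  while (acc_area < target_area && tries < 300000L) {
    tries <- tries + 1L
    ctr <- centres[sample.int(nrow(centres), 1), ]
    p <- ctr + rnorm(2, sd = sd_cluster)
    # snap across-row coordinate to the nearest inter-row centreline
    v <- sum(p * uv$n)
    k <- round((v - geom$rows$phase - sc$row_spacing / 2) / sc$row_spacing)
    v_mid <- geom$rows$phase + sc$row_spacing / 2 + k * sc$row_spacing +
      runif(1, -jit_v, jit_v)
    u <- sum(p * uv$d)
    p <- u * uv$d + v_mid * uv$n
    ok <- p[1] > r + 0.05 && p[1] < W - r - 0.05 &&
      p[2] > r + 0.05 && p[2] < H - r - 0.05
    if (ok && nrow(fr) > 0) {
      pad <- r + 0.1
      ok <- !any(p[1] > fr$x - pad & p[1] < fr$x + fr$side + pad &
                   p[2] > fr$y - pad & p[2] < fr$y + fr$side + pad)
    }
    if (ok && nrow(cp) > 0) {
      ok <- all((cp$x - p[1])^2 + (cp$y - p[2])^2 >
                  (r + sc$marker_size / 2 + 0.2)^2)
    }
    if (ok && length(all_x) > 0) {
      ok <- all((all_x - p[1])^2 + (all_y - p[2])^2 >
                  (all_r + r + 0.02)^2)
    }
    if (ok) {
      out <- rbind(out, data.frame(x = p[1], y = p[2], r = r,
                                   frame_id = NA_integer_))
      all_x <- c(all_x, p[1]); all_y <- c(all_y, p[2]); all_r <- c(all_r, r)
      acc_area <- acc_area + pi * r^2
      fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails %% 4000L == 0L) sd_cluster <- sd_cluster * 1.5
    }
  }
  if (acc_area < 0.8 * target_area) {
    warning(sprintf("background weed placement reached only %.2f of %.2f m2",
                    acc_area, target_area))
  }
  out
}

# --- rasterisation ----------------------------------------------------------

label_raster_dim <- function(field_size, gsd) {
  g <- gsd / 100
  c(nr = max(1L, floor(field_size[2] / g + 1e-9)),
    nc = max(1L, floor(field_size[1] / g + 1e-9)))
}

#' Rasterise ground-truth class labels at a given ground sample distance
#'
#' Labels every pixel centre from the continuous scene geometry: 1 (crop)
#' inside the planted band of a row where the planting slot is occupied,
#' 2 (weed) inside a weed disc (crop takes precedence), 0 (soil) otherwise.
#'
#' @param truth A [generate_scene()] result.
#' @param gsd Target GSD in cm/pixel.
#' @return Integer matrix of class labels.
#' @export
rasterize_labels <- function(truth, gsd) {
  sc <- truth$scenario
  d <- label_raster_dim(truth$field_size, gsd)
  g <- gsd / 100
  xc <- (seq_len(d["nc"]) - 0.5) * g
  yc <- truth$field_size[2] - (seq_len(d["nr"]) - 0.5) * g
  uv <- row_uv(truth$rows$orientation)
  u <- outer(yc * uv$d[2], xc * uv$d[1], "+")
  v <- outer(yc * uv$n[2], xc * uv$n[1], "+")
  labels <- matrix(0L, d["nr"], d["nc"])
  # crop rows
  k <- round((v - truth$rows$phase) / truth$rows$spacing)
  dv <- v - truth$rows$phase - k * truth$rows$spacing
  cand <- which(abs(dv) <= truth$rows$halfwidth)
  if (length(cand)) {
    ridx <- pmin(pmax(k[cand] - truth$rows$kmin + 1L, 1L),
                 nrow(truth$slots$on))
    sidx <- pmin(pmax(floor((u[cand] - truth$slots$u0) /
                              truth$slots$slot_len) + 1L, 1L),
                 ncol(truth$slots$on))
    on <- truth$slots$on[cbind(ridx, sidx)]
    labels[cand[on]] <- 1L
  }
  # weed discs (crop precedence; discs are laid out clear of the rows)
  H <- truth$field_size[2]
  for (i in seq_len(nrow(truth$discs))) {
    dc <- truth$discs[i, ]
    c0 <- max(1L, floor((dc$x - dc$r) / g))
    c1 <- min(d[["nc"]], ceiling((dc$x + dc$r) / g) + 1L)
    r0 <- max(1L, floor((H - dc$y - dc$r) / g))
    r1 <- min(d[["nr"]], ceiling((H - dc$y + dc$r) / g) + 1L)
    if (c0 > c1 || r0 > r1) next
    lx <- (c0:c1 - 0.5) * g - dc$x
    ly <- H - (r0:r1 - 0.5) * g - dc$y
    inside <- outer(ly^2, lx^2, "+") <= dc$r^2
    sub <- labels[r0:r1, c0:c1, drop = FALSE]
    sub[inside & sub == 0L] <- 2L
    labels[r0:r1, c0:c1] <- sub
  }
  labels
}

# percent weed cover of one frame from a label raster (pixel-centre rule)
frame_cover_from_labels <- function(labels, gsd, field_size, frame) {
  g <- gsd / 100
  H <- field_size[2]
  # pixel (r, c) centre: x = (c - 0.5) g, y = H - (r - 0.5) g
  c0 <- ceiling(frame$x / g + 0.5)
  c1 <- floor((frame$x + frame$side) / g + 0.5)
  r0 <- ceiling((H - frame$y - frame$side) / g + 0.5)
  r1 <- floor((H - frame$y) / g + 0.5)
  c0 <- max(1L, c0); r0 <- max(1L, r0)
  c1 <- min(ncol(labels), c1); r1 <- min(nrow(labels), r1)
  if (c0 > c1 || r0 > r1) stop("frame lies outside the raster", call. = FALSE)
  sub <- labels[r0:r1, c0:c1]
  100 * mean(sub == 2L)
}

# --- rendering --------------------------------------------------------------

#' Render a synthetic ortho-image from ground truth
#'
#' Draws every pixel's digital number from the per-class, per-band normal
#' model of the scenario, quantised and clamped to 8 bits, and stamps the
#' control-point markers as saturated (DN 255) squares. Rendering is
#' deterministic given the scenario seed, the GSD and the band set.
#'
#' @param truth A [generate_scene()] result.
#' @param scenario The [field_scenario()] that produced `truth`.
#' @param gsd Rendering GSD in cm/pixel.
#' @param band_set `"RGB"` (bands R, G, B) or `"RNIR"` (bands R, NIR).
#' @return An [ortho_image()] with origin at the field's upper-left corner.
#' @export
render_image <- function(truth, scenario, gsd,
                         band_set = c("RGB", "RNIR")) {
  stopifnot(inherits(truth, "ground_truth"))
  band_set <- match.arg(band_set)
  bands <- switch(band_set, RGB = c("R", "G", "B"), RNIR = c("R", "NIR"))
  d <- label_raster_dim(truth$field_size, gsd)
  if (d["nr"] < 50 || d["nc"] < 50) {
    stop("gsd too coarse for this field: rendered image must be at least 50 x 50 px",
         call. = FALSE)
  }
  labels <- if (abs(gsd - truth$gsd) < 1e-9) truth$labels else
    rasterize_labels(truth, gsd)
  rseed <- as.integer((as.numeric(scenario$seed) * 1009 +
                         round(gsd * 1000) %% 100000 +
                         length(bands) * 97) %% 2147483647)
  mu <- rbind(scenario$spectra$soil, scenario$spectra$crop,
              scenario$spectra$weed)
  out <- with_seed(rseed, {
    lapply(bands, function(b) {
      m <- mu[labels + 1L, b]
      dn <- round(m + rnorm(length(m), sd = scenario$noise_sd))
      matrix(as.integer(pmin(255, pmax(0, dn))), nrow(labels), ncol(labels))
    })
  })
  names(out) <- bands
  img <- ortho_image(out, gsd = gsd, origin = c(0, truth$field_size[2]),
                     meta = list(seed = scenario$seed, band_set = band_set,
                                 synthetic = TRUE))
  stamp_markers(img, truth$control_points, scenario$marker_size)
}

# overwrite marker footprints with saturated DN in every band
stamp_markers <- function(image, control_points, marker_size) {
  g <- image$gsd / 100
  H <- image$origin[2]
  d <- dim(image)
  half <- marker_size / 2
  for (i in seq_len(nrow(control_points))) {
    x <- control_points$x[i]; y <- control_points$y[i]
    c0 <- max(1L, ceiling((x - half) / g + 0.5))
    c1 <- min(d[2], floor((x + half) / g + 0.5))
    r0 <- max(1L, ceiling((H - y - half) / g + 0.5))
    r1 <- min(d[1], floor((H - y + half) / g + 0.5))
    if (c0 > c1 || r0 > r1) next
    for (b in band_names(image)) image$bands[[b]][r0:r1, c0:c1] <- 255L
  }
  image
}

#' Rasterise the true row-centreline mask
#'
#' Pixels whose centre lies within half a pixel of a true crop-row
#' centreline; the reference set for scoring detected row bands.
#'
#' @param truth A [generate_scene()] result.
#' @param gsd GSD in cm/pixel.
#' @return Logical matrix.
#' @export
row_centerline_mask <- function(truth, gsd) {
  d <- label_raster_dim(truth$field_size, gsd)
  g <- gsd / 100
  xc <- (seq_len(d["nc"]) - 0.5) * g
  yc <- truth$field_size[2] - (seq_len(d["nr"]) - 0.5) * g
  uv <- row_uv(truth$rows$orientation)
  v <- outer(yc * uv$n[2], xc * uv$n[1], "+")
  dv <- v - truth$rows$phase
  abs(dv - round(dv / truth$rows$spacing) * truth$rows$spacing) <= g / 2
}
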