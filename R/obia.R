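#' Vegetation index raster
#'
#' For visible imagery the excess-green index ExG = 2g - r - b is computed on
#' per-pixel chromatic coordinates (each band divided by R+G+B); for imagery
#' with a near-infrared band, NDVI = (NIR - R) / (NIR + R). Pixels whose
#' denominator is zero get index 0 by convention.
#'
#' @param image An [ortho_image()] with bands R,G,B or R,NIR.
#' @param index `"auto"` (NDVI if a NIR band exists, else ExG), `"exg"` or
#'   `"ndvi"`.
#' @return Numeric matrix of index values (NDVI lies in \[-1, 1\]).
#' @export
vegetation_index <- function(image, index = c("auto", "exg", "ndvi")) {
  stopifnot(inherits(image, "ortho_image"))
  index <- match.arg(index)
  bn <- band_names(image)
  if (index == "auto") index <- if ("NIR" %in% bn) "ndvi" else "exg"
  if (index == "ndvi") {
    if (!all(c("R", "NIR") %in% bn)) {
      stop("NDVI requires bands R and NIR", call. = FALSE)
    }
    nir <- image$bands$NIR; r <- image$bands$R
    s <- nir + r
    out <- ifelse(s == 0, 0, (nir - r) / s)
  } else {
    if (!all(c("R", "G", "B") %in% bn)) {
      stop("ExG requires bands R, G and B", call. = FALSE)
    }
    s <- image$bands$R + image$bands$G + image$bands$B
    s0 <- ifelse(s == 0, 1, s)
    out <- ifelse(s == 0, 0,
                  (2 * image$bands$G - image$bands$R - image$bands$B) / s0)
  }
  matrix(out, nrow(image$bands[[1]]), ncol(image$bands[[1]]))
}

#' Segment vegetation objects from an index raster
#'
#' Thresholds the index automatically (Otsu on a 256-level histogram) and
#' extracts 8-connected components as vegetation objects. If the automatic
#' threshold is degenerate (nearly empty or nearly full mask, as happens on
#' unimodal histograms), a fixed fallback threshold is used with a warning
#' (ExG 0.05 / NDVI 0.2).
#'
#' @param index Numeric index raster from [vegetation_index()].
#' @param gsd GSD in cm/pixel (for object areas in m^2).
#' @param min_object_area Minimum object size in pixels (default 4); smaller
#'   components are returned to the soil background.
#' @param index_type `"exg"` or `"ndvi"`, controls the fallback threshold.
#' @param origin World coordinates (m) of the raster's upper-left corner.
#' @return List with `mask` (logical), `labels` (integer component raster),
#'   `objects` (data frame: `id`, `area_px`, `area_m2`, `centroid_x`,
#'   `centroid_y`, `mean_index`), `threshold`, `threshold_method`.
#' @export
segment_vegetation <- function(index, gsd, min_object_area = 4,
                               index_type = c("ndvi", "exg"),
                               origin = c(0, nrow(index) * gsd / 100)) {
  index_type <- match.arg(index_type)
  if (anyNA(index) || any(!is.finite(index))) {
    stop("index raster must be finite", call. = FALSE)
  }
  rng <- range(index)
  thr <- NA_real_
  method <- "otsu"
  if (rng[2] > rng[1]) {
    scaled <- (index - rng[1]) / (rng[2] - rng[1])
    t01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = 256)
    thr <- rng[1] + t01 * (rng[2] - rng[1])
  }
  frac <- if (is.na(thr)) NA_real_ else mean(index > thr)
  if (is.na(thr) || frac < 0.001 || frac > 0.95) {
    thr <- if (index_type == "ndvi") 0.2 else 0.05
    method <- "fixed-fallback"
    warning(sprintf(
      "degenerate index histogram: falling back to fixed %s threshold %.2f",
      toupper(index_type), thr))
  }
  mask <- index > thr
  lab <- label_components(mask)
  objects <- summarise_objects(lab, index, gsd, origin)
  keep <- objects$area_px >= min_object_area
  if (any(!keep)) {
    drop_ids <- objects$id[!keep]
    lab[lab %in% drop_ids] <- 0L
    mask <- lab > 0L
    objects <- objects[keep, , drop = FALSE]
  }
  list(mask = mask, labels = lab, objects = objects,
       threshold = thr, threshold_method = method)
}

# 8-connected component labelling: EBImage's 4-connected pass plus a
# union-find merge of diagonally adjacent labels
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  storage.mode(lab) <- "integer"
  nlab <- max(lab)
  if (nlab < 2) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
  pr <- rbind(cbind(as.vector(a1), as.vector(b1)),
              cbind(as.vector(a2), as.vector(b2)))
  pr <- pr[pr[, 1] > 0 & pr[, 2] > 0 & pr[, 1] != pr[, 2], , drop = FALSE]
  if (nrow(pr) == 0) return(lab)
  pr <- unique(pr)
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pr))) {
    ra <- find(pr[k, 1]); rb <- find(pr[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), find, 0L)
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[out > 0L] <- dense[out[out > 0L]]
  out
}

summarise_objects <- function(lab, index, gsd, origin) {
  idx <- which(lab > 0L)
  if (!length(idx)) {
    return(data.frame(id = integer(0), area_px = integer(0),
                      area_m2 = numeric(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), mean_index = numeric(0)))
  }
  nr <- nrow(lab)
  l <- lab[idx]
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  g <- gsd / 100
  agg <- rowsum(cbind(1, rows, cols, index[idx]), l)
  ids <- as.integer(rownames(agg))
  n <- agg[, 1]
  data.frame(id = ids,
             area_px = as.integer(n),
             area_m2 = n * g^2,
             centroid_x = origin[1] + (agg[, 3] / n - 0.5) * g,
             centroid_y = origin[2] - (agg[, 2] / n - 0.5) * g,
             mean_index = agg[, 4] / n,
             row.names = NULL)
}

#' Detect the crop-row structure from a vegetation mask
#'
#' The row orientation is the direction maximising the variance of the
#' across-row projection profile (vegetation-pixel counts binned at one
#' pixel width), swept over 0-180 degrees at an effective resolution of
#' 0.25 degrees (coarse 1-degree sweep on a pixel subsample, then local
#' 0.25-degree refinement on the full mask). The row spacing is the first
#' dominant peak of the profile's autocorrelation, refined by parabolic
#' interpolation, and the row phase is the centroid of the folded across-row
#' coordinate near its modal bin.
#'
#' @param mask Logical vegetation mask.
#' @param gsd GSD in cm/pixel.
#' @param origin World coordinates (m) of the raster's upper-left corner.
#' @param row_halfwidth Half-width in m of the crop-row band used for
#'   classification; default `max(0.15, 2 * gsd / 100)`.
#' @param max_spacing Largest row spacing considered, in m (default 3).
#' @return An object of class `row_model`: `orientation` (deg), `spacing`
#'   (m), `phase` (m), `offsets` (row centreline positions, m),
#'   `row_halfwidth` (m) and the autocorrelation `peak` diagnostics.
#'   Errors with "row detection failed" when the profile shows no periodic
#'   structure (autocorrelation peak below twice its baseline).
#' @export
detect_crop_rows <- function(mask, gsd, origin = c(0, nrow(mask) * gsd / 100),
                             row_halfwidth = NULL, max_spacing = 3) {
  if (!any(mask)) stop("vegetation mask is empty", call. = FALSE)
  g <- gsd / 100
  nr <- nrow(mask)
  idx <- which(mask)
  x <- origin[1] + (((idx - 1L) %/% nr) + 0.5) * g
  y <- origin[2] - (((idx - 1L) %% nr) + 0.5) * g
  sub <- function(n_max) {
    if (length(x) <= n_max) seq_along(x)
    else seq(1L, length(x), length.out = n_max)
  }
  profile_var <- function(theta_deg, xi, yi, bin) {
    th <- theta_deg * pi / 180
    v <- -xi * sin(th) + yi * cos(th)
    stats::var(tabulate(floor((v - min(v)) / bin) + 1L))
  }
  i1 <- sub(40000L)
  coarse <- seq(0, 179, by = 1)
  s1 <- vapply(coarse, profile_var, 0, xi = x[i1], yi = y[i1], bin = g)
  best3 <- coarse[order(s1, decreasing = TRUE)[1:3]]
  fine <- sort(unique(round(as.vector(outer(best3, seq(-1.5, 1.5, by = 0.25),
                                            "+")) %% 180, 4)))
  i2 <- sub(200000L)
  s2 <- vapply(fine, profile_var, 0, xi = x[i2], yi = y[i2], bin = g)
  theta <- fine[which.max(s2)]  # ties: which.max takes the first = smallest
  th <- theta * pi / 180
  v <- -x * sin(th) + y * cos(th)
  # support-normalised profile: raw counts carry the geometric envelope of
  # the rotated raster footprint, which would fake long-range correlation
  nc <- ncol(mask)
  a_col <- -(origin[1] + (seq_len(nc) - 0.5) * g) * sin(th)
  b_row <- (origin[2] - (seq_len(nr) - 0.5) * g) * cos(th)
  v_all <- outer(b_row, a_col, "+")
  v0 <- min(v_all)
  support <- tabulate(floor((v_all - v0) / g + 0.5) + 1L)
  counts <- tabulate(floor((v - v0) / g + 0.5) + 1L, nbins = length(support))
  keep <- which(support >= 0.6 * max(support))
  i0 <- min(keep); i1 <- max(keep)
  density <- counts[i0:i1] / support[i0:i1]
  lag_max <- min(length(density) - 1L, ceiling(max_spacing / g))
  ac <- as.numeric(stats::acf(density, lag.max = lag_max, plot = FALSE,
                              demean = TRUE)$acf)
  # smooth the correlogram: binning the profile at pixel width aliases a
  # non-integer row period into a 2-bin oscillation of the raw ACF
  acs <- as.numeric(stats::filter(ac, c(0.25, 0.5, 0.25)))
  acs[is.na(acs)] <- ac[is.na(acs)]
  lag0 <- max(2L, round(0.2 / g))          # ignore spacings below 0.2 m
  cand <- (lag0 + 1L):(lag_max + 1L)       # acs[k + 1] is lag k
  top <- max(acs[cand])
  baseline <- stats::median(abs(acs[cand]))
  if (top < max(2 * baseline, 0.15)) {
    stop(sprintf(
      "row detection failed: no periodic row structure (autocorrelation peak %.3f, baseline %.3f)",
      top, baseline), call. = FALSE)
  }
  # fundamental spacing: the smallest-lag local maximum comparable to the
  # global peak (the global maximum itself may sit on a harmonic), then a
  # least-squares fit through all harmonic peaks k * lag
  ac_c <- acs[cand]
  n_c <- length(ac_c)
  is_lmax <- ac_c >= c(-Inf, ac_c[-n_c]) & ac_c >= c(ac_c[-1], -Inf)
  loc <- cand[is_lmax & ac_c >= 0.5 * top]
  peak_i <- if (length(loc)) min(loc) else cand[which.max(ac_c)]
  peak <- acs[peak_i]
  refine <- function(i) {
    y0 <- acs[i - 1L]; y1 <- acs[i]; y2 <- acs[i + 1L]
    if (!is.na(y2) && !is.na(y0) && (y0 - 2 * y1 + y2) < 0) {
      (i - 1L) + 0.5 * (y0 - y2) / (y0 - 2 * y1 + y2)
    } else i - 1L
  }
  L1 <- refine(peak_i)
  ks <- numeric(0); lags <- numeric(0)
  for (k in seq_len(max(1L, floor(lag_max / L1)))) {
    win <- round(k * L1) + seq(-ceiling(L1 / 4), ceiling(L1 / 4))
    win <- win[win >= lag0 & win <= lag_max]
    if (!length(win)) next
    j <- win[which.max(acs[win + 1L])] + 1L
    if (acs[j] < 0.3 * top) next
    ks <- c(ks, k); lags <- c(lags, refine(j))
  }
  spacing <- if (length(ks)) sum(ks * lags) / sum(ks^2) * g else L1 * g
  # phase: modal bin of the folded coordinate, refined by local centroid
  w <- (v - min(v)) %% spacing
  h <- tabulate(floor(w / (spacing / 64)) + 1L, nbins = 64L)
  w_peak <- (which.max(h) - 0.5) * spacing / 64
  dw <- ((w - w_peak + spacing / 2) %% spacing) - spacing / 2
  near <- abs(dw) <= 0.25 * spacing
  phase_local <- w_peak + mean(dw[near])
  phase <- min(v) + phase_local
  kmin <- ceiling((min(v) - phase) / spacing)
  kmax <- floor((max(v) - phase) / spacing)
  if (is.null(row_halfwidth)) row_halfwidth <- max(0.15, 2 * g)
  structure(list(orientation = theta, spacing = spacing, phase = phase,
                 offsets = phase + (kmin:kmax) * spacing,
                 row_halfwidth = row_halfwidth,
                 peak = c(value = peak, baseline = baseline)),
            class = "row_model")
}

#' @export
print.row_model <- function(x, ...) {
  cat(sprintf("<row_model> orientation %.2f deg, spacing %.3f m, %d rows, halfwidth %.3f m\n",
              x$orientation, x$spacing, length(x$offsets), x$row_halfwidth))
  invisible(x)
}

# perpendicular distance of points to the nearest row centreline
row_distance <- function(x, y, row_model) {
  th <- row_model$orientation * pi / 180
  v <- -x * sin(th) + y * cos(th)
  dv <- v - row_model$phase
  abs(dv - round(dv / row_model$spacing) * row_model$spacing)
}

#' Classify vegetation objects as crop or weed by row position
#'
#' An object whose centroid lies within the row band (perpendicular distance
#' to the nearest detected row centreline at most `row_halfwidth`) is crop;
#' any other vegetation object is weed. Pixels inherit their object's class.
#'
#' @param segmentation Result of [segment_vegetation()].
#' @param row_model A [detect_crop_rows()] result.
#' @param gsd GSD in cm/pixel.
#' @param origin World coordinates (m) of the raster's upper-left corner.
#' @param provenance Optional list recorded in the map.
#' @return An object of class `classified_map`: integer raster `classes`
#'   (0 soil, 1 crop, 2 weed), `gsd`, `origin`, `objects` (with a `class`
#'   column) and `provenance`.
#' @export
classify_objects <- function(segmentation, row_model, gsd,
                             origin = c(0, nrow(segmentation$labels) * gsd / 100),
                             provenance = list()) {
  stopifnot(inherits(row_model, "row_model"))
  obj <- segmentation$objects
  lab <- segmentation$labels
  classes <- matrix(0L, nrow(lab), ncol(lab))
  if (nrow(obj) > 0) {
    d <- row_distance(obj$centroid_x, obj$centroid_y, row_model)
    obj$class <- ifelse(d <= row_model$row_halfwidth, 1L, 2L)
    cls_map <- integer(max(obj$id))
    cls_map[obj$id] <- obj$class
    nz <- lab > 0L
    classes[nz] <- cls_map[lab[nz]]
  } else {
    obj$class <- integer(0)
  }
  structure(list(classes = classes, gsd = gsd, origin = origin,
                 objects = obj, row_model = row_model,
                 provenance = provenance),
            class = "classified_map")
}

#' @export
print.classified_map <- function(x, ...) {
  tab <- tabulate(as.vector(x$classes) + 1L, 3L)
  cat(sprintf("<classified_map> %d x %d px at %.3g cm: soil %.1f%%, crop %.1f%%, weed %.1f%%\n",
              nrow(x$classes), ncol(x$classes), x$gsd,
              100 * tab[1] / length(x$classes),
              100 * tab[2] / length(x$classes),
              100 * tab[3] / length(x$classes)))
  invisible(x)
}

#' Default OBIA parameters
#'
#' @param min_object_area Minimum vegetation-object size in pixels.
#' @param row_halfwidth Crop-row band half-width in m (`NULL` = automatic,
#'   `max(0.15, 2 pixels)`).
#' @param index Vegetation index (`"auto"`, `"exg"`, `"ndvi"`).
#' @param max_spacing Largest candidate row spacing in m.
#' @return List of parameters for [run_obia()].
#' @export
obia_params <- function(min_object_area = 4, row_halfwidth = NULL,
                        index = "auto", max_spacing = 3) {
  list(min_object_area = min_object_area, row_halfwidth = row_halfwidth,
       index = index, max_spacing = max_spacing)
}

#' Run the three-step OBIA weed-mapping procedure
#'
#' (1) Segment the image into vegetation and bare-soil objects, (2)
#' discriminate vegetation by its spectral index, (3) classify each
#' vegetation object as crop or weed from its position relative to the
#' detected crop-row structure. An image with no vegetation objects yields
#' an all-soil map without attempting row detection.
#'
#' @param image An [ortho_image()].
#' @param params An [obia_params()] list.
#' @return A `classified_map`; its `provenance` logs the index type, the
#'   segmentation threshold and the detected orientation and spacing.
#' @export
run_obia <- function(image, params = obia_params()) {
  stopifnot(inherits(image, "ortho_image"))
  idx_type <- params$index
  if (idx_type == "auto") {
    idx_type <- if ("NIR" %in% band_names(image)) "ndvi" else "exg"
  }
  index <- vegetation_index(image, idx_type)
  seg <- segment_vegetation(index, image$gsd,
                            min_object_area = params$min_object_area,
                            index_type = idx_type, origin = image$origin)
  prov <- list(index = idx_type, threshold = seg$threshold,
               threshold_method = seg$threshold_method,
               gsd = image$gsd)
  if (nrow(seg$objects) == 0) {
    return(structure(list(classes = matrix(0L, nrow(index), ncol(index)),
                          gsd = image$gsd, origin = image$origin,
                          objects = seg$objects, row_model = NULL,
                          provenance = prov),
                     class = "classified_map"))
  }
  rm_model <- detect_crop_rows(seg$mask, image$gsd, origin = image$origin,
                               row_halfwidth = params$row_halfwidth,
                               max_spacing = params$max_spacing)
  prov$orientation <- rm_model$orientation
  prov$spacing <- rm_model$spacing
  classify_objects(seg, rm_model, image$gsd, origin = image$origin,
                   provenance = prov)
}

#' Fraction of true row-centreline pixels inside detected row bands
#'
#' Scores a detected row model against the generating geometry: the share of
#' ground-truth centreline pixels (at the given GSD) whose perpendicular
#' distance to the nearest detected row centreline is at most the model's
#' row band half-width.
#'
#' @param truth A [generate_scene()] result.
#' @param row_model A [detect_crop_rows()] result.
#' @param gsd GSD in cm/pixel.
#' @return Fraction in \[0, 1\].
#' @export
row_detection_accuracy <- function(truth, row_model, gsd) {
  mask <- row_centerline_mask(truth, gsd)
  g <- gsd / 100
  nr <- nrow(mask)
  idx <- which(mask)
  x <- (((idx - 1L) %/% nr) + 0.5) * g
  y <- truth$field_size[2] - (((idx - 1L) %% nr) + 0.5) * g
  mean(row_distance(x, y, row_model) <= row_model$row_halfwidth)
}

#' Pixel-level agreement between a classified map and ground truth
#'
#' @param map A `classified_map`.
#' @param truth A [generate_scene()] result (labels are rasterised at the
#'   map's GSD).
#' @return List with overall pixel `accuracy`, `vegetation_accuracy`
#'   (vegetation-vs-soil), and per-class weed `recall` and `precision`.
#' @export
classification_metrics <- function(map, truth) {
  ref <- rasterize_labels(truth, map$gsd)
  stopifnot(identical(dim(ref), dim(map$classes)))
  got <- map$classes
  weed_ref <- ref == 2L; weed_got <- got == 2L
  list(accuracy = mean(got == ref),
       vegetation_accuracy = mean((got > 0L) == (ref > 0L)),
       recall = if (any(weed_ref)) mean(weed_got[weed_ref]) else NA_real_,
       precision = if (any(weed_got)) mean(weed_ref[weed_got]) else NA_real_)
}
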