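#' Root-mean-square error of positional discrepancies
#'
#' @param discrepancies Non-empty numeric vector of coordinate differences
#'   (any length unit; the result is in the same unit).
#' @return `sqrt(mean(discrepancies^2))`.
#' @export
rmse <- function(discrepancies) {
  if (length(discrepancies) == 0) stop("empty discrepancy list", call. = FALSE)
  if (anyNA(discrepancies) || any(!is.finite(discrepancies))) {
    stop("discrepancies must be finite", call. = FALSE)
  }
  sqrt(mean(discrepancies^2))
}

#' ASPRS 1990 Class-1 limiting horizontal RMSE
#'
#' The 1990 ASPRS large-scale map accuracy standard sets the allowable
#' per-axis RMSE for Class 1 proportional to the map scale; the constant is
#' 0.025 cm per unit scale denominator, so a 1:50 map allows 1.25 cm.
#' Classes 2 and 3 allow two and three times this limit.
#'
#' @param scale_denominator Positive integer map-scale denominator
#'   (50 for 1:50).
#' @return Class-1 limiting RMSE in cm.
#' @examples
#' class1_limit(50)  # 1.25
#' @export
class1_limit <- function(scale_denominator) {
  if (length(scale_denominator) != 1 || !is.finite(scale_denominator) ||
      scale_denominator <= 0) {
    stop("scale denominator must be a single positive number", call. = FALSE)
  }
  0.025 * scale_denominator
}

#' ASPRS horizontal accuracy test
#'
#' Evaluates per-axis RMSEs of at least 20 check points and assigns the map
#' to accuracy Class 1, 2 or 3 (or `"fail"`). X and Y are evaluated
#' separately and the worse axis determines the class: the achieved class is
#' the smallest k in 1..3 such that `max(rmse_x, rmse_y) <= k * class1_limit`.
#'
#' @param pairs Data frame of point pairs with columns `id`, `ref_x`,
#'   `ref_y`, `test_x`, `test_y` (coordinates in m), e.g. from
#'   [measure_pairs()].
#' @param scale_denominator Map-scale denominator for the class limits.
#' @return A list of class `asprs_report`: `n_points`, `rmse_x`, `rmse_y`
#'   (cm), `scale_denominator`, `class_limit_1` (cm), `achieved_class`
#'   (1, 2, 3 or `"fail"`) and `limiting_axis` (`"X"` or `"Y"`).
#' @export
asprs_test <- function(pairs, scale_denominator) {
  req <- c("id", "ref_x", "ref_y", "test_x", "test_y")
  miss <- setdiff(req, names(pairs))
  if (length(miss)) {
    stop("point-pair table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  pairs <- pairs[stats::complete.cases(pairs[req]), , drop = FALSE]
  if (nrow(pairs) < 20) {
    stop(sprintf("insufficient points for the ASPRS test: %d found, a minimum of 20 is required",
                 nrow(pairs)), call. = FALSE)
  }
  rmse_x <- rmse((pairs$test_x - pairs$ref_x) * 100)  # m -> cm
  rmse_y <- rmse((pairs$test_y - pairs$ref_y) * 100)
  lim1 <- class1_limit(scale_denominator)
  worst <- max(rmse_x, rmse_y)
  k <- which(worst <= (1:3) * lim1)
  structure(list(n_points = nrow(pairs),
                 rmse_x = rmse_x, rmse_y = rmse_y,
                 scale_denominator = scale_denominator,
                 class_limit_1 = lim1,
                 achieved_class = if (length(k)) min(k) else "fail",
                 limiting_axis = if (rmse_x >= rmse_y) "X" else "Y"),
            class = "asprs_report")
}

#' @export
print.asprs_report <- function(x, ...) {
  cat(sprintf("<asprs_report> n = %d, RMSE X = %.3f cm, Y = %.3f cm (1:%d, Class-1 limit %.3f cm)\n",
              x$n_points, x$rmse_x, x$rmse_y, x$scale_denominator, x$class_limit_1))
  cat(sprintf("  achieved class: %s (limiting axis %s)\n",
              as.character(x$achieved_class), x$limiting_axis))
  invisible(x)
}

#' Per-band mean and standard deviation
#'
#' Band statistics are the histogram summaries used to verify that a
#' resampling method left the digital numbers of an image unmodified.
#'
#' @param image An [ortho_image()].
#' @return Data frame with columns `band`, `mean`, `sd`.
#' @export
band_stats <- function(image) {
  stopifnot(inherits(image, "ortho_image"))
  data.frame(band = band_names(image),
             mean = vapply(image$bands, function(m) mean(as.numeric(m)), 0),
             sd = vapply(image$bands, function(m) stats::sd(as.numeric(m)), 0),
             row.names = NULL)
}

#' Compare per-band statistics of two images
#'
#' @param a,b [ortho_image()] objects with identical band sets.
#' @param digits Decimals for the reported deltas (default 2).
#' @return Data frame with per-band means/sds of both images and the deltas
#'   `(b - a)` rounded to `digits`.
#' @export
compare_stats <- function(a, b, digits = 2) {
  sa <- band_stats(a); sb <- band_stats(b)
  if (!identical(sa$band, sb$band)) {
    stop("band sets differ between the two images", call. = FALSE)
  }
  data.frame(band = sa$band,
             mean_a = sa$mean, sd_a = sa$sd,
             mean_b = sb$mean, sd_b = sb$sd,
             dmean = round(sb$mean - sa$mean, digits),
             dsd = round(sb$sd - sa$sd, digits))
}

#' Locate control-point markers in two images and pair them
#'
#' Control points are rendered as saturated high-contrast square markers.
#' For each point, a search window (+/- `window` pixels around the true
#' position) is examined in each image, bright pixels (DN >= `threshold` in
#' the first band) are collected and their DN-weighted centroid gives the
#' measured position in world metres. A marker with no bright pixel in its
#' window is reported missing (`NA` coordinates).
#'
#' @param reference,test [ortho_image()] objects covering the same ground.
#' @param control_points Data frame with columns `id`, `x`, `y` (true world
#'   positions, m).
#' @param window Half-width of the search window in pixels (default 10).
#' @param threshold DN threshold identifying marker pixels (default 250).
#' @return Data frame `id`, `ref_x`, `ref_y`, `test_x`, `test_y`, `missing`.
#' @export
measure_pairs <- function(reference, test, control_points,
                          window = 10, threshold = 250) {
  req <- c("id", "x", "y")
  miss <- setdiff(req, names(control_points))
  if (length(miss)) {
    stop("control-point table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  loc_ref <- t(vapply(seq_len(nrow(control_points)), function(i) {
    marker_centroid(reference, control_points$x[i], control_points$y[i],
                    window, threshold)
  }, c(0, 0)))
  loc_tst <- t(vapply(seq_len(nrow(control_points)), function(i) {
    marker_centroid(test, control_points$x[i], control_points$y[i],
                    window, threshold)
  }, c(0, 0)))
  data.frame(id = control_points$id,
             ref_x = loc_ref[, 1], ref_y = loc_ref[, 2],
             test_x = loc_tst[, 1], test_y = loc_tst[, 2],
             missing = is.na(loc_ref[, 1]) | is.na(loc_tst[, 1]))
}

# DN-weighted centroid (world m) of marker pixels near a true position
marker_centroid <- function(image, x, y, window, threshold) {
  d <- dim(image)
  px <- world_to_px(image, x, y)
  r0 <- max(1L, floor(px[1, "row"] - window))
  r1 <- min(d[1], ceiling(px[1, "row"] + window))
  c0 <- max(1L, floor(px[1, "col"] - window))
  c1 <- min(d[2], ceiling(px[1, "col"] + window))
  if (r0 > r1 || c0 > c1) return(c(NA_real_, NA_real_))
  sub <- image$bands[[1]][r0:r1, c0:c1, drop = FALSE]
  hit <- which(sub >= threshold, arr.ind = TRUE)
  if (nrow(hit) == 0) return(c(NA_real_, NA_real_))
  w <- as.numeric(sub[hit])
  rows <- r0 + hit[, 1] - 1
  cols <- c0 + hit[, 2] - 1
  ctr <- px_center_world(image, sum(rows * w) / sum(w), sum(cols * w) / sum(w))
  c(ctr[1, "x"], ctr[1, "y"])
}
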