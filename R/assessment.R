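#' The seven weed-threshold series
#'
#' Thresholds for treatment mapping run from 0% (treat on any weed presence)
#' to 15% weed cover in steps of 2.5 percentage points.
#'
#' @return Numeric vector `c(0, 2.5, 5, 7.5, 10, 12.5, 15)`.
#' @export
threshold_series <- function() seq(0, 15, by = 2.5)

#' Weed cover of one sampling frame on a classified map
#'
#' Percent of the frame's pixels classified as weed, counting a pixel as
#' inside the frame when its centre is (pixel-centre rule).
#'
#' @param map A `classified_map` from [run_obia()].
#' @param frame One-row data frame (or list) with `x`, `y` (min corner, m)
#'   and `side` (m).
#' @return Weed cover in percent.
#' @export
frame_weed_cover <- function(map, frame) {
  stopifnot(inherits(map, "classified_map"))
  g <- map$gsd / 100
  x0 <- frame$x - map$origin[1]
  ytop <- map$origin[2] - (frame$y + frame$side)
  c0 <- max(1L, ceiling(x0 / g + 0.5))
  c1 <- min(ncol(map$classes), floor((x0 + frame$side) / g + 0.5))
  r0 <- max(1L, ceiling(ytop / g + 0.5))
  r1 <- min(nrow(map$classes), floor((ytop + frame$side) / g + 0.5))
  if (c0 > ncol(map$classes) || r0 > nrow(map$classes) ||
      c1 < 1 || r1 < 1 || c0 > c1 || r0 > r1) {
    stop("frame lies outside the classified raster", call. = FALSE)
  }
  100 * mean(map$classes[r0:r1, c0:c1] == 2L)
}

#' Per-frame weed covers for a whole frame table
#'
#' @param map A `classified_map`.
#' @param frames Data frame with columns `id`, `x`, `y`, `side` (and
#'   optionally `category`).
#' @return Data frame `id`, `cover` (percent), plus `category` if present.
#' @export
frame_covers <- function(map, frames) {
  out <- data.frame(id = frames$id,
                    cover = vapply(seq_len(nrow(frames)), function(i) {
                      frame_weed_cover(map, frames[i, ])
                    }, 0))
  if ("category" %in% names(frames)) out$category <- frames$category
  out
}

#' Treatment decision at a weed threshold
#'
#' Herbicide Treatment is prescribed when the weed cover strictly exceeds
#' the threshold; at threshold 0 this means treatment on any weed presence,
#' and a cover exactly equal to an interior threshold is No-Treatment.
#'
#' @param cover Weed cover in percent (0-100), vectorised.
#' @param threshold Threshold in percent (0-100).
#' @return Character vector `"Treatment"` / `"No-Treatment"`.
#' @export
treatment_decision <- function(cover, threshold) {
  if (any(cover < 0 | cover > 100) || any(threshold < 0 | threshold > 100)) {
    stop("cover and threshold must lie in [0, 100]", call. = FALSE)
  }
  ifelse(cover > threshold, "Treatment", "No-Treatment")
}

#' Treatment map of frames at one threshold
#'
#' @param covers Data frame with `id` and `cover` (e.g. [frame_covers()]).
#' @param threshold Weed threshold in percent.
#' @return Data frame `id`, `cover`, `decision`, with attribute `threshold`.
#' @export
treatment_map <- function(covers, threshold) {
  out <- data.frame(id = covers$id, cover = covers$cover,
                    decision = treatment_decision(covers$cover, threshold))
  attr(out, "threshold") <- threshold
  out
}

#' Treatment/No-Treatment concordance between two cover estimates
#'
#' For each threshold, the percentage of frames receiving the same decision
#' from both cover estimates. When categories are supplied, per-category
#' match percentages and the 2x2 decision table per threshold are reported.
#'
#' @param covers_a,covers_b Data frames with `id`, `cover` (and optionally
#'   `category` in `covers_a`) over the same frame ids.
#' @param thresholds Threshold series in percent (default
#'   [threshold_series()]).
#' @return An object of class `concordance_report`: `per_threshold` (data
#'   frame `threshold`, `match_pct`, `n_treat_a`, `n_treat_b`),
#'   `per_category` (match percent by category and threshold, or `NULL`),
#'   `decision_tables` (list of 2x2 tables), `n_frames`.
#' @export
concordance <- function(covers_a, covers_b, thresholds = threshold_series()) {
  if (!setequal(covers_a$id, covers_b$id) ||
      length(covers_a$id) != length(covers_b$id)) {
    stop("frame id mismatch between the two cover tables", call. = FALSE)
  }
  b <- covers_b[match(covers_a$id, covers_b$id), ]
  ca <- covers_a$cover; cb <- b$cover
  lev <- c("Treatment", "No-Treatment")
  per <- lapply(thresholds, function(t) {
    da <- factor(treatment_decision(ca, t), levels = lev)
    db <- factor(treatment_decision(cb, t), levels = lev)
    list(match = 100 * mean(da == db),
         tab = table(a = da, b = db),
         n_a = sum(da == "Treatment"), n_b = sum(db == "Treatment"))
  })
  per_threshold <- data.frame(
    threshold = thresholds,
    match_pct = vapply(per, `[[`, 0, "match"),
    n_treat_a = vapply(per, `[[`, 0L, "n_a"),
    n_treat_b = vapply(per, `[[`, 0L, "n_b"))
  per_category <- NULL
  if ("category" %in% names(covers_a)) {
    per_category <- do.call(rbind, lapply(thresholds, function(t) {
      same <- treatment_decision(ca, t) == treatment_decision(cb, t)
      agg <- aggregate(same, by = list(category = covers_a$category), FUN = mean)
      data.frame(threshold = t, category = agg$category,
                 match_pct = 100 * agg$x)
    }))
  }
  structure(list(per_threshold = per_threshold,
                 per_category = per_category,
                 decision_tables = stats::setNames(lapply(per, `[[`, "tab"),
                                                   paste0("t", thresholds)),
                 n_frames = length(ca)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %d frames\n", x$n_frames))
  print(x$per_threshold, row.names = FALSE)
  invisible(x)
}

#' Field-level weed cover of a classified map
#'
#' @param map A `classified_map`.
#' @param mask Optional logical matrix restricting the computation to a
#'   common area (e.g. when two maps cover slightly different extents).
#' @return Percent of (masked) pixels classified as weed.
#' @export
field_weed_cover <- function(map, mask = NULL) {
  stopifnot(inherits(map, "classified_map"))
  cls <- map$classes
  if (length(cls) == 0) stop("empty classified map", call. = FALSE)
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(cls)))
    cls <- cls[mask]
  }
  100 * mean(cls == 2L)
}
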