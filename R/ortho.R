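#' Georeferenced multi-band ortho-image
#'
#' An `ortho_image` is a set of equally sized single-band rasters of 8-bit
#' digital numbers (DN, integers 0-255) with a ground sample distance and a
#' world origin. Pixels are row-major with origin at the top-left corner;
#' world x increases with column, world y decreases with row, so `origin`
#' is the world coordinate (m) of the outer corner of pixel (1, 1).
#'
#' @param bands Named list of integer matrices (same dimensions, values in
#'   0-255). Recognised band sets contain at least `R`,`G`,`B` or `R`,`NIR`.
#' @param gsd Ground sample distance in cm per pixel.
#' @param origin Numeric length-2, world (x, y) in m of the upper-left corner.
#' @param meta Optional list of provenance metadata.
#' @return An object of class `ortho_image`.
#' @export
ortho_image <- function(bands, gsd, origin = c(0, 0), meta = list()) {
  if (!is.list(bands) || length(bands) == 0 || is.null(names(bands)) ||
      any(!nzchar(names(bands)))) {
    stop("bands must be a non-empty named list of matrices", call. = FALSE)
  }
  d <- dim(bands[[1]])
  for (b in names(bands)) {
    m <- bands[[b]]
    if (!is.matrix(m) || !identical(dim(m), d)) {
      stop("all bands must be matrices of identical dimensions", call. = FALSE)
    }
    if (anyNA(m) || any(m < 0) || any(m > 255) || any(m != round(m))) {
      stop(sprintf("band '%s' must hold integer digital numbers in [0, 255]", b),
           call. = FALSE)
    }
  }
  if (!is.finite(gsd) || gsd <= 0) stop("gsd must be positive", call. = FALSE)
  structure(list(bands = lapply(bands, function(m) {
    storage.mode(m) <- "integer"; m
  }),
  gsd = gsd, origin = as.numeric(origin), meta = meta),
  class = "ortho_image")
}

#' @export
dim.ortho_image <- function(x) dim(x$bands[[1]])

#' @export
print.ortho_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<ortho_image> %d x %d px, %d band(s) [%s], gsd %.4g cm/px, origin (%.2f, %.2f) m\n",
              d[1], d[2], length(x$bands), paste(names(x$bands), collapse = ","),
              x$gsd, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Band names of an ortho-image
#' @param image An [ortho_image()].
#' @return Character vector of band names.
#' @export
band_names <- function(image) names(image$bands)

# world coordinates (m) of pixel centres for row/column indices (1-based)
px_center_world <- function(image, row, col) {
  g <- image$gsd / 100
  cbind(x = image$origin[1] + (col - 0.5) * g,
        y = image$origin[2] - (row - 0.5) * g)
}

# fractional (row, col) of a world point; pixel (r,c) spans (r-1,r] x (c-1,c]
world_to_px <- function(image, x, y) {
  g <- image$gsd / 100
  cbind(row = (image$origin[2] - y) / g + 0.5,
        col = (x - image$origin[1]) / g + 0.5)
}
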