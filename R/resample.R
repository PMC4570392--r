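#' Nearest-neighbour resampling of an ortho-image
#'
#' Produces a raster at a new ground sample distance by copying, for every
#' output pixel, the digital number of the source pixel whose centre is
#' nearest to the output pixel centre. No digital number is ever modified or
#' averaged, so the output DN values are a sub-multiset of the input values
#' (the defining property of nearest-neighbour degradation, in contrast to
#' bilinear or cubic interpolation).
#'
#' Conventions: pixel (r, c) has its centre at (r - 0.5, c - 0.5) in grid
#' units; output dimensions are `floor(input_dim * factor)`; an output centre
#' mapped to source coordinates selects the source pixel with the nearest
#' centre, ties broken toward the upper-left (smaller index).
#'
#' @param image An [ortho_image()].
#' @param spec A [resample_spec()] whose `source_gsd` matches `image$gsd`
#'   (within 1e-6).
#' @return An [ortho_image()] at `spec$target_gsd` with the same origin.
#'   Upsampling (factor > 1) is allowed and flagged in `meta$upsampled`.
#' @examples
#' img <- ortho_image(list(R = matrix(0:15, 4, 4, byrow = TRUE)), gsd = 1)
#' nn_resample(img, resample_spec(1, 2))
#' @export
nn_resample <- function(image, spec) {
  stopifnot(inherits(image, "ortho_image"), inherits(spec, "resample_spec"))
  if (abs(spec$source_gsd - image$gsd) > 1e-6) {
    stop("resample_spec source GSD does not match the image GSD", call. = FALSE)
  }
  d <- dim(image)
  out_nr <- floor(d[1] * spec$yfactor)
  out_nc <- floor(d[2] * spec$xfactor)
  if (out_nr < 1 || out_nc < 1) {
    stop("resampling factor too small: output raster would be empty", call. = FALSE)
  }
  rows <- nn_source_index(out_nr, spec$yfactor, d[1])
  cols <- nn_source_index(out_nc, spec$xfactor, d[2])
  bands <- lapply(image$bands, function(m) m[rows, cols, drop = FALSE])
  meta <- image$meta
  meta$resample <- list(method = "nearest", source_gsd = spec$source_gsd,
                        xfactor = spec$xfactor, yfactor = spec$yfactor)
  meta$upsampled <- spec$xfactor >= 1
  ortho_image(bands, gsd = spec$target_gsd, origin = image$origin, meta = meta)
}

# source index of the nearest source-pixel centre for each of n output pixels:
# output centre (i - 0.5) maps to (i - 0.5)/factor in source grid units; the
# nearest centre (j - 0.5) is j = ceiling(mapped), which rounds exact ties
# toward the smaller (upper-left) index.
nn_source_index <- function(n_out, factor, n_src) {
  src <- (seq_len(n_out) - 0.5) / factor
  pmin(pmax(ceiling(src), 1L), n_src)
}

#' Integer-stride subsampling oracle
#'
#' Reference implementation of nearest-neighbour downsampling for integer
#' factors 1/step: picks every `step`-th pixel starting from the one whose
#' centre is nearest the first output centre under the same pixel-centre
#' convention as [nn_resample()]. For `factor = 1/step` the two must agree
#' bit-exactly; this function exists as an independently simple cross-check.
#'
#' @param image An [ortho_image()].
#' @param step Integer stride >= 1.
#' @return An [ortho_image()] at `step * image$gsd`.
#' @export
striding_oracle <- function(image, step) {
  stopifnot(inherits(image, "ortho_image"))
  if (length(step) != 1 || !is.finite(step) || step != round(step) || step < 1) {
    stop("step must be a single integer >= 1", call. = FALSE)
  }
  step <- as.integer(step)
  d <- dim(image)
  start <- as.integer(ceiling(step / 2))
  if (start > d[1] || start > d[2] || floor(d[1] / step) < 1 || floor(d[2] / step) < 1) {
    stop("stride exceeds image dimensions: output raster would be empty", call. = FALSE)
  }
  rows <- seq.int(start, by = step, length.out = floor(d[1] / step))
  cols <- seq.int(start, by = step, length.out = floor(d[2] / step))
  bands <- lapply(image$bands, function(m) m[rows, cols, drop = FALSE])
  ortho_image(bands, gsd = image$gsd * step, origin = image$origin,
              meta = c(image$meta, list(stride = step)))
}
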