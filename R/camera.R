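#' Camera models and ground-sample-distance arithmetic
#'
#' A `camera_model` bundles the sensor and optics parameters from which the
#' ground footprint of a pixel (ground sample distance, GSD) at a given
#' flight altitude is derived: GSD = altitude x pixel pitch / focal length.
#'
#' @param name Short camera name.
#' @param sensor_width,sensor_height Physical sensor size in mm.
#' @param image_width,image_height Image size in pixels.
#' @param focal_length Focal length in mm.
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model("RGB", 17.3, 13, 4032, 3024, 14)
#' pixel_pitch(cam)           # 4.3 micrometres
#' gsd(flight_spec(60, cam))  # 1.84 cm/pixel
#' @export
camera_model <- function(name, sensor_width, sensor_height,
                         image_width, image_height, focal_length) {
  dims <- c(sensor_width = sensor_width, sensor_height = sensor_height,
            image_width = image_width, image_height = image_height,
            focal_length = focal_length)
  if (any(!is.finite(dims)) || any(dims <= 0)) {
    stop("invalid camera: all sensor/image/focal dimensions must be strictly positive",
         call. = FALSE)
  }
  pitch_w <- sensor_width / image_width
  pitch_h <- sensor_height / image_height
  if (pitch_w <= 0 || pitch_w >= 1 || pitch_h <= 0 || pitch_h >= 1) {
    stop("invalid camera: pixel pitch must lie in (0, 1) mm", call. = FALSE)
  }
  structure(list(name = name,
                 sensor_width = sensor_width, sensor_height = sensor_height,
                 image_width = image_width, image_height = image_height,
                 focal_length = focal_length),
            class = "camera_model")
}

#' Built-in camera presets
#'
#' Two presets are provided: `"RGB"`, a 12-megapixel visible-range still
#' camera (4032 x 3024 px, 17.3 x 13 mm sensor, zoom lens fixed at its 14 mm
#' wide end), and `"TTC"`, a 1.3-megapixel multispectral camera with a
#' near-infrared band (1280 x 1024 px, 6.66 x 5.32 mm sensor, 9.6 mm focal
#' length).
#'
#' @param name `"RGB"` or `"TTC"`.
#' @return A [camera_model()].
#' @export
camera_preset <- function(name = c("RGB", "TTC")) {
  name <- match.arg(name)
  switch(name,
         RGB = camera_model("RGB", 17.3, 13, 4032, 3024, 14),
         TTC = camera_model("TTC", 6.66, 5.32, 1280, 1024, 9.6))
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> %s: %d x %d px, sensor %.2f x %.2f mm, f = %.1f mm, pitch %.1f um\n",
              x$name, x$image_width, x$image_height,
              x$sensor_width, x$sensor_height, x$focal_length, pixel_pitch(x)))
  invisible(x)
}

#' Pixel pitch of a camera
#'
#' Physical size of one sensor pixel, `sensor_width / image_width`, expressed
#' in micrometres and rounded to 0.1 um. The width axis and the 0.1-um
#' rounding are the conventions under which the reference 60 m and 100 m
#' pixel sizes of both preset cameras are reproduced exactly.
#'
#' @param camera A [camera_model()].
#' @return Pixel pitch in micrometres (um), rounded to 0.1 um.
#' @export
pixel_pitch <- function(camera) {
  stopifnot(inherits(camera, "camera_model"))
  round(camera$sensor_width / camera$image_width * 1000, 1)
}

#' Flight specification
#'
#' @param altitude Flight altitude above ground in m (> 0).
#' @param camera A [camera_model()].
#' @return An object of class `flight_spec`.
#' @export
flight_spec <- function(altitude, camera) {
  stopifnot(inherits(camera, "camera_model"))
  if (!is.finite(altitude) || altitude <= 0) {
    stop("altitude must be strictly positive", call. = FALSE)
  }
  structure(list(altitude = altitude, camera = camera), class = "flight_spec")
}

#' Ground sample distance for a flight
#'
#' GSD = altitude x pixel pitch / focal length, converted to cm per pixel and
#' reported rounded to 2 decimals (internal arithmetic is unrounded and
#' linear in altitude; only the pixel pitch carries its own 0.1-um rounding).
#'
#' @param flight A [flight_spec()].
#' @param round_to Decimal places for the reported value (default 2; use
#'   `Inf` for the unrounded value).
#' @return GSD in cm per pixel.
#' @examples
#' gsd(flight_spec(100, camera_preset("TTC")))  # 5.42
#' @export
gsd <- function(flight, round_to = 2) {
  stopifnot(inherits(flight, "flight_spec"))
  pitch_mm <- pixel_pitch(flight$camera) / 1000
  g_cm <- flight$altitude * 100 * pitch_mm / flight$camera$focal_length
  if (is.finite(round_to)) round(g_cm, round_to) else g_cm
}

#' Resampling specification between two ground sample distances
#'
#' The x and y scale factors of a resampling operation are the ratio of the
#' source pixel size to the targeted pixel size; a factor below 1 is a
#' downsampling (spatial degradation).
#'
#' @param source_gsd,target_gsd Pixel sizes in cm/pixel (> 0).
#' @return An object of class `resample_spec` with fields `source_gsd`,
#'   `target_gsd`, `xfactor`, `yfactor`.
#' @examples
#' resample_spec(1.07, 3.07)  # 30 m visible imagery degraded to 100 m
#' @export
resample_spec <- function(source_gsd, target_gsd) {
  if (!is.finite(source_gsd) || !is.finite(target_gsd) ||
      source_gsd <= 0 || target_gsd <= 0) {
    stop("source and target GSD must be strictly positive", call. = FALSE)
  }
  f <- source_gsd / target_gsd
  structure(list(source_gsd = source_gsd, target_gsd = target_gsd,
                 xfactor = f, yfactor = f),
            class = "resample_spec")
}

#' @export
print.resample_spec <- function(x, ...) {
  cat(sprintf("<resample_spec> %.4g -> %.4g cm/px (factor %.4f, %s)\n",
              x$source_gsd, x$target_gsd, x$xfactor,
              if (x$xfactor < 1) "downsampling" else "upsampling/identity"))
  invisible(x)
}
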