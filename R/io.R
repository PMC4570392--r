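#' Write an ortho-image to disk
#'
#' Writes the digital numbers as an 8-bit TIFF or PNG (bands as channels),
#' an ESRI world file (`.tfw` / `.pgw`) carrying the affine transform in
#' metres, and a JSON sidecar (`.json`) with band names, GSD and metadata.
#' The round trip through [read_ortho()] is DN-exact.
#'
#' @param image An [ortho_image()].
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_ortho <- function(image, path) {
  stopifnot(inherits(image, "ortho_image"))
  ext <- tolower(tools::file_ext(path))
  d <- dim(image)
  arr <- array(0, c(d[1], d[2], length(image$bands)))
  for (i in seq_along(image$bands)) arr[, , i] <- image$bands[[i]] / 255
  ok <- switch(ext,
               tif = , tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8),
               png = png::writePNG(drop_to_png(arr), path),
               stop("unsupported raster format: .", ext, call. = FALSE))
  g <- image$gsd / 100
  world <- c(g, 0, 0, -g,
             image$origin[1] + g / 2, image$origin[2] - g / 2)
  writeLines(formatC(world, format = "fg", digits = 10),
             world_path(path))
  jsonlite::write_json(list(bands = names(image$bands), gsd = image$gsd,
                            origin = image$origin, meta = image$meta),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# PNG writer accepts 1-4 channels only
drop_to_png <- function(arr) {
  if (dim(arr)[3] > 4) stop("PNG supports at most 4 bands", call. = FALSE)
  if (dim(arr)[3] == 2) arr <- arr[, , c(1, 1, 2)]  # pad R,NIR to 3 channels
  arr
}

world_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  sub(paste0("\\.", ext, "$"), if (ext == "png") ".pgw" else ".tfw",
      path, ignore.case = TRUE)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read an ortho-image written by [write_ortho()]
#'
#' @param path Path to the `.tif`/`.png` file; the world file and JSON
#'   sidecar written alongside it are required.
#' @return An [ortho_image()].
#' @export
read_ortho <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  side <- sidecar_path(path)
  if (!file.exists(side)) {
    stop("missing JSON sidecar for raster: ", side, call. = FALSE)
  }
  info <- jsonlite::read_json(side, simplifyVector = TRUE)
  ext <- tolower(tools::file_ext(path))
  # libtiff flags our 2-band (R/NIR) layout as "extra samples"; benign here
  read_tif <- function(p) withCallingHandlers(
    tiff::readTIFF(p),
    warning = function(w) {
      if (grepl("ExtraSamples", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  arr <- switch(ext,
                tif = , tiff = read_tif(path),
                png = png::readPNG(path),
                stop("unsupported raster format: .", ext, call. = FALSE))
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
  nb <- length(info$bands)
  if (ext == "png" && nb == 2 && dim(arr)[3] == 3) {
    arr <- arr[, , c(1, 3), drop = FALSE]  # undo R,NIR padding
  }
  if (dim(arr)[3] != nb) {
    stop(sprintf("format error in %s: %d channel(s) on disk but %d band(s) declared",
                 path, dim(arr)[3], nb), call. = FALSE)
  }
  bands <- lapply(seq_len(nb), function(i) {
    matrix(as.integer(round(arr[, , i] * 255)), dim(arr)[1], dim(arr)[2])
  })
  names(bands) <- info$bands
  meta <- if (is.null(info$meta)) list() else as.list(info$meta)
  ortho_image(bands, gsd = info$gsd, origin = as.numeric(info$origin),
              meta = meta)
}

check_columns <- function(df, required, what, path) {
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("schema error in %s '%s': missing column(s) %s",
                 what, path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Read / write sampling-frame tables
#'
#' Frames CSVs carry columns `id`, `x`, `y` (min corner, m), `side` (m),
#' `category` (0-3) and `true_cover` (percent).
#'
#' @param path CSV path.
#' @return `read_frames`: the validated data frame.
#' @export
read_frames <- function(path) {
  if (!file.exists(path)) stop("frames file not found: ", path, call. = FALSE)
  check_columns(read.csv(path), c("id", "x", "y", "side", "category"),
                "frames CSV", path)
}

#' @rdname read_frames
#' @param frames Data frame of frames.
#' @export
write_frames <- function(frames, path) {
  check_columns(frames, c("id", "x", "y", "side", "category"),
                "frames table", path)
  write.csv(frames, path, row.names = FALSE)
  invisible(path)
}

#' Read / write control-point tables
#'
#' Control-point CSVs carry columns `id`, `x`, `y` (true positions, m).
#'
#' @param path CSV path.
#' @return `read_control_points`: the validated data frame.
#' @export
read_control_points <- function(path) {
  if (!file.exists(path)) {
    stop("control-point file not found: ", path, call. = FALSE)
  }
  check_columns(read.csv(path), c("id", "x", "y"), "control-point CSV", path)
}

#' @rdname read_control_points
#' @param control_points Data frame of control points.
#' @export
write_control_points <- function(control_points, path) {
  check_columns(control_points, c("id", "x", "y"), "control-point table", path)
  write.csv(control_points, path, row.names = FALSE)
  invisible(path)
}

#' Write a complete synthetic fixture to a directory
#'
#' Writes `image.tif` (+ world file and sidecar), `labels.tif` (class
#' raster: 0 soil, 1 crop, 2 weed), `frames.csv` and `control_points.csv`.
#'
#' @param truth A [generate_scene()] result.
#' @param image An [ortho_image()] rendered from `truth`.
#' @param directory Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(truth, image, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) {
    stop("cannot create fixture directory: ", directory, call. = FALSE)
  }
  paths <- c(image = file.path(directory, "image.tif"),
             labels = file.path(directory, "labels.tif"),
             frames = file.path(directory, "frames.csv"),
             control_points = file.path(directory, "control_points.csv"))
  write_ortho(image, paths["image"])
  lab_img <- ortho_image(list(class = truth$labels), gsd = truth$gsd,
                         origin = c(0, truth$field_size[2]),
                         meta = list(legend = "0=soil,1=crop,2=weed"))
  write_ortho(lab_img, paths["labels"])
  write_frames(truth$frames, paths["frames"])
  write_control_points(truth$control_points, paths["control_points"])
  invisible(paths)
}

#' Read a YAML configuration file
#'
#' Sections: `scenario` (arguments of [field_scenario()]), `cameras`
#' (`altitudes`, `sensors`, `gsd30`), `obia` ([obia_params()] overrides),
#' `assessment` (`thresholds`, `scale_denominator`).
#'
#' @param path YAML file path.
#' @return Config list merged over [default_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

# named sub-lists merge recursively; unnamed lists (arrays) and scalars
# replace the default outright
merge_config <- function(base, user) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]) &&
                     !is.null(names(user[[k]])) && all(nzchar(names(user[[k]])))) {
      merge_config(base[[k]], user[[k]])
    } else user[[k]]
  }
  base
}

#' Default end-to-end configuration
#'
#' Two fields (consecutive scenario seeds), both preset cameras with their
#' 30 m mosaic GSDs (1.07 cm visible, 1.6 cm multispectral), degradation to
#' the 60 m and 100 m pixel sizes, and the one missing flight of the
#' emulated campaign (field 1, visible camera, 60 m) excluded, giving seven
#' resampled images.
#'
#' @param seed Base seed for field 1 (field 2 uses `seed + 101`).
#' @return Config list for [full_run()].
#' @export
default_config <- function(seed = 1) {
  list(seed = seed,
       n_fields = 2,
       scenario = list(),   # field_scenario() overrides
       cameras = list(altitudes = c(60, 100),
                      sensors = c("RGB", "TTC"),
                      gsd30 = list(RGB = 1.07, TTC = 1.6)),
       exclude = list(list(field = 1, sensor = "RGB", altitude = 60)),
       obia = list(),
       assessment = list(thresholds = threshold_series(),
                         scale_denominator = 50))
}
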