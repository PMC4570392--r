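#' Run the complete resampling / weed-mapping experiment
#'
#' Orchestrates the whole design on synthetic fields: generates the fields,
#' renders the 30 m baseline image per sensor, degrades it by
#' nearest-neighbour resampling to the 60 m and 100 m pixel sizes, renders
#' the corresponding "real-flight" images for comparison, and for every
#' resampled/real pair runs the positional quality test, the band-statistics
#' comparison, the OBIA classification of both images, the per-frame weed
#' covers and the Treatment/No-Treatment concordance over the threshold
#' series. Every report embeds the fully resolved configuration and seeds,
#' so a rerun of the same config is byte-identical.
#'
#' @param config Configuration list, see [default_config()] /
#'   [read_config()].
#' @param out_dir Optional output directory; when given, `report.json`,
#'   `frame_covers.csv` and the classified rasters are written there.
#' @param quiet Suppress progress messages.
#' @return The report list, invisibly when `out_dir` is given.
#' @export
full_run <- function(config = default_config(), out_dir = NULL,
                     quiet = FALSE) {
  config <- merge_config(default_config(), config)
  say <- function(...) if (!quiet) message(sprintf(...))
  alts <- config$cameras$altitudes
  if (!length(alts) || all(alts <= 30)) {
    warning("no altitude above 30 m configured: no resampling performed")
  }
  thresholds <- config$assessment$thresholds
  scale_den <- config$assessment$scale_denominator
  obia_p <- do.call(obia_params, config$obia)
  report <- list(config = config, fields = list(), n_rs_images = 0L)
  covers_out <- list()
  rasters <- list()

  for (f in seq_len(config$n_fields)) {
    f_seed <- config$seed + (f - 1L) * 101L
    sc <- do.call(field_scenario,
                  modifyList(config$scenario, list(seed = f_seed)))
    say("field %d: generating scene (seed %d)", f, f_seed)
    truth <- generate_scene(sc)
    field_rep <- list(seed = f_seed, cases = list())
    for (sensor in config$cameras$sensors) {
      band_set <- if (sensor == "TTC") "RNIR" else "RGB"
      gsd30 <- config$cameras$gsd30[[sensor]]
      base <- render_image(truth, sc, gsd30, band_set)
      say("field %d %s: 30 m baseline at %.3g cm/px (%d x %d)",
          f, sensor, gsd30, nrow(base$bands[[1]]), ncol(base$bands[[1]]))
      for (alt in alts[alts > 30]) {
        if (any(vapply(config$exclude, function(e) {
          e$field == f && e$sensor == sensor && e$altitude == alt
        }, TRUE))) {
          say("field %d %s %d m: excluded", f, sensor, alt)
          next
        }
        tg <- gsd(flight_spec(alt, camera_preset(sensor)))
        rs <- nn_resample(base, resample_spec(gsd30, tg))
        uav <- render_image(truth, sc, tg, band_set)
        report$n_rs_images <- report$n_rs_images + 1L
        case <- run_case(truth, sc, uav, rs, tg, thresholds, scale_den,
                         obia_p)
        case$field <- f; case$sensor <- sensor; case$altitude <- alt
        say("field %d %s %d m: RMSE X %.2f / Y %.2f cm (class %s), cover uav %.2f%% rs %.2f%%",
            f, sensor, alt, case$quality$rmse_x, case$quality$rmse_y,
            as.character(case$quality$achieved_class),
            case$field_cover_uav, case$field_cover_rs)
        key <- sprintf("field%d_%s_%dm", f, sensor, alt)
        field_rep$cases[[key]] <- case
        cov <- case$frame_cover_table
        cov$field <- f; cov$sensor <- sensor; cov$altitude <- alt
        covers_out[[key]] <- cov
        rasters[[paste0(key, "_rs")]] <- case$map_rs
        rasters[[paste0(key, "_uav")]] <- case$map_uav
        field_rep$cases[[key]]$map_rs <- NULL
        field_rep$cases[[key]]$map_uav <- NULL
        field_rep$cases[[key]]$frame_cover_table <- NULL
      }
    }
    report$fields[[paste0("field", f)]] <- field_rep
  }
  report$frame_covers <- if (length(covers_out)) {
    do.call(rbind, c(covers_out, list(make.row.names = FALSE)))
  } else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    if (!is.null(report$frame_covers)) {
      write.csv(report$frame_covers, file.path(out_dir, "frame_covers.csv"),
                row.names = FALSE)
    }
    for (key in names(rasters)) {
      m <- rasters[[key]]
      write_ortho(ortho_image(list(class = m$classes), gsd = m$gsd,
                              origin = m$origin,
                              meta = list(legend = "0=soil,1=crop,2=weed")),
                  file.path(out_dir, paste0(key, ".tif")))
    }
    return(invisible(report))
  }
  report
}

# quality + OBIA + assessment for one resampled/real image pair
run_case <- function(truth, sc, uav, rs, tg, thresholds, scale_den, obia_p) {
  pairs <- measure_pairs(uav, rs, truth$control_points)
  qual <- asprs_test(pairs[!pairs$missing, ], scale_den)
  stats_cmp <- compare_stats(uav, rs)
  map_uav <- run_obia(uav, obia_p)
  map_rs <- run_obia(rs, obia_p)
  cov_uav <- frame_covers(map_uav, truth$frames)
  cov_rs <- frame_covers(map_rs, truth$frames)
  conc <- concordance(cov_uav, cov_rs, thresholds)
  d <- pmin(dim(map_uav$classes), dim(map_rs$classes))
  common <- function(m) m$classes[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
  tab <- data.frame(id = cov_uav$id, category = truth$frames$category,
                    true_cover = truth$frames$true_cover,
                    cover_uav = cov_uav$cover, cover_rs = cov_rs$cover)
  list(target_gsd = tg,
       quality = unclass(qual),
       band_stats = stats_cmp,
       obia_uav = map_uav$provenance,
       obia_rs = map_rs$provenance,
       field_cover_uav = 100 * mean(common(map_uav) == 2L),
       field_cover_rs = 100 * mean(common(map_rs) == 2L),
       concordance = list(per_threshold = conc$per_threshold,
                          per_category = conc$per_category),
       frame_cover_table = tab,
       map_uav = map_uav, map_rs = map_rs)
}

# strip non-serialisable bits for the JSON report
report_json <- function(report) {
  report$frame_covers <- NULL
  report
}
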