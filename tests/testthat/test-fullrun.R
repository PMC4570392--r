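small_config <- function() {
  cfg <- default_config(seed = 42)
  cfg$n_fields <- 1
  cfg$cameras$sensors <- "TTC"
  cfg$cameras$altitudes <- 60
  cfg$exclude <- list()
  cfg
}

test_that("a 30 m-only configuration warns that nothing is resampled", {
  cfg <- small_config()
  cfg$cameras$altitudes <- 30
  expect_warning(rep <- full_run(cfg, quiet = TRUE), "no resampling")
  expect_equal(rep$n_rs_images, 0L)
  expect_null(rep$frame_covers)
})

test_that("the same config and seed produce byte-identical reports", {
  cfg <- small_config()
  d1 <- file.path(tempdir(), "run1")
  d2 <- file.path(tempdir(), "run2")
  r1 <- full_run(cfg, out_dir = d1, quiet = TRUE)
  r2 <- full_run(cfg, out_dir = d2, quiet = TRUE)
  expect_equal(r1$n_rs_images, 1L)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  expect_true(file.exists(file.path(d1, "frame_covers.csv")))
  expect_true(file.exists(file.path(d1, "field1_TTC_60m_rs.tif")))
  # the report embeds the fully resolved config and seed
  expect_equal(r1$config$seed, 42)
  expect_equal(r1$config$assessment$scale_denominator, 50)
  case <- r1$fields$field1$cases$field1_TTC_60m
  expect_equal(case$target_gsd, 3.25)
  expect_true(case$quality$achieved_class %in% 1:3)
  expect_equal(nrow(case$concordance$per_threshold), 7)
})
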