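fake_map <- function(classes, gsd = 10, origin = NULL) {
  if (is.null(origin)) origin <- c(0, nrow(classes) * gsd / 100)
  structure(list(classes = classes, gsd = gsd, origin = origin,
                 objects = NULL, row_model = NULL, provenance = list()),
            class = "classified_map")
}

test_that("the threshold series runs 0 to 15 percent in steps of 2.5", {
  expect_equal(threshold_series(), c(0, 2.5, 5, 7.5, 10, 12.5, 15))
  expect_length(threshold_series(), 7)
})

test_that("treatment requires cover to strictly exceed the threshold", {
  expect_equal(treatment_decision(5, 5), "No-Treatment")
  expect_equal(treatment_decision(5.01, 5), "Treatment")
  expect_equal(treatment_decision(0.1, 0), "Treatment")  # any weed at 0%
  expect_equal(treatment_decision(0, 0), "No-Treatment")
  expect_equal(treatment_decision(c(0, 3, 20), 2.5),
               c("No-Treatment", "Treatment", "Treatment"))
  expect_error(treatment_decision(-1, 5), "0, 100")
  expect_error(treatment_decision(5, 101), "0, 100")
})

test_that("a quarter-weed frame has 25 percent cover", {
  cls <- matrix(0L, 20, 20)
  cls[1:10, 1:10] <- 2L
  map <- fake_map(cls, gsd = 10)           # 2 x 2 m raster
  expect_equal(frame_weed_cover(map, list(x = 0, y = 0, side = 2)), 25)
  expect_equal(field_weed_cover(map), 25)
  # the weed quadrant is the upper-left one: world y in [1, 2]
  expect_equal(frame_weed_cover(map, list(x = 0, y = 1, side = 1)), 100)
  expect_equal(frame_weed_cover(map, list(x = 1, y = 0, side = 1)), 0)
  expect_error(frame_weed_cover(map, list(x = 5, y = 5, side = 1)),
               "outside")
})

test_that("treated-frame counts are non-increasing in the threshold", {
  covers <- data.frame(id = 1:12, cover = c(0, 0, 1, 2, 3, 5, 7, 9, 11,
                                            13, 16, 40))
  n_treat <- vapply(threshold_series(), function(t) {
    sum(treatment_decision(covers$cover, t) == "Treatment")
  }, 0L)
  expect_true(all(diff(n_treat) <= 0))
  cc <- concordance(covers, covers)
  expect_equal(cc$per_threshold$n_treat_a, n_treat)
})

test_that("concordance is reflexive, symmetric and id-aligned", {
  a <- data.frame(id = 1:8, cover = c(0, 1, 3, 6, 8, 12, 20, 30),
                  category = rep(0:3, each = 2))
  b <- data.frame(id = 8:1, cover = rev(c(0, 2, 3, 4, 9, 12, 14, 35)))
  self <- concordance(a, a)
  expect_equal(self$per_threshold$match_pct, rep(100, 7))
  ab <- concordance(a, b)
  ba <- concordance(b, a)
  expect_equal(ab$per_threshold$match_pct, ba$per_threshold$match_pct)
  expect_equal(ab$n_frames, 8)
  expect_s3_class(ab$per_category, "data.frame")   # categories in a
  expect_equal(nrow(ab$per_category), 7 * 4)
  expect_error(concordance(a, data.frame(id = 2:9, cover = 1:8)),
               "id mismatch")
})

test_that("field cover honours a common-area mask", {
  cls <- matrix(0L, 10, 10)
  cls[, 1:5] <- 2L
  map <- fake_map(cls)
  expect_equal(field_weed_cover(map), 50)
  mask <- matrix(FALSE, 10, 10); mask[, 1:5] <- TRUE
  expect_equal(field_weed_cover(map, mask), 100)
  expect_error(field_weed_cover(map, matrix(TRUE, 2, 2)))
})
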