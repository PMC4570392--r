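make_pairs <- function(n, dx_cm, dy_cm) {
  data.frame(id = seq_len(n), ref_x = seq_len(n), ref_y = rev(seq_len(n)),
             test_x = seq_len(n) + dx_cm / 100,
             test_y = rev(seq_len(n)) + dy_cm / 100)
}

test_that("rmse is the quadratic mean and rejects degenerate input", {
  expect_equal(rmse(c(3, 4)), sqrt(12.5))
  expect_equal(rmse(rep(-2, 10)), 2)
  expect_error(rmse(numeric(0)), "empty")
  expect_error(rmse(c(1, NA)), "finite")
})

test_that("the Class-1 limit scales with the map-scale denominator", {
  expect_equal(class1_limit(50), 1.25)
  expect_equal(class1_limit(100), 2.5)
  expect_error(class1_limit(0), "positive")
  expect_error(class1_limit(c(50, 100)), "single")
})

test_that("asprs_test classifies by the worst axis against k-fold limits", {
  r1 <- asprs_test(make_pairs(25, 1.0, 0.5), 50)
  expect_equal(r1$achieved_class, 1)
  expect_equal(r1$rmse_x, 1.0)
  expect_equal(r1$rmse_y, 0.5)
  expect_equal(r1$limiting_axis, "X")
  expect_equal(r1$n_points, 25)
  r2 <- asprs_test(make_pairs(25, 0.3, 2.0), 50)
  expect_equal(r2$achieved_class, 2)
  expect_equal(r2$limiting_axis, "Y")
  expect_equal(asprs_test(make_pairs(25, 3.7, 0), 50)$achieved_class, 3)
  expect_equal(asprs_test(make_pairs(25, 4.0, 0), 50)$achieved_class, "fail")
  # just beyond the Class-1 limit falls to Class 2
  expect_equal(asprs_test(make_pairs(20, 1.3, 0), 50)$achieved_class, 2)
})

test_that("fewer than 20 check points is a hard error", {
  expect_error(asprs_test(make_pairs(19, 0.1, 0.1), 50),
               "minimum of 20")
  expect_error(asprs_test(make_pairs(25, 0.1, 0.1)[, -2], 50), "ref_x")
})

test_that("band statistics of an image compared with itself are unchanged", {
  img <- tiny_image()
  cmp <- compare_stats(img, img)
  expect_equal(cmp$dmean, c(0, 0))
  expect_equal(cmp$dsd, c(0, 0))
  expect_error(compare_stats(img,
                             ortho_image(list(R = img$bands$R), gsd = 2)),
               "band sets differ")
})

test_that("measure_pairs recovers a marker centroid to sub-pixel accuracy", {
  dn <- matrix(50L, 100, 100)
  dn[40:42, 60:62] <- 255L                 # 3x3 marker block
  img <- ortho_image(list(R = dn), gsd = 2, origin = c(0, 2))
  # block centre: row 41, col 61 -> world x = 60.5 * 0.02 = 1.21,
  # y = 2 - 40.5 * 0.02 = 1.19
  cp <- data.frame(id = 1, x = 1.21, y = 1.19)
  got <- measure_pairs(img, img, cp)
  expect_false(got$missing)
  expect_equal(got$ref_x, 1.21)
  expect_equal(got$ref_y, 1.19)
  # a point with no bright pixel nearby is reported missing, not an error
  far <- measure_pairs(img, img, data.frame(id = 2, x = 0.2, y = 1.8))
  expect_true(far$missing)
  expect_true(is.na(far$ref_x))
})
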