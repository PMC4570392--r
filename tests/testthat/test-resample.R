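test_that("halving a 4x4 raster keeps the documented pixel-centre choices", {
  img <- ortho_image(list(R = matrix(0:15, 4, 4, byrow = TRUE)), gsd = 1)
  out <- nn_resample(img, resample_spec(1, 2))
  expect_equal(dim(out), c(2L, 2L))
  expect_equal(out$bands$R, matrix(c(0L, 8L, 2L, 10L), 2, 2))
  expect_equal(out$gsd, 2)
})

test_that("nn_resample agrees bit-exactly with the striding oracle", {
  img <- tiny_image()
  for (k in c(2L, 3L, 5L)) {
    via_spec <- nn_resample(img, resample_spec(img$gsd, img$gsd * k))
    via_stride <- striding_oracle(img, k)
    expect_identical(via_spec$bands, via_stride$bands)
    expect_equal(via_spec$gsd, via_stride$gsd)
  }
})

test_that("nearest-neighbour source indices match a brute-force search", {
  # independent oracle: for each output centre, pick the argmin distance to
  # the source-pixel centres, breaking exact ties toward the smaller index
  brute <- function(n_out, factor, n_src) {
    vapply(seq_len(n_out), function(i) {
      d <- abs((i - 0.5) / factor - (seq_len(n_src) - 0.5))
      which(d == min(d))[1]
    }, 0L)
  }
  for (factor in c(1 / 3, 0.37, 1.6 / 3.25, 1.6 / 5.42, 0.99, 1)) {
    n_src <- 57L
    n_out <- floor(n_src * factor)
    expect_equal(uavweed:::nn_source_index(n_out, factor, n_src),
                 brute(n_out, factor, n_src),
                 info = paste("factor", factor))
  }
})

test_that("resampling never modifies digital numbers", {
  img <- tiny_image()
  out <- nn_resample(img, resample_spec(2, 5.42 / 1.6 * 2))
  for (b in band_names(img)) {
    tin <- table(img$bands[[b]])
    tout <- table(out$bands[[b]])
    expect_true(all(names(tout) %in% names(tin)))
    expect_true(all(tout <= tin[names(tout)]))
  }
})

test_that("identity, upsampling and degenerate resampling behave as specified", {
  img <- tiny_image()
  same <- nn_resample(img, resample_spec(2, 2))
  expect_identical(same$bands, img$bands)
  up <- nn_resample(img, resample_spec(2, 1))
  expect_equal(dim(up), 2L * dim(img))
  expect_true(up$meta$upsampled)
  expect_false(nn_resample(img, resample_spec(2, 4))$meta$upsampled)
  expect_error(nn_resample(img, resample_spec(1.9, 3.8)),
               "does not match")
  expect_error(nn_resample(img, resample_spec(2, 2000)), "empty")
  expect_error(striding_oracle(img, 2.5), "integer")
  expect_error(striding_oracle(img, 500), "empty")
})
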