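test_that("ortho_image validates band structure and digital numbers", {
  m <- matrix(0L, 3, 3)
  expect_s3_class(ortho_image(list(R = m), gsd = 1), "ortho_image")
  expect_error(ortho_image(list(m), gsd = 1), "named")
  expect_error(ortho_image(list(R = m, G = matrix(0L, 2, 3)), gsd = 1),
               "identical dimensions")
  expect_error(ortho_image(list(R = m + 256L), gsd = 1), "0, 255")
  expect_error(ortho_image(list(R = m - 1L), gsd = 1), "0, 255")
  expect_error(ortho_image(list(R = m + 0.5), gsd = 1), "integer")
  expect_error(ortho_image(list(R = m), gsd = 0), "gsd")
})

test_that("pixel-centre and world coordinates are mutually inverse", {
  img <- ortho_image(list(R = matrix(0L, 40, 60)), gsd = 2.5,
                     origin = c(3, 17))
  rc <- cbind(row = c(1, 7.25, 40), col = c(1, 33.5, 60))
  w <- uavweed:::px_center_world(img, rc[, "row"], rc[, "col"])
  back <- uavweed:::world_to_px(img, w[, "x"], w[, "y"])
  expect_equal(unname(back), unname(rc))
  # pixel (1,1) centre is half a pixel in from the origin corner
  expect_equal(unname(w[1, ]), c(3 + 0.0125, 17 - 0.0125))
})
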