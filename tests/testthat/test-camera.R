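test_that("preset cameras have the documented pixel pitches", {
  expect_equal(pixel_pitch(camera_preset("RGB")), 4.3)
  expect_equal(pixel_pitch(camera_preset("TTC")), 5.2)
})

test_that("GSD is altitude x pitch / focal length, linear in altitude", {
  cam <- camera_model("test", sensor_width = 10, sensor_height = 8,
                      image_width = 1000, image_height = 800,
                      focal_length = 10)
  # pitch 10 um -> at 50 m: 50 * 100 * 0.01 / 10 = 5 cm/px
  expect_equal(gsd(flight_spec(50, cam)), 5)
  g60 <- gsd(flight_spec(60, camera_preset("RGB")), round_to = Inf)
  g120 <- gsd(flight_spec(120, camera_preset("RGB")), round_to = Inf)
  expect_equal(g120, 2 * g60)
})

test_that("resample_spec factors are the source/target GSD ratio", {
  sp <- resample_spec(1.07, 3.07)
  expect_equal(sp$xfactor, 1.07 / 3.07)
  expect_equal(sp$yfactor, sp$xfactor)
  expect_lt(sp$xfactor, 1)                      # downsampling
  expect_gt(resample_spec(3.25, 1.6)$xfactor, 1)  # upsampling
  expect_equal(resample_spec(2, 2)$xfactor, 1)
})

test_that("invalid cameras, flights and resample specs are rejected", {
  expect_error(camera_model("bad", -1, 13, 4032, 3024, 14), "positive")
  expect_error(camera_model("bad", 4032, 13, 17.3, 3024, 14), "pitch")
  expect_error(flight_spec(0, camera_preset("RGB")), "positive")
  expect_error(flight_spec(-60, camera_preset("TTC")), "positive")
  expect_error(resample_spec(0, 3), "positive")
  expect_error(resample_spec(1.6, -3.25), "positive")
})
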