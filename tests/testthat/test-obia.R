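test_that("vegetation indices reproduce hand-computed values", {
  img <- ortho_image(list(R = matrix(c(100L, 0L), 1, 2),
                          NIR = matrix(c(200L, 0L), 1, 2)), gsd = 1)
  ndvi <- vegetation_index(img, "ndvi")
  expect_equal(ndvi[1, 1], 1 / 3)
  expect_equal(ndvi[1, 2], 0)      # zero denominator -> 0 by convention
  rgb <- ortho_image(list(R = matrix(c(50L, 0L), 1, 2),
                          G = matrix(c(100L, 0L), 1, 2),
                          B = matrix(c(50L, 0L), 1, 2)), gsd = 1)
  exg <- vegetation_index(rgb, "exg")
  expect_equal(exg[1, 1], 0.5)     # chromatic coords: (200-50-50)/200
  expect_equal(exg[1, 2], 0)
  # auto picks NDVI when a NIR band exists, ExG otherwise
  expect_equal(vegetation_index(img), ndvi)
  expect_equal(vegetation_index(rgb), exg)
  expect_error(vegetation_index(img, "exg"), "requires bands R, G and B")
  expect_error(vegetation_index(rgb, "ndvi"), "requires bands R and NIR")
})

test_that("component labelling is 8-connected", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- m[2, 2] <- TRUE       # down-right diagonal touch
  lab <- uavweed:::label_components(m)
  expect_equal(max(lab), 1L)
  m2 <- matrix(FALSE, 4, 4)
  m2[1, 2] <- m2[2, 1] <- TRUE     # down-left diagonal touch
  expect_equal(max(uavweed:::label_components(m2)), 1L)
  m3 <- matrix(FALSE, 4, 4)
  m3[1, 1] <- m3[3, 3] <- TRUE     # separated by a full pixel
  expect_equal(max(uavweed:::label_components(m3)), 2L)
})

test_that("segmentation drops objects below the minimum area", {
  idx <- matrix(0, 30, 30)
  idx[5:8, 5:8] <- 1               # 16-px object
  idx[20, 20:21] <- 1              # 2-px object
  seg <- segment_vegetation(idx, gsd = 2, min_object_area = 4,
                            index_type = "ndvi")
  expect_equal(nrow(seg$objects), 1)
  expect_equal(seg$objects$area_px, 16L)
  expect_equal(sum(seg$mask), 16)
  expect_equal(seg$objects$area_m2, 16 * 0.02^2)
})

test_that("a unimodal index falls back to the fixed threshold with a warning", {
  idx <- matrix(0.5, 40, 40)
  idx[1, 1] <- 0.5001
  expect_warning(seg <- segment_vegetation(idx, gsd = 2, index_type = "ndvi"),
                 "degenerate")
  expect_equal(seg$threshold_method, "fixed-fallback")
  expect_equal(seg$threshold, 0.2)
})

test_that("row detection recovers a constructed periodic stripe pattern", {
  nr <- 400; nc <- 400                      # 2 cm/px, 8 x 8 m
  mask <- matrix(FALSE, nr, nc)
  mask[, which(((seq_len(nc) - 1) %% 35) < 5)] <- TRUE  # 0.7 m period
  rm_ <- detect_crop_rows(mask, gsd = 2)
  expect_equal(rm_$orientation, 90)          # stripes of constant x
  expect_lt(abs(rm_$spacing - 0.7) / 0.7, 0.05)
  expect_equal(diff(rm_$offsets),
               rep(rm_$spacing, length(rm_$offsets) - 1))
})

test_that("an aperiodic vegetation mask makes row detection fail loudly", {
  set.seed(7)
  mask <- matrix(runif(500 * 500) < 0.15, 500, 500)
  expect_error(detect_crop_rows(mask, gsd = 2), "row detection failed")
  expect_error(detect_crop_rows(matrix(FALSE, 10, 10), gsd = 2), "empty")
})

test_that("objects are crop on a row centreline and weed between rows", {
  row_model <- structure(list(orientation = 0, spacing = 0.7, phase = 0.35,
                              offsets = c(0.35, 1.05, 1.75),
                              row_halfwidth = 0.15,
                              peak = c(value = 1, baseline = 0)),
                         class = "row_model")
  lab <- matrix(0L, 100, 100)               # 2 cm/px, 2 x 2 m, origin (0, 2)
  lab[82:84, 10:14] <- 1L                   # centroid y ~ 0.35: on a row
  lab[66:68, 50:54] <- 2L                   # centroid y ~ 0.67: inter-row
  idx <- (lab > 0L) * 0.8
  seg <- list(labels = lab, objects = uavweed:::summarise_objects(
    lab, idx, gsd = 2, origin = c(0, 2)))
  map <- classify_objects(seg, row_model, gsd = 2, origin = c(0, 2))
  expect_true(all(map$classes[82:84, 10:14] == 1L))   # crop
  expect_true(all(map$classes[66:68, 50:54] == 2L))   # weed
  expect_true(all(map$classes[lab == 0L] == 0L))      # soil untouched
})

test_that("the full OBIA run maps the default scene close to ground truth", {
  pm <- paired_maps()
  s <- default_scene()
  expect_s3_class(pm$map_uav, "classified_map")
  expect_true(all(pm$map_uav$classes %in% 0:2))
  expect_equal(pm$map_uav$provenance$index, "ndvi")
  met <- classification_metrics(pm$map_uav, s$truth)
  expect_gt(met$accuracy, 0.97)
  expect_gt(met$vegetation_accuracy, 0.97)
  expect_gt(met$recall, 0.9)
  expect_gt(met$precision, 0.9)
})
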