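test_that("a perfectly uniform image collapses to a single segment", {
  segs <- segment_scene(matrix(0.5, 12, 9), scale = 0.001, w_color = 1)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_px, 108)
  expect_equal(segs$area_m2, 108)  # pixel_size defaults to 1 for raw matrices
})

test_that("segmentation always partitions the raster", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      img <- array(runif(18 * 15 * 2), c(18, 15, 2))
      for (scale in c(0.5, 5, 50)) {
        segs <- segment_scene(img, scale = scale, w_color = 0.7)
        lab <- attr(segs, "label_matrix")
        expect_equal(dim(lab), c(18, 15))
        expect_true(all(lab >= 1))
        expect_equal(sum(segs$n_px), 18 * 15)           # pixel conservation
        expect_equal(sort(unique(as.vector(lab))), segs$segment_id)
        # segments are 4-connected
        for (id in segs$segment_id) {
          cc <- flood_fill_cc(lab == id)
          expect_equal(max(cc), 1)
        }
      }
    }
  })
})

test_that("segment count is non-increasing in the scale parameter", {
  withr::with_seed(17, img <- matrix(runif(20 * 20), 20, 20))
  n_segs <- vapply(c(0.1, 0.5, 1, 2, 5, 20, 100),
                   function(s) nrow(segment_scene(img, scale = s, w_color = 0.8)),
                   numeric(1))
  expect_true(all(diff(n_segs) <= 0))
})

test_that("segmentation matches the brute-force merge oracle exactly", {
  # band values restricted to {0, 1} so that both routes' floating-point
  # arithmetic is exact and merge orders must coincide
  two_halves <- cbind(matrix(0, 6, 3), matrix(1, 6, 3))
  for (w in c(1, 0.8)) {
    got <- attr(segment_scene(two_halves, scale = 2, w_color = w), "label_matrix")
    want <- oracle_segment(two_halves, scale = 2, w_color = w)
    expect_identical(got, want)
  }
  expect_equal(max(oracle_segment(two_halves, scale = 2, w_color = 1)), 2)

  withr::with_seed(13, {
    for (rep in 1:4) {
      img <- matrix(sample(c(0, 1), 36, replace = TRUE), 6, 6)
      for (scale in c(0.3, 1.5)) {
        got <- attr(segment_scene(img, scale = scale, w_color = 0.8),
                    "label_matrix")
        expect_identical(got, oracle_segment(img, scale = scale, w_color = 0.8))
      }
    }
  })
})

test_that("segment features agree with direct recomputation", {
  withr::with_seed(23, img <- array(runif(10 * 10 * 3), c(10, 10, 3)))
  segs <- segment_scene(img, scale = 3, w_color = 0.8, pixel_size = 0.1)
  lab <- attr(segs, "label_matrix")
  id <- segs$segment_id[which.max(segs$n_px)]
  sel <- lab == id
  row <- segs[segs$segment_id == id, ]
  expect_equal(row$n_px, sum(sel))
  expect_equal(row$area_m2, sum(sel) * 0.01)
  expect_equal(row$mean_b2, mean(img[, , 2][sel]))
  # population sd, recomputed directly
  v <- img[, , 3][sel]
  expect_equal(row$sd_b3, sqrt(mean(v^2) - mean(v)^2), tolerance = 1e-12)
  expect_equal(row$compactness, row$perimeter_px / (4 * sqrt(row$n_px)))
  expect_gte(row$smoothness, 1 - 1e-12)  # perimeter >= bounding box perimeter
  expect_error(segment_scene(img, scale = 0), class = "rheosense_config_error")
})
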