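test_that("NDVI arithmetic matches the definition and handles 0/0 pixels", {
  s <- ms_scene(red_band = matrix(c(0.1, 0.3, 0.0, 0.0), 2, 2),
                nir_band = matrix(c(0.5, 0.3, 0.0, 0.4), 2, 2))
  nd <- compute_ndvi(s)
  expect_equal(nd$values[1, 1], (0.5 - 0.1) / (0.5 + 0.1))  # 0.6667
  expect_equal(nd$values[2, 1], 0)                          # NIR = R symmetry
  expect_true(is.na(nd$values[1, 2]))                       # 0/0 undefined
  expect_true(nd$undefined_mask[1, 2])
  expect_equal(nd$values[2, 2], 1)                          # R = 0, NIR > 0
})

test_that("defined NDVI values are bounded in [-1, 1] for any nonnegative bands", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      red <- matrix(rexp(100, 5), 10, 10)
      nir <- matrix(rexp(100, 5), 10, 10)
      v <- compute_ndvi(ms_scene(red, nir))$values
      expect_true(all(v >= -1 & v <= 1, na.rm = TRUE))
    }
  })
})

test_that("band shape mismatch is a structural error", {
  expect_error(ms_scene(matrix(0.1, 2, 2), matrix(0.1, 2, 3)),
               class = "rheosense_structure_error")
})

test_that("vegetation classification is strict at both thresholds", {
  v <- matrix(c(0.05, 0.1, 0.1 + 1e-12, 0.5, 1 - 1e-12, 1), 1)
  cls <- classify_vegetation(v)
  expect_equal(as.vector(cls$mask), c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(cls$n_veg, 3)
  expect_equal(cls$n_nonveg, 3)
  expect_error(classify_vegetation(v, lower = 1, upper = 0.1),
               class = "rheosense_config_error")
})

test_that("all-low NDVI yields zero vegetation and counts conserve", {
  cls <- classify_vegetation(matrix(0.05, 4, 5))
  expect_equal(cls$n_veg, 0)
  expect_equal(cls$n_nonveg, 20)
})

test_that("undefined pixels count as nonvegetation; nodata pixels are excluded", {
  red <- matrix(0.1, 4, 4); nir <- matrix(0.5, 4, 4)
  red[1, 1] <- nir[1, 1] <- 0              # undefined pixel
  nodata <- matrix(FALSE, 4, 4); nodata[4, 4] <- TRUE
  cls <- classify_vegetation(compute_ndvi(ms_scene(red, nir, nodata_mask = nodata)))
  expect_equal(cls$n_veg + cls$n_nonveg, 15)  # nodata excluded
  expect_equal(cls$n_nonveg, 1)               # the undefined pixel
})

test_that("raising the lower threshold never increases the vegetation count", {
  withr::with_seed(7, v <- matrix(runif(400, -0.5, 1.2), 20, 20))
  counts <- vapply(seq(-0.2, 0.9, by = 0.1),
                   function(lo) classify_vegetation(v, lower = lo, upper = 1.5)$n_veg,
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("vegetation ratio reproduces the printed scene accounting", {
  r <- vegetation_ratio(305676, 189658)
  expect_equal(r$pct_rounded, 62)
  expect_equal(r$pct, 100 * 305676 / 495334, tolerance = 1e-12)
  expect_equal(round(r$pct, 2), 61.71)
  expect_equal(vegetation_ratio(0, 10)$pct, 0)
  expect_equal(vegetation_ratio(10, 0)$pct, 100)
  expect_error(vegetation_ratio(0, 0), class = "rheosense_undefined_ratio")
})

test_that("area accounting reproduces the reported chain and the direct value", {
  a <- area_summary(305676, 189658, pixel_size = 30)
  expect_equal(a$M_km2_reported, 445)
  expect_equal(a$M1_km2_reported, 276)
  expect_equal(a$M1_km2_direct, 305676 * 900 / 1e6)  # 275.1084
  expect_equal(round(a$M1_km2_direct, 1), 275.1)
  expect_equal(a$M_km2, 495334 * 900 / 1e6)
  z <- area_summary(0, 0, pixel_size = 30)
  expect_equal(z$M_km2, 0)
  expect_equal(z$M1_km2_reported, 0)
  expect_s3_class(tidy(a), "tbl_df")
})

test_that("noise-free simulated scenes recover the configured fraction exactly", {
  cfg <- satellite_sim_config(width = 100, height = 100, veg_fraction = 0.62,
                              ndvi_noise_sd = 0, seed = 5)
  sim <- simulate_satellite(cfg)
  cls <- classify_vegetation(compute_ndvi(sim$scene))
  expect_equal(vegetation_ratio(cls)$pct, 62)
  expect_equal(cls$mask, sim$truth$veg_mask)
})
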