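test_that("effective amount is the unit-consistent product S x rho", {
  expect_equal(effective_amount(1, 1), 1e4)   # 1 km2 at 1 per 100 m2
  expect_equal(effective_amount(276, 0), 0)
  # density back-derived from the bundled effective count: oracle by division
  rho <- 350000 / (276 * 1e4)
  expect_equal(effective_amount(276, rho), 350000)
  # bilinear in both arguments
  expect_equal(effective_amount(2 * 276, rho), 2 * effective_amount(276, rho))
  expect_equal(effective_amount(276, 3 * rho), 3 * effective_amount(276, rho))
})

test_that("structure ratio brackets the integer percent interval", {
  r <- structure_ratio(35e4, 718e4)
  expect_equal(r$pct, 100 * 35 / 718)
  expect_equal(round(r$pct, 2), 4.87)
  expect_equal(r$quota_lo, 4)
  expect_equal(r$quota_hi, 5)
  expect_equal(structure_ratio(10, 10)$pct, 100)
  expect_equal(structure_ratio(0, 10)$pct, 0)
  expect_error(structure_ratio(1, 0), class = "rheosense_undefined_ratio")
})

test_that("the combined assessment reproduces the bundled campaign numbers", {
  tab <- load_survey(survey_fixture_path())
  area <- area_summary(305676, 189658, pixel_size = 30)
  a <- assess(area, survey_density(tab, 2008), effective_count = 350000)
  expect_equal(a$veg_area_km2, 276)
  expect_equal(a$effective_1e4, 35)
  expect_equal(a$future_1e4, 718)
  expect_equal(a$safe_quota, c(lo = 4, hi = 5))
  expect_true(a$structure_ratio_pct > 4 && a$structure_ratio_pct < 5)
  td <- tidy(a)
  expect_equal(td$future_count, 7176000)
  expect_equal(td$safe_quota_hi, 5)
})

test_that("assessment is invariant to the area unit representation", {
  viaKm <- assess(276, 2.6, rho = 0.12, area_unit = "km2")
  viaHa <- assess(27600, 2.6, rho = 0.12, area_unit = "ha")
  viaM2 <- assess(276e6, 2.6, rho = 0.12, area_unit = "m2")
  expect_equal(tidy(viaKm), tidy(viaHa))
  expect_equal(tidy(viaKm), tidy(viaM2))
})

test_that("degenerate assessments are flagged, not silently wrong", {
  z <- assess(0, 0, effective_count = 0)
  expect_equal(z$effective_count, 0)
  expect_equal(z$future_count, 0)
  expect_true(is.na(z$structure_ratio_pct))
  expect_error(assess(276, 2.6), class = "rheosense_config_error")
})

test_that("end-to-end synthetic run recovers the configured intensities", {
  # small full-chain run: satellite fraction, aerial density, survey intensity
  sat <- simulate_satellite(satellite_sim_config(width = 60, height = 60,
                                                 veg_fraction = 0.5,
                                                 ndvi_noise_sd = 0, seed = 6))
  area <- area_summary(classify_vegetation(compute_ndvi(sat$scene)))
  expect_equal(area$P, 0.5)

  counts <- vapply(1:25, function(s) {
    cfg <- aerial_sim_config(footprint_w = 12, footprint_h = 12,
                             plant_intensity = 0.03, seed = 200 + s)
    nrow(simulate_aerial(cfg, render = FALSE)$truth$plants)
  }, numeric(1))
  rho <- estimate_density(counts, rep(144, 25), n_boot = 0)
  expect_lt(abs(rho$rho_per_100m2 - 3), 3 * sqrt(3 / (25 * 1.44)))

  rec <- simulate_survey(survey_sim_config(intensity = 2.6, seed = 7))
  sd08 <- survey_density(rec, 2008)
  a <- assess(area$M1_km2_direct, sd08, rho = rho)
  expect_equal(a$effective_count,
               area$M1_km2_direct * 1e4 * rho$rho_per_100m2)
  expect_equal(a$future_count, sd08$density_1dp * area$M1_km2_direct * 1e4)
})
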