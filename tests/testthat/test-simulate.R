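test_that("satellite generator is seed-deterministic and conserves the truth count", {
  cfg <- satellite_sim_config(width = 40, height = 30, veg_fraction = 0.37, seed = 11)
  a <- simulate_satellite(cfg)
  b <- simulate_satellite(cfg)
  expect_identical(a$scene$red_band, b$scene$red_band)
  expect_identical(a$truth$veg_mask, b$truth$veg_mask)
  expect_equal(sum(a$truth$veg_mask), round(0.37 * 40 * 30))

  empty <- simulate_satellite(satellite_sim_config(width = 10, height = 10,
                                                   veg_fraction = 0, seed = 2))
  expect_false(any(empty$truth$veg_mask))
})

test_that("class means near the threshold trigger a warning, invalid means an error", {
  expect_warning(
    simulate_satellite(satellite_sim_config(width = 5, height = 5,
                                            veg_ndvi_mean = 0.2,
                                            ndvi_noise_sd = 0.05, seed = 1)),
    class = "rheosense_threshold_overlap_warning")
  expect_error(satellite_sim_config(veg_ndvi_mean = 0.05),
               class = "rheosense_config_error")
  expect_error(satellite_sim_config(veg_fraction = 1.2),
               class = "rheosense_config_error")
})

test_that("noisy satellite scenes recover the fraction within the Gaussian-tail bound", {
  # nonveg mean -0.1, noise 0.05: crossing the 0.1 threshold is a 4 sd event,
  # so the recovered ratio stays within 2 percentage points of the truth
  cfg <- satellite_sim_config(width = 100, height = 100, veg_fraction = 0.5,
                              ndvi_noise_sd = 0.05, seed = 1)
  sim <- simulate_satellite(cfg)
  cls <- classify_vegetation(compute_ndvi(sim$scene))
  expect_lt(abs(vegetation_ratio(cls)$pct - 50), 2)
})

test_that("aerial generator: zero intensity, forced plants and truth bookkeeping", {
  cfg0 <- aerial_sim_config(footprint_w = 5, footprint_h = 5,
                            plant_intensity = 0, noise_sd = 0, seed = 9)
  sim0 <- simulate_aerial(cfg0)
  expect_equal(nrow(sim0$truth$plants), 0)
  expect_false(any(sim0$truth$mask))
  expect_equal(length(unique(as.vector(sim0$scene$bands[, , 1]))), 1)  # uniform bg

  cfg1 <- aerial_sim_config(footprint_w = 10, footprint_h = 10, noise_sd = 0, seed = 4)
  sim1 <- simulate_aerial(cfg1, plants = data.frame(x = 5, y = 5, area_m2 = 1.5))
  expect_equal(nrow(sim1$truth$plants), 1)
  # rasterised pixel count approximates the analytic area (1.5 m2 = 150 px)
  expect_lt(abs(sim1$truth$plants$raster_area_px - 150), 10)
  expect_equal(sum(sim1$truth$mask), sim1$truth$plants$raster_area_px)
})

test_that("aerial plant counts are Poisson with mean intensity x footprint", {
  lambda_a <- 0.05 * 10 * 10  # 5 expected plants per image
  counts <- vapply(1:200, function(s) {
    cfg <- aerial_sim_config(footprint_w = 10, footprint_h = 10,
                             plant_intensity = 0.05, seed = s)
    nrow(simulate_aerial(cfg, render = FALSE)$truth$plants)
  }, numeric(1))
  expect_lt(abs(mean(counts) - lambda_a), 3 * sqrt(lambda_a / 200))
})

test_that("aerial canopies never overlap and packing failures are reported", {
  cfg <- aerial_sim_config(footprint_w = 15, footprint_h = 15,
                           plant_intensity = 0.04, noise_sd = 0, seed = 21)
  sim <- simulate_aerial(cfg)
  # disjoint ellipses: mask pixel count equals the sum of per-plant counts
  expect_equal(sum(sim$truth$mask), sum(sim$truth$plants$raster_area_px))
  expect_error(
    simulate_aerial(aerial_sim_config(footprint_w = 6, footprint_h = 6,
                                      plant_intensity = 3, seed = 1),
                    render = FALSE),
    class = "rheosense_packing_error")
})

test_that("survey generator matches the study layout and Poisson moments", {
  cfg <- survey_sim_config(seed = 3)
  rec <- simulate_survey(cfg)
  expect_equal(nrow(rec), 10 * 4 * 3)
  expect_equal(sum(rec$year == 2008), 40)
  expect_equal(unique(rec$fence_w_m[rec$fence_id == "III"]), 150)
  expect_identical(rec, simulate_survey(cfg))  # seed determinism

  zero <- simulate_survey(survey_sim_config(intensity = 0, seed = 8))
  expect_true(all(zero$count == 0))

  # unbiasedness: mean pooled density over 500 replicates approaches 2.6
  ests <- vapply(1:500, function(s) {
    r <- simulate_survey(survey_sim_config(intensity = 2.6, years = 2008, seed = s))
    survey_density(r, 2008)$density_per_100m2
  }, numeric(1))
  mc_se <- sd(ests) / sqrt(500)
  expect_lt(abs(mean(ests) - 2.6), 3 * mc_se)
})
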