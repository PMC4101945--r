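test_that("the bundled campaign table loads and validates", {
  tab <- load_survey(survey_fixture_path())
  expect_equal(nrow(tab), 120)  # 10 fences x 4 quadrats x 3 years
  expect_equal(sum(tab$year == 2008), 40)
  fences <- attr(tab, "fences")
  expect_equal(nrow(fences), 10)
  expect_equal(fences$fence_w_m[fences$fence_id == "III"], 150)
  expect_true(all(fences$fence_w_m[fences$fence_id != "III"] == 200))
})

test_that("malformed survey files are rejected with row diagnostics", {
  write_tmp <- function(df) {
    f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
    utils::write.csv(df, f, row.names = FALSE)
    f
  }
  base <- utils::read.csv(survey_fixture_path())
  empty <- base[0, ]
  expect_error(load_survey(write_tmp(empty)), class = "rheosense_validation_error")

  frac <- base; frac$count[3] <- 2.5
  expect_error(load_survey(write_tmp(frac)), "bad rows: 3",
               class = "rheosense_validation_error")

  neg <- base; neg$count[5] <- -1
  expect_error(load_survey(write_tmp(neg)), class = "rheosense_validation_error")

  nocol <- base; nocol$count <- NULL
  expect_error(load_survey(write_tmp(nocol)), "missing columns",
               class = "rheosense_validation_error")

  baddim <- base; baddim$fence_w_m[1] <- 190  # fence I in two geometries
  expect_error(load_survey(write_tmp(baddim)), class = "rheosense_validation_error")
})

test_that("pooled densities reproduce the three campaign years", {
  tab <- load_survey(survey_fixture_path())
  d <- survey_density(tab)
  expect_equal(d$total_count, c(104, 152, 122))
  expect_equal(d$n_quadrats, c(40, 40, 40))
  expect_equal(d$density_per_100m2, c(2.6, 3.8, 3.05))
  expect_equal(d$density_1dp, c(2.6, 3.8, 3.1))  # 3.05 rounds half-up
  expect_error(survey_density(tab, 1999), class = "rheosense_validation_error")
})

test_that("pooled density equals the mean per-quadrat count", {
  tab <- load_survey(survey_fixture_path())
  for (y in c(2008, 2010, 2011)) {
    d <- survey_density(tab, y)
    expect_equal(d$density_per_100m2, mean(tab$count[tab$year == y]))
  }
})

test_that("per-fence extrapolation reproduces the 2010 headline figures", {
  tab <- load_survey(survey_fixture_path())
  d2010 <- survey_density(tab, 2010)
  expect_equal(fence_abundance(d2010, 200, 200), 1520)
  expect_equal(fence_abundance(d2010, 150, 150), 855)
  expect_equal(fence_abundance(0, 200, 200), 0)
  ft <- fence_table(tab, 2011)
  # fence II 2011: 3 plants over 4 quadrats -> 0.75/100 m2 -> 300 a fence
  expect_equal(ft$abundance_fence_specific[ft$fence_id == "II"], 300)
})

test_that("pasture totals follow density x vegetation area, rounded to 1e4", {
  tab <- load_survey(survey_fixture_path())
  expect_equal(total_resource(survey_density(tab, 2008), 276)$total_1e4, 718)
  expect_equal(total_resource(survey_density(tab, 2010), 276)$total_1e4, 1049)
  expect_equal(total_resource(survey_density(tab, 2011), 276)$total_1e4, 856)
  expect_equal(total_resource(survey_density(tab, 2008), 276)$total, 7176000)
  # linear in both arguments
  expect_equal(total_resource(5.2, 276)$total,
               2 * total_resource(2.6, 276)$total)
  expect_equal(total_resource(2.6, 552)$total,
               2 * total_resource(2.6, 276)$total)
})
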