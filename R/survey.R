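#' Load a fence/quadrat survey table
#'
#' Reads and validates a survey CSV with one row per (fence, quadrat, year)
#' count.  Required columns: `fence_id`, `fence_w_m`, `fence_h_m`,
#' `quadrat_id`, `year`, `count`; `quadrat_side_m` is optional (default
#' 10 m).  Counts must be nonnegative integers; inconsistent fence
#' dimensions or malformed rows raise a validation error naming the rows.
#' The bundled fixture (`system.file("extdata", "survey_counts.csv",
#' package = "rheosense")`) holds the three-year, ten-fence rhubarb
#' monitoring campaign that the worked examples reproduce.
#'
#' @param path CSV file path.
#' @return a `survey_records` tibble; the per-fence geometry is attached as
#'   `attr(, "fences")` (tibble `fence_id`, `fence_w_m`, `fence_h_m`).
#' @export
load_survey <- function(path) {
  if (!file.exists(path)) abort_validation(paste("no such file:", path))
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) abort_validation(paste("cannot parse CSV:",
                                                            conditionMessage(e))))
  if (nrow(df) == 0) abort_validation("survey file contains no records")
  required <- c("fence_id", "fence_w_m", "fence_h_m", "quadrat_id", "year", "count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    abort_validation(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (is.null(df$quadrat_side_m)) df$quadrat_side_m <- 10
  df <- as_tibble(df)
  validate_survey(df)
}

validate_survey <- function(df) {
  bad <- which(!is.finite(df$count) | df$count < 0 | df$count != floor(df$count))
  if (length(bad) > 0)
    abort_validation(paste("counts must be nonnegative integers; bad rows:",
                           paste(head(bad, 10), collapse = ", ")))
  bad_dim <- which(!is.finite(df$fence_w_m) | df$fence_w_m <= 0 |
                   !is.finite(df$fence_h_m) | df$fence_h_m <= 0)
  if (length(bad_dim) > 0)
    abort_validation(paste("fence dimensions must be positive; bad rows:",
                           paste(head(bad_dim, 10), collapse = ", ")))
  dims <- unique(df[c("fence_id", "fence_w_m", "fence_h_m")])
  if (anyDuplicated(dims$fence_id))
    abort_validation("a fence_id appears with conflicting dimensions")
  df$count <- as.integer(df$count)
  attr(df, "fences") <- dims
  if (!inherits(df, "survey_records")) class(df) <- c("survey_records", class(df))
  df
}

#' Survey density per 100 m-squared
#'
#' Pools all quadrats of a year with equal weight:
#' `density = sum(counts) / n_quadrats` plants per 100 m-squared (quadrats
#' are 10 m x 10 m, so this equals the mean per-quadrat count).  The
#' reported figure `density_1dp` rounds half-up to one decimal; downstream
#' extrapolations use the rounded figure, matching standard field-report
#' arithmetic.
#'
#' @param records a `survey_records` tibble ([load_survey()],
#'   [simulate_survey()] or any tibble with `year`, `count`,
#'   `quadrat_side_m`).
#' @param year survey year(s) to summarise; `NULL` (default) for all years.
#' @return a `survey_density` tibble: one row per year with `n_quadrats`,
#'   `total_count`, `density_per_100m2` (full precision) and `density_1dp`.
#' @examples
#' tab <- load_survey(system.file("extdata", "survey_counts.csv",
#'                                package = "rheosense"))
#' survey_density(tab, 2008)$density_per_100m2  # 2.6
#' @export
survey_density <- function(records, year = NULL) {
  if (!is.null(year)) {
    records <- records[records$year %in% year, , drop = FALSE]
    if (nrow(records) == 0)
      abort_validation(paste("no survey records for year",
                             paste(year, collapse = ", ")))
  }
  side <- records$quadrat_side_m %||% rep(10, nrow(records))
  qa <- unique(side)
  if (length(qa) != 1)
    abort_validation("mixed quadrat sizes: pooled density would be ill-defined")
  scale <- qa^2 / 100  # quadrat area in 100 m2 units
  out <- records |>
    dplyr::group_by(year = .data$year) |>
    dplyr::summarise(n_quadrats = dplyr::n(),
                     total_count = sum(.data$count), .groups = "drop") |>
    dplyr::mutate(density_per_100m2 = .data$total_count / (.data$n_quadrats * scale),
                  density_1dp = round_half_up(.data$density_per_100m2, 1))
  class(out) <- c("survey_density", class(out))
  out
}

density_1dp_of <- function(density) {
  if (inherits(density, "survey_density") || is.data.frame(density)) {
    if (nrow(density) != 1)
      abort_config("supply a single-year density (or a plain number)")
    density$density_1dp
  } else {
    check_number(density, "density", lower = 0)
    density
  }
}

#' Extrapolate density to a whole fence
#'
#' `plants per fence = density_1dp x fence area / 100 m-squared`, e.g. 3.8
#' per 100 m-squared over a 200 m x 200 m fence gives 1,520 plants (855 for
#' a 150 m x 150 m fence).
#'
#' @param density a one-row `survey_density` or a plain per-100-m-squared
#'   density (the one-decimal reported value).
#' @param fence_w,fence_h fence dimensions in metres (vectorised).
#' @return numeric vector of plants per fence.
#' @export
fence_abundance <- function(density, fence_w = 200, fence_h = 200) {
  d <- density_1dp_of(density)
  if (any(fence_w <= 0) || any(fence_h <= 0))
    abort_config("fence dimensions must be positive")
  d * fence_w * fence_h / 100
}

#' Per-fence abundance table
#'
#' Reports, for each fence, the fence-specific density (that fence's
#' quadrats only) and abundance, together with the pooled-density
#' extrapolation used for the headline per-fence figures.
#'
#' @inheritParams survey_density
#' @param year single survey year.
#' @return tibble with one row per fence: `fence_id`, dimensions, quadrat
#'   count, fence-specific `density_1dp` and `abundance_fence_specific`,
#'   and `abundance_pooled`.
#' @export
fence_table <- function(records, year) {
  pooled <- survey_density(records, year)
  records <- records[records$year == year, , drop = FALSE]
  records |>
    dplyr::group_by(fence_id = .data$fence_id,
                    fence_w_m = .data$fence_w_m,
                    fence_h_m = .data$fence_h_m) |>
    dplyr::summarise(n_quadrats = dplyr::n(),
                     total_count = sum(.data$count), .groups = "drop") |>
    dplyr::mutate(
      density_per_100m2 = .data$total_count / .data$n_quadrats,
      density_1dp = round_half_up(.data$density_per_100m2, 1),
      # fence-specific extrapolation keeps the exact fence density (rounding
      # to one decimal is a reporting convention of the pooled chain only)
      abundance_fence_specific = .data$density_per_100m2 * .data$fence_w_m *
        .data$fence_h_m / 100,
      abundance_pooled = fence_abundance(pooled$density_1dp,
                                         .data$fence_w_m, .data$fence_h_m))
}

#' Pasture-wide total from the ground survey
#'
#' Extrapolates a quadrat density over the satellite-derived vegetation
#' area: `total = density_1dp x vegetation area / 100 m-squared`.  With
#' density 2.6 per 100 m-squared and 276 km-squared of vegetation this is
#' 7,176,000 plants, reported as 718 (in units of 10^4).
#'
#' @inheritParams fence_abundance
#' @param veg_area_km2 vegetation area in km-squared.
#' @return list with `total` (plants, full precision) and `total_1e4`
#'   (rounded to the nearest 10^4 and expressed in 10^4 units).
#' @export
total_resource <- function(density, veg_area_km2) {
  d <- density_1dp_of(density)
  check_number(veg_area_km2, "veg_area_km2", lower = 0)
  total <- d * veg_area_km2 * 1e4  # 1 km2 = 1e4 x (100 m2)
  list(total = total, total_1e4 = round_half_up(d * veg_area_km2))
}
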