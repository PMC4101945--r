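#' Effective resource amount M = S * rho
#'
#' The imagery-based stock of aerially interpretable plants: vegetation area
#' `S` (satellite) times the density `rho` of plants with canopies above the
#' minimum mapping unit (aerial detection).
#'
#' @param veg_area_km2 vegetation area S in km-squared (see `area_unit` of
#'   [assess()] for other units).
#' @param rho density per 100 m-squared, or a [estimate_density()] object.
#' @return number of plants (full precision; [assess()] reports it rounded
#'   to the nearest 10^4).
#' @examples
#' effective_amount(276, 0.126811)  # ~350,000
#' @export
effective_amount <- function(veg_area_km2, rho) {
  if (inherits(rho, "density_estimate")) rho <- rho$rho_per_100m2
  check_number(veg_area_km2, "veg_area_km2", lower = 0)
  check_number(rho, "rho", lower = 0)
  veg_area_km2 * 1e4 * rho  # 1 km2 = 1e4 x (100 m2)
}

#' Population-structure ratio and harvest bracket
#'
#' The effective (imagery-detectable, currently harvestable) stock as a
#' percentage of the future (all-sizes, ground-survey) stock.  Reported at
#' full precision together with the integer percent bracket
#' `[floor, ceiling]` used as the sustainable-harvest quota (e.g. 4.87
#' percent reads as "4 to 5 percent").
#'
#' @param effective,future plant counts.
#' @return list with `pct`, `quota_lo`, `quota_hi`.
#' @export
structure_ratio <- function(effective, future) {
  check_number(effective, "effective", lower = 0)
  if (!is.numeric(future) || length(future) != 1 || !is.finite(future) || future <= 0)
    abort("structure ratio undefined: future amount must be positive",
          class = "rheosense_undefined_ratio")
  pct <- 100 * effective / future
  list(pct = pct,
       quota_lo = max(floor(pct), 0),
       quota_hi = min(ceiling(pct), 100))
}

#' Combined multilevel resource assessment
#'
#' Wires the three observation levels together: the satellite vegetation
#' area S, the aerial density rho (or a directly supplied effective count,
#' for value-file runs without imagery), and the ground-survey density.
#' Outputs the effective amount `M = S * rho`, the survey-based future
#' amount, the population-structure ratio and its integer percent bracket
#' (the safe-harvest quota), with a provenance trail of every input and
#' rounding step.
#'
#' @param area an [area_summary()], or a plain vegetation area (then
#'   interpreted in `area_unit`).
#' @param survey a one-row [survey_density()] or plain density per 100
#'   m-squared.
#' @param rho aerial density per 100 m-squared or [estimate_density()]
#'   object; alternatively give `effective_count` directly.
#' @param effective_count effective plant count, used when no aerial
#'   density is available.
#' @param area_unit unit of a plain-number `area` (`"km2"`, `"ha"` or
#'   `"m2"`); everything is normalised to km-squared internally, so the
#'   assessment is invariant to the representation.
#' @return a `resource_assessment` object.
#' @examples
#' assess(area = 276, survey = 2.6, effective_count = 35e4)
#' @export
assess <- function(area, survey, rho = NULL, effective_count = NULL,
                   area_unit = c("km2", "ha", "m2")) {
  area_unit <- match.arg(area_unit)
  if (inherits(area, "area_summary")) {
    veg_km2 <- area$M1_km2_reported
    area_src <- "area_summary (reported M1)"
  } else {
    check_number(area, "area", lower = 0)
    veg_km2 <- area / switch(area_unit, km2 = 1, ha = 100, m2 = 1e6)
    area_src <- paste("plain value in", area_unit)
  }
  if (is.null(rho) && is.null(effective_count))
    abort_config("supply either `rho` or `effective_count`")
  if (!is.null(rho)) {
    if (inherits(rho, "density_estimate")) rho <- rho$rho_per_100m2
    effective <- effective_amount(veg_km2, rho)
    eff_src <- sprintf("S (%g km2) x rho (%g per 100 m2)", veg_km2, rho)
  } else {
    check_number(effective_count, "effective_count", lower = 0)
    effective <- effective_count
    rho <- if (veg_km2 > 0) effective / (veg_km2 * 1e4) else NA_real_
    eff_src <- "supplied effective count"
  }
  d1 <- density_1dp_of(survey)
  fut <- total_resource(d1, veg_km2)
  ratio <- if (fut$total > 0) structure_ratio(effective, fut$total) else
    list(pct = NA_real_, quota_lo = NA_real_, quota_hi = NA_real_)
  structure(list(
    veg_area_km2 = veg_km2,
    rho_per_100m2 = rho,
    survey_density_1dp = d1,
    effective_count = effective,
    effective_1e4 = round_half_up(effective / 1e4),
    future_count = fut$total,
    future_1e4 = fut$total_1e4,
    structure_ratio_pct = ratio$pct,
    safe_quota = c(lo = ratio$quota_lo, hi = ratio$quota_hi),
    provenance = list(
      area = area_src,
      effective = eff_src,
      future = sprintf("survey density %.1f per 100 m2 x %g km2, total rounded to nearest 1e4",
                       d1, veg_km2),
      quota = "integer percent bracket [floor, ceiling] of the exact ratio")),
    class = "resource_assessment")
}

#' @export
print.resource_assessment <- function(x, ...) {
  cat("<resource_assessment>\n")
  cat(sprintf("  vegetation area S:  %g km2\n", x$veg_area_km2))
  cat(sprintf("  effective amount:   %g (%g x 10^4), rho = %.4g per 100 m2\n",
              x$effective_count, x$effective_1e4, x$rho_per_100m2))
  cat(sprintf("  future amount:      %g (%g x 10^4), survey density %.1f per 100 m2\n",
              x$future_count, x$future_1e4, x$survey_density_1dp))
  if (is.na(x$structure_ratio_pct)) {
    cat("  structure ratio:    undefined (future amount is zero)\n")
  } else {
    cat(sprintf("  structure ratio:    %.2f%% -> safe quota %g%% to %g%%\n",
                x$structure_ratio_pct, x$safe_quota["lo"], x$safe_quota["hi"]))
  }
  invisible(x)
}

#' @rdname assess
#' @param x a `resource_assessment`.
#' @param ... unused.
#' @export
tidy.resource_assessment <- function(x, ...) {
  tibble(veg_area_km2 = x$veg_area_km2,
         rho_per_100m2 = x$rho_per_100m2,
         survey_density_1dp = x$survey_density_1dp,
         effective_count = x$effective_count,
         effective_1e4 = x$effective_1e4,
         future_count = x$future_count,
         future_1e4 = x$future_1e4,
         structure_ratio_pct = x$structure_ratio_pct,
         safe_quota_lo = unname(x$safe_quota["lo"]),
         safe_quota_hi = unname(x$safe_quota["hi"]))
}

#' @rdname assess
#' @export
glance.resource_assessment <- function(x, ...) tidy(x, ...)
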