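#' Multispectral satellite scene
#'
#' Light container for the two NDVI input bands of a 30 m satellite scene.
#' Rasters are numeric matrices in row-major, top-left-origin, pixel-is-area
#' convention; no geographic projection is carried (area accounting only
#' needs the pixel size).
#'
#' @param red_band,nir_band numeric matrices of nonnegative reflectances,
#'   identical shape.
#' @param pixel_size pixel edge length in metres (default 30).
#' @param nodata_mask optional logical matrix marking pixels to exclude from
#'   all counts (e.g. outside the pasture boundary).
#' @return an object of class `ms_scene`.
#' @export
ms_scene <- function(red_band, nir_band, pixel_size = 30, nodata_mask = NULL) {
  if (!is.matrix(red_band) || !is.matrix(nir_band) ||
      !all(dim(red_band) == dim(nir_band)))
    abort_structure("red and NIR bands must be matrices of identical shape")
  if (any(red_band < 0, na.rm = TRUE) || any(nir_band < 0, na.rm = TRUE))
    abort_validation("reflectances must be nonnegative")
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  if (is.null(nodata_mask)) nodata_mask <- matrix(FALSE, nrow(red_band), ncol(red_band))
  if (!is.logical(nodata_mask) || !all(dim(nodata_mask) == dim(red_band)))
    abort_structure("`nodata_mask` must be a logical matrix matching the bands")
  structure(list(red_band = red_band, nir_band = nir_band,
                 pixel_size = pixel_size, nodata_mask = nodata_mask),
            class = "ms_scene")
}

#' @export
print.ms_scene <- function(x, ...) {
  cat(sprintf("<ms_scene> %d x %d pixels, %g m pixels, %d nodata\n",
              nrow(x$red_band), ncol(x$red_band), x$pixel_size,
              sum(x$nodata_mask)))
  invisible(x)
}

#' Compute the normalized difference vegetation index
#'
#' NDVI = (NIR - R) / (NIR + R) per pixel.  Pixels where both bands are zero
#' (0/0) and nodata pixels are undefined (`NA` in the values, flagged in
#' `undefined_mask`).  Every defined value lies in \[-1, 1\] for nonnegative
#' reflectances.
#'
#' @param scene an [ms_scene()].
#' @return an object of class `ndvi_raster` with elements `values` (numeric
#'   matrix, `NA` where undefined), `undefined_mask`, `nodata_mask`,
#'   `pixel_size`.
#' @examples
#' s <- ms_scene(matrix(0.1), matrix(0.5), pixel_size = 30)
#' compute_ndvi(s)$values  # 0.6667
#' @export
compute_ndvi <- function(scene) {
  if (!inherits(scene, "ms_scene")) abort_structure("`scene` must be an ms_scene")
  denom <- scene$nir_band + scene$red_band
  undefined <- (denom == 0) | scene$nodata_mask
  vals <- (scene$nir_band - scene$red_band) / denom
  vals[undefined] <- NA_real_
  structure(list(values = vals, undefined_mask = undefined,
                 nodata_mask = scene$nodata_mask, pixel_size = scene$pixel_size),
            class = "ndvi_raster")
}

#' Classify vegetation by NDVI thresholds
#'
#' A pixel is vegetation iff `lower < NDVI < upper` (both strict, the
#' conventional interpretation-key rule with `lower = 0.1`).  Undefined
#' pixels count as nonvegetation so the two classes exhaust the scene;
#' nodata pixels are excluded from both counts.
#'
#' @param ndvi an `ndvi_raster` from [compute_ndvi()], or a plain numeric
#'   matrix of NDVI values.
#' @param lower,upper strict vegetation bounds (defaults 0.1 and 1).
#' @return an object of class `veg_mask`: list with `mask` (logical matrix,
#'   `TRUE` = vegetation), `n_veg`, `n_nonveg`, `lower`, `upper`,
#'   `pixel_size`.
#' @export
classify_vegetation <- function(ndvi, lower = 0.1, upper = 1) {
  if (lower >= upper) abort_config("`lower` must be below `upper`")
  if (is.matrix(ndvi) && is.numeric(ndvi))
    ndvi <- structure(list(values = ndvi,
                           undefined_mask = is.na(ndvi),
                           nodata_mask = matrix(FALSE, nrow(ndvi), ncol(ndvi)),
                           pixel_size = NA_real_),
                      class = "ndvi_raster")
  if (!inherits(ndvi, "ndvi_raster")) abort_structure("`ndvi` must be an ndvi_raster")
  v <- ndvi$values
  mask <- !is.na(v) & v > lower & v < upper
  mask[ndvi$nodata_mask] <- FALSE
  counted <- !ndvi$nodata_mask
  n_veg <- sum(mask)
  n_nonveg <- sum(counted) - n_veg
  structure(list(mask = mask, n_veg = n_veg, n_nonveg = n_nonveg,
                 lower = lower, upper = upper, pixel_size = ndvi$pixel_size),
            class = "veg_mask")
}

#' @export
print.veg_mask <- function(x, ...) {
  cat(sprintf("<veg_mask> %d vegetation / %d nonvegetation pixels (%s < NDVI < %s)\n",
              x$n_veg, x$n_nonveg, format(x$lower), format(x$upper)))
  invisible(x)
}

#' Vegetation area ratio
#'
#' P = n_veg / (n_veg + n_nonveg), reported as a percentage at full precision
#' together with the whole-percent value (ties rounded up) used by the
#' downstream reporting chain.
#'
#' @param n_veg,n_nonveg pixel counts, or a `veg_mask` as first argument.
#' @return list with `P` (fraction), `pct` (percent, full precision) and
#'   `pct_rounded` (whole percent).
#' @examples
#' vegetation_ratio(305676, 189658)$pct_rounded  # 62
#' @export
vegetation_ratio <- function(n_veg, n_nonveg = NULL) {
  if (inherits(n_veg, "veg_mask")) {
    n_nonveg <- n_veg$n_nonveg
    n_veg <- n_veg$n_veg
  }
  if (n_veg < 0 || n_nonveg < 0) abort_validation("counts must be nonnegative")
  total <- n_veg + n_nonveg
  if (total <= 0) abort("vegetation ratio undefined: zero total pixel count",
                        class = "rheosense_undefined_ratio")
  P <- n_veg / total
  list(P = P, pct = 100 * P, pct_rounded = round_half_up(100 * P))
}

#' Area accounting from vegetation pixel counts
#'
#' Converts pixel counts into the scene's area bookkeeping: total area M,
#' vegetation ratio P and vegetation area M1 (the S that feeds the resource
#' estimate M = S * rho).  Two M1 values are reported: `M1_km2_direct`
#' (n_veg times the pixel area) and `M1_km2_reported`, which follows the
#' field-report convention of chaining whole-unit figures -- M truncated to
#' whole square kilometres, P rounded to whole percent, and
#' `M1 = round(M_reported * P_pct / 100)`.  Full-precision values are always
#' carried alongside the reported ones.
#'
#' @param n_veg,n_nonveg pixel counts, or a `veg_mask` as first argument
#'   (its pixel size then used unless `pixel_size` is given).
#' @param pixel_size pixel edge length in metres.
#' @return an object of class `area_summary`.
#' @examples
#' a <- area_summary(305676, 189658, pixel_size = 30)
#' a$M_km2_reported   # 445
#' a$M1_km2_reported  # 276
#' @export
area_summary <- function(n_veg, n_nonveg = NULL, pixel_size = 30) {
  if (inherits(n_veg, "veg_mask")) {
    if (!is.na(n_veg$pixel_size)) pixel_size <- n_veg$pixel_size
    n_nonveg <- n_veg$n_nonveg
    n_veg <- n_veg$n_veg
  }
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  total <- n_veg + n_nonveg
  M_km2 <- total * pixel_size^2 / 1e6
  M1_km2_direct <- n_veg * pixel_size^2 / 1e6
  if (total > 0) {
    r <- vegetation_ratio(n_veg, n_nonveg)
    P <- r$P; pct <- r$pct; pct_rounded <- r$pct_rounded
  } else {
    P <- pct <- pct_rounded <- NA_real_
  }
  M_km2_reported <- trunc(M_km2)
  M1_km2_reported <- if (is.na(pct_rounded)) 0 else
    round_half_up(M_km2_reported * pct_rounded / 100)
  structure(list(n_veg = n_veg, n_nonveg = n_nonveg, pixel_size = pixel_size,
                 P = P, P_pct = pct, P_pct_rounded = pct_rounded,
                 M_km2 = M_km2, M_km2_reported = M_km2_reported,
                 M1_km2_direct = M1_km2_direct,
                 M1_km2_reported = M1_km2_reported),
            class = "area_summary")
}

#' @export
print.area_summary <- function(x, ...) {
  cat("<area_summary>\n")
  cat(sprintf("  pixels: %d vegetation / %d nonvegetation (%g m)\n",
              x$n_veg, x$n_nonveg, x$pixel_size))
  cat(sprintf("  P  = %.2f%% (reported %g%%)\n", x$P_pct, x$P_pct_rounded))
  cat(sprintf("  M  = %.4f km2 (reported %g km2)\n", x$M_km2, x$M_km2_reported))
  cat(sprintf("  M1 = %.4f km2 direct (reported %g km2)\n",
              x$M1_km2_direct, x$M1_km2_reported))
  invisible(x)
}

#' @rdname area_summary
#' @param x an `area_summary`.
#' @param ... unused.
#' @export
tidy.area_summary <- function(x, ...) {
  tibble(n_veg = x$n_veg, n_nonveg = x$n_nonveg, pixel_size = x$pixel_size,
         P_pct = x$P_pct, P_pct_rounded = x$P_pct_rounded,
         M_km2 = x$M_km2, M_km2_reported = x$M_km2_reported,
         M1_km2_direct = x$M1_km2_direct,
         M1_km2_reported = x$M1_km2_reported)
}
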