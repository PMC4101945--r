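#' Read and write scenes as TIFF with a JSON sidecar
#'
#' Rasters are stored as plain 32-bit float TIFF; the ground geometry that a
#' geographic format would carry (pixel size, band names) lives in a JSON
#' sidecar `<path>.json`.  No projection is stored: the pipeline only needs
#' pixel areas.
#'
#' @param scene an [ms_scene()] or [aerial_scene()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  if (inherits(scene, "ms_scene")) {
    arr <- array(c(scene$red_band, scene$nir_band),
                 dim = c(dim(scene$red_band), 2))
    meta <- list(type = "ms_scene", pixel_size = scene$pixel_size,
                 bands = c("red", "nir"))
    if (any(scene$nodata_mask)) meta$nodata_idx <- which(scene$nodata_mask)
  } else if (inherits(scene, "aerial_scene")) {
    arr <- scene$bands
    meta <- list(type = "aerial_scene", pixel_size = scene$pixel_size,
                 bands = paste0("b", seq_len(dim(scene$bands)[3])))
  } else {
    abort_structure("`scene` must be an ms_scene or aerial_scene")
  }
  tiff::writeTIFF(pmin(pmax(arr, 0), 1), path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(meta_path))
    abort_validation(paste("missing raster or sidecar for", path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  # band semantics come from the sidecar, so libtiff's guess about
  # non-RGB sample counts (a benign warning) is irrelevant here
  arr <- suppressWarnings(tiff::readTIFF(path))
  if (length(dim(arr)) == 2) arr <- array(arr, dim = c(dim(arr), 1))
  if (identical(meta$type, "ms_scene")) {
    nodata <- matrix(FALSE, dim(arr)[1], dim(arr)[2])
    if (!is.null(meta$nodata_idx)) nodata[meta$nodata_idx] <- TRUE
    ms_scene(arr[, , 1], arr[, , 2], pixel_size = meta$pixel_size,
             nodata_mask = nodata)
  } else {
    aerial_scene(arr, pixel_size = meta$pixel_size)
  }
}

#' Write a vegetation mask as TIFF
#'
#' @param mask a `veg_mask` from [classify_vegetation()] or a logical matrix.
#' @param path output TIFF path.
#' @export
write_mask <- function(mask, path) {
  m <- if (inherits(mask, "veg_mask")) mask$mask else mask
  tiff::writeTIFF(m * 1, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Write stage reports as JSON
#'
#' `write_area_report()` serialises an [area_summary()];
#' `write_assessment()` a [assess()] result (including the provenance
#' trail); `report_markdown()` renders the assessment as a short
#' human-readable Markdown report.
#'
#' @param x the object to serialise.
#' @param path output path.
#' @export
write_area_report <- function(x, path) {
  if (!inherits(x, "area_summary")) abort_structure("`x` must be an area_summary")
  jsonlite::write_json(list(
    n_veg = x$n_veg, n_nonveg = x$n_nonveg, pixel_size = x$pixel_size,
    P_pct = x$P_pct, P_pct_rounded = x$P_pct_rounded,
    M_km2 = x$M_km2, M_km2_reported = x$M_km2_reported,
    M1_km2_direct = x$M1_km2_direct, M1_km2_reported = x$M1_km2_reported),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_area_report
#' @export
write_assessment <- function(x, path) {
  if (!inherits(x, "resource_assessment"))
    abort_structure("`x` must be a resource_assessment")
  out <- unclass(x)
  out$safe_quota <- as.list(x$safe_quota)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_area_report
#' @export
report_markdown <- function(x) {
  if (!inherits(x, "resource_assessment"))
    abort_structure("`x` must be a resource_assessment")
  c("# Resource assessment",
    "",
    sprintf("* Vegetation area S: **%g km2** (%s)", x$veg_area_km2,
            x$provenance$area),
    sprintf("* Effective amount: **%g** (%g x 10^4); %s", x$effective_count,
            x$effective_1e4, x$provenance$effective),
    sprintf("* Future amount: **%g** (%g x 10^4); %s", x$future_count,
            x$future_1e4, x$provenance$future),
    if (is.na(x$structure_ratio_pct))
      "* Structure ratio: undefined (future amount is zero)"
    else
      sprintf("* Structure ratio: **%.2f%%**, safe harvest quota %g%% to %g%% (%s)",
              x$structure_ratio_pct, x$safe_quota["lo"], x$safe_quota["hi"],
              x$provenance$quota))
}
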