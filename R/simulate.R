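#' Simulation configurations
#'
#' Constructors for the three synthetic input layers.  The generators exist
#' so that every downstream stage has a parameter-recovery test against known
#' ground truth: a two-class satellite scene with a controllable vegetation
#' fraction, aerial scenes of non-overlapping elliptical plant canopies with
#' a size distribution straddling the 1 m-squared minimum mapping unit, and
#' quadrat counts from a homogeneous Poisson process.
#'
#' @param width,height scene size in pixels.
#' @param pixel_size pixel edge length in metres.
#' @param veg_fraction fraction of pixels that are vegetation, in \[0, 1\].
#' @param veg_ndvi_mean,nonveg_ndvi_mean class NDVI means; vegetation must sit
#'   above the 0.1 classification threshold and nonvegetation below it.
#' @param ndvi_noise_sd Gaussian sd of per-pixel NDVI around the class mean.
#' @param seed integer seed; identical config + seed gives identical output.
#' @return a classed config list.
#' @export
satellite_sim_config <- function(width = 100, height = 100, pixel_size = 30,
                                 veg_fraction = 0.62,
                                 veg_ndvi_mean = 0.6, nonveg_ndvi_mean = -0.1,
                                 ndvi_noise_sd = 0.05, seed = 1) {
  check_number(width, "width", lower = 1)
  check_number(height, "height", lower = 1)
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  check_number(veg_fraction, "veg_fraction", lower = 0, upper = 1)
  check_number(ndvi_noise_sd, "ndvi_noise_sd", lower = 0)
  check_number(veg_ndvi_mean, "veg_ndvi_mean", lower = -1, upper = 1)
  check_number(nonveg_ndvi_mean, "nonveg_ndvi_mean", lower = -1, upper = 1)
  if (!(veg_ndvi_mean > 0.1 && nonveg_ndvi_mean < 0.1))
    abort_config("class means must straddle the 0.1 threshold: veg > 0.1 > nonveg")
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size, veg_fraction = veg_fraction,
                 veg_ndvi_mean = veg_ndvi_mean,
                 nonveg_ndvi_mean = nonveg_ndvi_mean,
                 ndvi_noise_sd = ndvi_noise_sd, seed = as.integer(seed)),
            class = "satellite_sim_config")
}

#' @rdname satellite_sim_config
#' @param footprint_w,footprint_h ground footprint of one aerial image, metres.
#' @param plant_intensity expected plants per square metre (Poisson).
#' @param area_distribution canopy-area distribution spec: one of
#'   `list(type = "lognormal", meanlog, sdlog)`,
#'   `list(type = "uniform", min, max)` or `list(type = "fixed", area)`
#'   (areas in m-squared, strictly positive).
#' @param plant_color,background_color per-band mean reflectances (length 3).
#' @param noise_sd per-pixel, per-band Gaussian reflectance noise sd.
#' @export
aerial_sim_config <- function(footprint_w = 20, footprint_h = 20,
                              pixel_size = 0.1, plant_intensity = 0.02,
                              area_distribution = list(type = "lognormal",
                                                       meanlog = log(0.8),
                                                       sdlog = 0.6),
                              plant_color = c(0.20, 0.32, 0.08),
                              background_color = c(0.07, 0.18, 0.05),
                              noise_sd = 0.02, seed = 1) {
  check_number(footprint_w, "footprint_w", lower = 0, strict_lower = TRUE)
  check_number(footprint_h, "footprint_h", lower = 0, strict_lower = TRUE)
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  check_number(plant_intensity, "plant_intensity", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (length(plant_color) != length(background_color))
    abort_config("plant and background colors must have the same band count")
  if (!is.list(area_distribution) ||
      !area_distribution$type %in% c("lognormal", "uniform", "fixed"))
    abort_config("`area_distribution` must be a lognormal, uniform or fixed spec")
  structure(list(footprint_w = footprint_w, footprint_h = footprint_h,
                 pixel_size = pixel_size, plant_intensity = plant_intensity,
                 area_distribution = area_distribution,
                 plant_color = plant_color, background_color = background_color,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "aerial_sim_config")
}

#' @rdname satellite_sim_config
#' @param n_fences number of fenced survey zones.
#' @param fence_dims list of `c(w, h)` metres, one per fence; the default
#'   mirrors the study layout (200 x 200 m, third fence 150 x 150 m).
#' @param quadrats_per_fence quadrats laid out in each fence.
#' @param quadrat_side quadrat edge length in metres (10 m, i.e. 100
#'   m-squared plots).
#' @param intensity expected plants per 100 m-squared.
#' @param years survey years.
#' @export
survey_sim_config <- function(n_fences = 10, fence_dims = NULL,
                              quadrats_per_fence = 4, quadrat_side = 10,
                              intensity = 2.6, years = c(2008, 2010, 2011),
                              seed = 1) {
  check_number(n_fences, "n_fences", lower = 1)
  check_number(quadrats_per_fence, "quadrats_per_fence", lower = 1)
  check_number(quadrat_side, "quadrat_side", lower = 0, strict_lower = TRUE)
  check_number(intensity, "intensity", lower = 0)
  if (is.null(fence_dims)) {
    fence_dims <- rep(list(c(200, 200)), n_fences)
    if (n_fences >= 3) fence_dims[[3]] <- c(150, 150)
  }
  if (length(fence_dims) != n_fences)
    abort_config("`fence_dims` must list one (w, h) pair per fence")
  for (d in fence_dims) {
    if (length(d) != 2 || any(d <= 0)) abort_config("fence dimensions must be positive pairs")
    if (quadrat_side^2 > prod(d)) abort_config("quadrat area exceeds a fence area")
  }
  structure(list(n_fences = as.integer(n_fences), fence_dims = fence_dims,
                 quadrats_per_fence = as.integer(quadrats_per_fence),
                 quadrat_side = quadrat_side, intensity = intensity,
                 years = years, seed = as.integer(seed)),
            class = "survey_sim_config")
}

#' Simulate a two-class satellite scene
#'
#' Builds a red + NIR reflectance raster whose per-pixel NDVI is Gaussian
#' around the class mean; the ground-truth vegetation mask contains exactly
#' `round(veg_fraction * width * height)` pixels placed by a seeded shuffle.
#' Bands are derived from the target NDVI at fixed brightness
#' (red + NIR = 0.5), so [compute_ndvi()] recovers the simulated index
#' exactly up to clamping.
#'
#' @param cfg a [satellite_sim_config()].
#' @return list with `scene` (an [ms_scene()]) and `truth` (list with
#'   `veg_mask`, `ndvi`, `n_veg`).
#' @export
simulate_satellite <- function(cfg) {
  if (!inherits(cfg, "satellite_sim_config"))
    abort_config("`cfg` must come from satellite_sim_config()")
  if (cfg$ndvi_noise_sd > 0) {
    gap <- min(cfg$veg_ndvi_mean - 0.1, 0.1 - cfg$nonveg_ndvi_mean)
    if (gap < 3 * cfg$ndvi_noise_sd)
      warn(paste("a class NDVI mean sits within 3 noise sd of the 0.1 threshold;",
                 "classification of this scene is not expected to recover the",
                 "configured fraction"),
           class = "rheosense_threshold_overlap_warning")
  }
  n <- cfg$width * cfg$height
  withr::with_seed(cfg$seed, {
    n_veg <- round(cfg$veg_fraction * n)
    veg <- logical(n)
    veg[sample.int(n, n_veg)] <- TRUE
    mu <- ifelse(veg, cfg$veg_ndvi_mean, cfg$nonveg_ndvi_mean)
    ndvi <- mu + if (cfg$ndvi_noise_sd > 0) rnorm(n, 0, cfg$ndvi_noise_sd) else 0
  })
  ndvi <- pmin(pmax(ndvi, -0.99), 0.99)
  dim(ndvi) <- c(cfg$height, cfg$width)
  veg_mask <- matrix(veg, cfg$height, cfg$width)
  red <- 0.25 * (1 - ndvi)
  nir <- 0.25 * (1 + ndvi)
  list(scene = ms_scene(red, nir, pixel_size = cfg$pixel_size),
       truth = list(veg_mask = veg_mask, ndvi = ndvi, n_veg = n_veg))
}

#' Aerial image scene
#'
#' @param bands numeric array `height x width x n_bands` of reflectances.
#' @param pixel_size pixel edge length in metres.
#' @return an object of class `aerial_scene`; `footprint_area` is the ground
#'   area covered, in m-squared.
#' @export
aerial_scene <- function(bands, pixel_size = 0.1) {
  if (!is.array(bands) || length(dim(bands)) != 3)
    abort_structure("`bands` must be a height x width x band array")
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  structure(list(bands = bands, pixel_size = pixel_size,
                 footprint_area = dim(bands)[1] * dim(bands)[2] * pixel_size^2),
            class = "aerial_scene")
}

#' @export
print.aerial_scene <- function(x, ...) {
  d <- dim(x$bands)
  cat(sprintf("<aerial_scene> %d x %d px, %d band(s), %g m pixels (%g m2 footprint)\n",
              d[1], d[2], d[3], x$pixel_size, x$footprint_area))
  invisible(x)
}

draw_areas <- function(dist, n) {
  a <- switch(dist$type,
    lognormal = stats::rlnorm(n, dist$meanlog, dist$sdlog),
    uniform   = runif(n, dist$min, dist$max),
    fixed     = rep(dist$area, n))
  if (any(a <= 0)) abort_config("canopy areas must be strictly positive")
  a
}

#' Simulate an aerial scene of elliptical plant canopies
#'
#' The plant count is Poisson(`plant_intensity` x footprint area); each plant
#' is an ellipse with area drawn from the configured distribution, axis ratio
#' uniform in \[1, 2.5\] and random orientation.  Ellipses are placed by
#' rejection sampling so that canopies never overlap or touch (a one-pixel
#' gap is enforced), keeping the count ground truth unambiguous; the call
#' fails after a bounded number of rejections if the requested intensity
#' cannot be packed.  Plant pixels take `plant_color` and the rest
#' `background_color`, both plus Gaussian noise.
#'
#' @param cfg an [aerial_sim_config()].
#' @param plants optional tibble with columns `x`, `y` (centre, metres from
#'   the top-left corner), `area_m2` and optionally `ratio`, `angle`, forcing
#'   these exact plants instead of random placement.
#' @param render if `FALSE`, skip rasterisation and return only the ground
#'   truth (fast path for count calibration studies).
#' @return list with `scene` (an [aerial_scene()], `NULL` when
#'   `render = FALSE`) and `truth` (list with `mask`, a logical canopy
#'   raster, and `plants`, a tibble of centres, analytic areas and
#'   rasterised pixel counts).
#' @export
simulate_aerial <- function(cfg, plants = NULL, render = TRUE) {
  if (!inherits(cfg, "aerial_sim_config"))
    abort_config("`cfg` must come from aerial_sim_config()")
  ps <- cfg$pixel_size
  H <- round(cfg$footprint_h / ps)
  W <- round(cfg$footprint_w / ps)
  nb <- length(cfg$plant_color)
  withr::with_seed(cfg$seed, {
    if (is.null(plants)) {
      n_target <- rpois(1, cfg$plant_intensity * cfg$footprint_w * cfg$footprint_h)
      xs <- ys <- areas <- ratios <- angles <- numeric(0)
      majors <- numeric(0)
      gap <- 2 * ps
      for (k in seq_len(n_target)) {
        placed <- FALSE
        for (attempt in seq_len(200L)) {
          a <- draw_areas(cfg$area_distribution, 1)
          r <- runif(1, 1, 2.5)
          s1 <- sqrt(a * r / pi)            # major semi-axis
          if (2 * s1 + gap > min(cfg$footprint_w, cfg$footprint_h)) next
          x <- runif(1, s1 + gap, cfg$footprint_w - s1 - gap)
          y <- runif(1, s1 + gap, cfg$footprint_h - s1 - gap)
          # conservative disjointness: bounding circles must not touch
          if (length(xs) == 0 ||
              all(sqrt((xs - x)^2 + (ys - y)^2) > majors + s1 + gap)) {
            xs <- c(xs, x); ys <- c(ys, y); areas <- c(areas, a)
            ratios <- c(ratios, r); angles <- c(angles, runif(1, 0, pi))
            majors <- c(majors, s1)
            placed <- TRUE
            break
          }
        }
        if (!placed)
          abort(sprintf("could not pack %d non-overlapping canopies at intensity %g",
                        n_target, cfg$plant_intensity),
                class = "rheosense_packing_error")
      }
      plants <- tibble(x = xs, y = ys, area_m2 = areas,
                       ratio = ratios, angle = angles)
    } else {
      plants <- as_tibble(plants)
      if (!all(c("x", "y", "area_m2") %in% names(plants)))
        abort_config("forced `plants` need columns x, y, area_m2")
      if (any(plants$area_m2 <= 0)) abort_config("canopy areas must be strictly positive")
      if (!"ratio" %in% names(plants)) plants$ratio <- 1
      if (!"angle" %in% names(plants)) plants$angle <- 0
    }

    mask <- NULL
    scene <- NULL
    raster_px <- rep(NA_integer_, nrow(plants))
    if (render) {
      mask <- matrix(FALSE, H, W)
      for (k in seq_len(nrow(plants))) {
        s1 <- sqrt(plants$area_m2[k] * plants$ratio[k] / pi)
        s2 <- sqrt(plants$area_m2[k] / (pi * plants$ratio[k]))
        th <- plants$angle[k]
        rr <- ceiling((s1 + ps) / ps)
        ci <- round(plants$y[k] / ps); cj <- round(plants$x[k] / ps)
        i <- max(1, ci - rr):min(H, ci + rr)
        j <- max(1, cj - rr):min(W, cj + rr)
        py <- (i - 0.5) * ps - plants$y[k]
        px <- (j - 0.5) * ps - plants$x[k]
        gx <- outer(rep(1, length(py)), px)
        gy <- outer(py, rep(1, length(px)))
        u <- gx * cos(th) + gy * sin(th)
        v <- -gx * sin(th) + gy * cos(th)
        inside <- (u / s1)^2 + (v / s2)^2 <= 1
        raster_px[k] <- sum(inside)
        mask[i, j] <- mask[i, j] | inside
      }
      bands <- array(0, dim = c(H, W, nb))
      for (b in seq_len(nb)) {
        plane <- matrix(cfg$background_color[b], H, W)
        plane[mask] <- cfg$plant_color[b]
        if (cfg$noise_sd > 0) plane <- plane + rnorm(H * W, 0, cfg$noise_sd)
        bands[, , b] <- pmin(pmax(plane, 0), 1)
      }
      scene <- aerial_scene(bands, pixel_size = ps)
    }
  })
  plants$raster_area_px <- raster_px
  list(scene = scene, truth = list(mask = mask, plants = plants))
}

#' Simulate a fence/quadrat ground survey
#'
#' Each quadrat count is drawn independently as
#' Poisson(`intensity` x quadrat area / 100 m-squared) for every fence,
#' quadrat and year.
#'
#' @param cfg a [survey_sim_config()].
#' @return a `survey_records` tibble with columns `fence_id`, `fence_w_m`,
#'   `fence_h_m`, `quadrat_id`, `quadrat_side_m`, `year`, `count`.
#' @export
simulate_survey <- function(cfg) {
  if (!inherits(cfg, "survey_sim_config"))
    abort_config("`cfg` must come from survey_sim_config()")
  fence_ids <- as.character(utils::as.roman(seq_len(cfg$n_fences)))
  grid <- expand.grid(quadrat_id = seq_len(cfg$quadrats_per_fence),
                      fence = seq_len(cfg$n_fences),
                      year = cfg$years)
  lambda <- cfg$intensity * cfg$quadrat_side^2 / 100
  counts <- withr::with_seed(cfg$seed, rpois(nrow(grid), lambda))
  out <- tibble(
    fence_id = fence_ids[grid$fence],
    fence_w_m = vapply(grid$fence, function(f) cfg$fence_dims[[f]][1], 0),
    fence_h_m = vapply(grid$fence, function(f) cfg$fence_dims[[f]][2], 0),
    quadrat_id = grid$quadrat_id,
    quadrat_side_m = cfg$quadrat_side,
    year = grid$year,
    count = counts)
  class(out) <- c("survey_records", class(out))
  out
}
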