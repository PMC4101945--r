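#' Pooled plant density across aerial images
#'
#' Area-weighted pooling: `rho = sum(counts) / sum(footprints)`, reported
#' per 100 m-squared and per hectare, with a percentile bootstrap interval
#' over images when at least two images are available.
#'
#' @param counts plants detected per image, or a data frame with columns
#'   `count` and `footprint_m2`.
#' @param footprints_m2 ground footprint of each image, m-squared.
#' @param n_boot bootstrap replicates (0 disables the interval).
#' @param conf interval coverage.
#' @param seed optional seed for the bootstrap resampling.
#' @return a `density_estimate` object: `rho_per_100m2`, `rho_per_ha`,
#'   `n_images`, `total_count`, `total_footprint_m2`, `ci` (per 100
#'   m-squared, `NA` when only one image).
#' @examples
#' estimate_density(c(2, 0), c(400, 600))$rho_per_100m2  # 0.2
#' @export
estimate_density <- function(counts, footprints_m2 = NULL, n_boot = 1000,
                             conf = 0.95, seed = NULL) {
  if (is.data.frame(counts)) {
    footprints_m2 <- counts$footprint_m2
    counts <- counts$count
  }
  if (length(counts) < 1 || length(counts) != length(footprints_m2))
    abort_structure("need one count and one footprint per image")
  if (any(counts < 0) || any(footprints_m2 <= 0))
    abort_validation("counts must be nonnegative and footprints positive")
  total_fp <- sum(footprints_m2)
  if (total_fp <= 0) abort_validation("zero total footprint")
  rho_m2 <- sum(counts) / total_fp
  ci <- c(NA_real_, NA_real_)
  if (length(counts) >= 2 && n_boot > 0) {
    boot_one <- function() {
      idx <- sample.int(length(counts), replace = TRUE)
      100 * sum(counts[idx]) / sum(footprints_m2[idx])
    }
    reps <- if (is.null(seed)) replicate(n_boot, boot_one()) else
      withr::with_seed(seed, replicate(n_boot, boot_one()))
    ci <- unname(quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  }
  structure(list(rho_per_100m2 = 100 * rho_m2, rho_per_ha = 1e4 * rho_m2,
                 n_images = length(counts), total_count = sum(counts),
                 total_footprint_m2 = total_fp, conf = conf, ci = ci),
            class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("<density_estimate> %.4g per 100 m2 (%.4g per ha), %d image(s)\n",
              x$rho_per_100m2, x$rho_per_ha, x$n_images))
  if (!anyNA(x$ci))
    cat(sprintf("  %g%% bootstrap CI: [%.4g, %.4g] per 100 m2\n",
                100 * x$conf, x$ci[1], x$ci[2]))
  invisible(x)
}

#' @rdname estimate_density
#' @param x a `density_estimate`.
#' @param ... unused.
#' @export
tidy.density_estimate <- function(x, ...) {
  tibble(rho_per_100m2 = x$rho_per_100m2, rho_per_ha = x$rho_per_ha,
         ci_low = x$ci[1], ci_high = x$ci[2], n_images = x$n_images,
         total_count = x$total_count, total_footprint_m2 = x$total_footprint_m2)
}

#' @rdname estimate_density
#' @export
glance.density_estimate <- function(x, ...) tidy(x, ...)

#' Score detections against a ground-truth canopy mask
#'
#' Ground truth is the set of 4-connected components of `truth_mask` whose
#' pixel area strictly exceeds the minimum mapping unit (the same rule the
#' detector applies).  Each detected object is assigned to the truth
#' component holding the majority of its pixels; an object whose majority
#' component is above-MMU and not yet claimed is a true positive, anything
#' else (background majority, below-MMU component, or duplicate claim) a
#' false positive.  Unclaimed above-MMU components are false negatives.
#'
#' @param objects detected objects from [detect_plants()] (the segment label
#'   raster attribute is required).
#' @param truth_mask logical ground-truth canopy raster.
#' @param mmu minimum mapping unit, m-squared.
#' @param pixel_size pixel edge length in metres (taken from `objects` if
#'   absent).
#' @return one-row tibble: `n_truth`, `n_detected`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`.
#' @export
evaluate_detection <- function(objects, truth_mask, mmu = 1,
                               pixel_size = NULL) {
  lab <- attr(objects, "label_matrix")
  if (is.null(lab)) abort_structure("`objects` must carry a label_matrix attribute")
  pixel_size <- pixel_size %||% attr(objects, "pixel_size")
  truth_lab <- label_components(truth_mask)
  truth_px <- tabulate(truth_lab)
  above <- which(truth_px * pixel_size^2 > mmu)
  claimed <- logical(max(truth_lab, 1))
  tp <- 0L; fp <- 0L
  for (id in sort(objects$segment_id)) {
    overlap <- truth_lab[lab == id]
    tab <- tabulate(overlap + 1L)  # slot 1 = background
    maj <- which.max(tab) - 1L
    if (maj > 0 && maj %in% above && !claimed[maj]) {
      claimed[maj] <- TRUE
      tp <- tp + 1L
    } else {
      fp <- fp + 1L
    }
  }
  fn <- length(above) - tp
  tibble(n_truth = length(above), n_detected = nrow(objects),
         tp = tp, fp = fp, fn = fn,
         precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Synthetic detection benchmark
#'
#' Simulates `n_images` noisy aerial scenes under one configuration (seeds
#' `seed, seed + 1, ...`), runs the full detector on each, scores it against
#' the ground truth and pools counts into a density estimate.
#'
#' @param cfg an [aerial_sim_config()]; its `seed` field is ignored in
#'   favour of the per-image seeds.
#' @param n_images number of simulated images.
#' @param seed base seed.
#' @inheritParams detect_plants
#' @return list with `metrics` (one-row tibble: pooled `tp`, `fp`, `fn`,
#'   `precision`, `recall`, plus detected and true densities per 100
#'   m-squared), `per_image` (tibble of per-image results) and `density`
#'   (the pooled [estimate_density()] of detected counts).
#' @export
detection_benchmark <- function(cfg = aerial_sim_config(), n_images = 15,
                                seed = 101, scale = 20, w_color = 0.8,
                                rules = NULL, mmu = 1) {
  if (is.null(rules)) rules <- default_plant_rules(plant_color = cfg$plant_color)
  per <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer(seed + i - 1L)
    sim <- simulate_aerial(cfg_i)
    obj <- detect_plants(sim$scene, scale = scale, w_color = w_color,
                         rules = rules, mmu = mmu)
    ev <- evaluate_detection(obj, sim$truth$mask, mmu = mmu)
    ev$image <- i
    ev$footprint_m2 <- sim$scene$footprint_area
    per[[i]] <- ev
  }
  per <- dplyr::bind_rows(per)
  dens <- estimate_density(per$n_detected, per$footprint_m2, n_boot = 0)
  true_dens <- 100 * sum(per$n_truth) / sum(per$footprint_m2)
  tp <- sum(per$tp); fp <- sum(per$fp); fn <- sum(per$fn)
  metrics <- tibble(n_images = n_images,
                    n_truth = sum(per$n_truth), tp = tp, fp = fp, fn = fn,
                    precision = tp / max(tp + fp, 1),
                    recall = tp / max(tp + fn, 1),
                    rho_detected_per_100m2 = dens$rho_per_100m2,
                    rho_true_per_100m2 = true_dens)
  list(metrics = metrics, per_image = per, density = dens)
}
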