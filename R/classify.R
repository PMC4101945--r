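#' Trapezoidal fuzzy rule
#'
#' One classification criterion: membership of a segment feature rises
#' linearly from 0 at `a` to 1 at `b`, stays 1 on the plateau \[`b`, `c`\]
#' and falls back to 0 at `d`.  Use `-Inf`/`Inf` shoulders for one-sided
#' rules.
#'
#' @param feature name of a segment-table column (e.g. `"mean_b2"`,
#'   `"area_m2"`, `"compactness"`).
#' @param a,b,c,d trapezoid knots, `a <= b <= c <= d`.
#' @return a `fuzzy_rule` object.
#' @export
fuzzy_rule <- function(feature, a, b, c, d) {
  if (!is.character(feature) || length(feature) != 1)
    abort_config("`feature` must be a single column name")
  if (!(a <= b && b <= c && c <= d))
    abort_config("trapezoid knots must satisfy a <= b <= c <= d")
  structure(list(feature = feature, a = a, b = b, c = c, d = d),
            class = "fuzzy_rule")
}

trapezoid_membership <- function(x, r) {
  m <- numeric(length(x))
  on_plateau <- x >= r$b & x <= r$c
  m[on_plateau] <- 1
  left <- x > r$a & x < r$b
  if (any(left)) m[left] <- (x[left] - r$a) / (r$b - r$a)
  right <- x > r$c & x < r$d
  if (any(right)) m[right] <- (r$d - x[right]) / (r$d - r$c)
  m
}

#' Default fuzzy rule set for plant canopies
#'
#' Spectral means must sit near the expected canopy colour (plateau within
#' `color_tol` of each band mean, zero membership beyond `2 * color_tol`),
#' the object area must fall in `area_range` (default 0.2-50 m-squared) and
#' the object must not be too ragged (`compactness` plateau up to
#' `compactness_max`, zero at `compactness_max + 1`).  All parameters are
#' user-overridable; the rules are ordinary [fuzzy_rule()] objects.
#'
#' @param plant_color expected per-band canopy reflectance.
#' @param color_tol half-width of the spectral plateau.
#' @param area_range plateau of the canopy-area rule, m-squared.
#' @param compactness_max plateau end of the shape rule.
#' @return list of [fuzzy_rule()] objects.
#' @export
default_plant_rules <- function(plant_color = c(0.20, 0.32, 0.08),
                                color_tol = 0.06,
                                area_range = c(0.2, 50),
                                compactness_max = 3) {
  rules <- lapply(seq_along(plant_color), function(b)
    fuzzy_rule(paste0("mean_b", b),
               plant_color[b] - 2 * color_tol, plant_color[b] - color_tol,
               plant_color[b] + color_tol, plant_color[b] + 2 * color_tol))
  c(rules,
    list(fuzzy_rule("area_m2", area_range[1] / 2, area_range[1],
                    area_range[2], area_range[2] * 1.2),
         fuzzy_rule("compactness", -Inf, -Inf, compactness_max,
                    compactness_max + 1)))
}

#' Classify segments as plant objects by fuzzy rules
#'
#' Evaluates every rule's trapezoidal membership on each segment and
#' combines them with the minimum (a conservative fuzzy AND).  A segment is
#' classified as a plant iff its overall membership reaches `threshold`
#' (inclusive, default 0.5: a feature sitting exactly at a shoulder midpoint
#' still classifies).
#'
#' @param segments a `segment_tbl` from [segment_scene()].
#' @param rules list of [fuzzy_rule()] objects (default
#'   [default_plant_rules()]).
#' @param threshold decision threshold on the overall membership.
#' @return the classified rows of `segments` with an added
#'   `overall_membership` column plus one `m_<feature>` column per rule;
#'   label raster and pixel size attributes are preserved.
#' @export
classify_objects <- function(segments, rules = default_plant_rules(),
                             threshold = 0.5) {
  if (inherits(rules, "fuzzy_rule")) rules <- list(rules)
  feats <- vapply(rules, function(r) r$feature, "")
  missing_feats <- setdiff(feats, names(segments))
  if (length(missing_feats) > 0)
    abort_config(paste("rules reference unknown features:",
                       paste(missing_feats, collapse = ", ")))
  m <- vapply(rules, function(r) trapezoid_membership(segments[[r$feature]], r),
              numeric(nrow(segments)))
  m <- matrix(m, nrow = nrow(segments))
  overall <- apply(m, 1, min)
  out <- segments
  for (i in seq_along(rules)) out[[paste0("m_", feats[i])]] <- m[, i]
  out$overall_membership <- overall
  keep <- overall >= threshold
  res <- out[keep, , drop = FALSE]
  attr(res, "label_matrix") <- attr(segments, "label_matrix")
  attr(res, "pixel_size") <- attr(segments, "pixel_size")
  res
}

#' Minimum-mapping-unit filter
#'
#' Keeps only objects whose canopy area strictly exceeds `mmu` ("more than"
#' 1 m-squared by default): at 0.1 m pixels an object of exactly 100 pixels
#' (1.0 m-squared) is removed.  Only these objects count as effective
#' (aerially interpretable) resource.
#'
#' @param objects tibble with an `area_m2` column.
#' @param mmu minimum mapping unit in m-squared.
#' @return the rows with `area_m2 > mmu`, attributes preserved.
#' @export
filter_mmu <- function(objects, mmu = 1) {
  check_number(mmu, "mmu", lower = 0, strict_lower = TRUE)
  res <- objects[objects$area_m2 > mmu, , drop = FALSE]
  attr(res, "label_matrix") <- attr(objects, "label_matrix")
  attr(res, "pixel_size") <- attr(objects, "pixel_size")
  res
}

#' Detect individual plants in an aerial scene
#'
#' The full object-based chain: [segment_scene()], [classify_objects()],
#' [filter_mmu()].  One classified object is one plant; adjacent objects are
#' never merged into individuals.
#'
#' @inheritParams segment_scene
#' @inheritParams classify_objects
#' @inheritParams filter_mmu
#' @return tibble of detected plant objects (see [classify_objects()]), with
#'   the segment label raster attached as an attribute.
#' @export
detect_plants <- function(scene, scale = 20, w_color = 0.8,
                          rules = default_plant_rules(), mmu = 1,
                          threshold = 0.5) {
  segs <- segment_scene(scene, scale = scale, w_color = w_color)
  filter_mmu(classify_objects(segs, rules, threshold = threshold), mmu = mmu)
}
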