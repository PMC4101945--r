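#' Segment an aerial scene by multiresolution region merging
#'
#' Partitions the raster into homogeneous objects by iterative pairwise
#' region merging.  At each step the globally cheapest merge of two adjacent
#' regions is performed, with fusion cost
#' `f = w_color * dh_color + (1 - w_color) * dh_shape`, where `h_color` is
#' the area-weighted sum of per-band pixel sds and `h_shape` the
#' area-weighted mean of compactness (`perimeter / (4 sqrt(n))`) and
#' smoothness (`perimeter / bounding-box perimeter`); merging stops once the
#' cheapest merge would cost more than `scale`.  Ties are broken by the
#' lowest segment id, so the result is deterministic.  Segments are
#' 4-connected and always form an exact partition of the raster.
#'
#' @param scene an [aerial_scene()], or a numeric matrix / 3-d array of band
#'   values (then `pixel_size` must be given).
#' @param scale heterogeneity budget; larger values merge further and yield
#'   fewer, larger segments.
#' @param w_color weight of the spectral term in \[0, 1\] (the remainder
#'   weights the shape term).
#' @param pixel_size pixel edge length in metres, for raw matrix input.
#' @return a `segment_tbl` tibble with one row per segment: pixel count,
#'   area, per-band spectral mean and sd, perimeter (pixel edges),
#'   compactness, smoothness and centroid (metres from the top-left corner).
#'   The integer label raster is attached as `attr(, "label_matrix")`.
#' @export
segment_scene <- function(scene, scale = 20, w_color = 0.8, pixel_size = NULL) {
  check_number(scale, "scale", lower = 0, strict_lower = TRUE)
  check_number(w_color, "w_color", lower = 0, upper = 1)
  if (inherits(scene, "aerial_scene")) {
    bands <- scene$bands
    pixel_size <- scene$pixel_size
  } else if (is.matrix(scene)) {
    bands <- array(scene, dim = c(dim(scene), 1))
  } else if (is.array(scene) && length(dim(scene)) == 3) {
    bands <- scene
  } else {
    abort_structure("`scene` must be an aerial_scene, matrix or 3-d array")
  }
  if (is.null(pixel_size)) pixel_size <- 1
  lab <- cpp_segment(bands, scale, w_color)
  out <- segment_features(lab, bands, pixel_size)
  attr(out, "label_matrix") <- lab
  attr(out, "pixel_size") <- pixel_size
  class(out) <- c("segment_tbl", class(out))
  out
}

# Per-segment feature table from a label raster.
segment_features <- function(lab, bands, pixel_size) {
  H <- nrow(lab); W <- ncol(lab)
  nb <- dim(bands)[3]
  labv <- as.vector(lab)
  n_px <- tabulate(labv)
  k <- length(n_px)
  means <- sds <- matrix(0, k, nb)
  for (b in seq_len(nb)) {
    v <- as.vector(bands[, , b])
    s <- rowsum(v, labv)[, 1]
    s2 <- rowsum(v * v, labv)[, 1]
    means[, b] <- s / n_px
    sds[, b] <- sqrt(pmax(s2 / n_px - means[, b]^2, 0))
  }
  # perimeter = 4n - 2 * (adjacent same-label pairs), image border included
  same_v <- lab[-H, , drop = FALSE] == lab[-1, , drop = FALSE]
  same_h <- lab[, -W, drop = FALSE] == lab[, -1, drop = FALSE]
  internal <- tabulate(c(lab[-H, , drop = FALSE][same_v],
                         lab[, -W, drop = FALSE][same_h]), nbins = k)
  perim <- 4 * n_px - 2 * internal
  rows <- as.vector(row(lab)); cols <- as.vector(col(lab))
  rmin <- tapply(rows, labv, min); rmax <- tapply(rows, labv, max)
  cmin <- tapply(cols, labv, min); cmax <- tapply(cols, labv, max)
  bbox_perim <- 2 * ((rmax - rmin + 1) + (cmax - cmin + 1))
  tibble(
    segment_id = seq_len(k),
    n_px = n_px,
    area_m2 = n_px * pixel_size^2,
    !!!setNames(lapply(seq_len(nb), function(b) means[, b]),
                paste0("mean_b", seq_len(nb))),
    !!!setNames(lapply(seq_len(nb), function(b) sds[, b]),
                paste0("sd_b", seq_len(nb))),
    perimeter_px = perim,
    compactness = perim / (4 * sqrt(n_px)),
    smoothness = perim / as.numeric(bbox_perim),
    centroid_x = (rowsum(cols, labv)[, 1] / n_px - 0.5) * pixel_size,
    centroid_y = (rowsum(rows, labv)[, 1] / n_px - 0.5) * pixel_size)
}
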