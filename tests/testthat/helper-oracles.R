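# Independent reference implementations used as oracles.  These deliberately
# recompute everything from pixel sets at every step (no incremental state,
# no heap), so they share no code path with the package internals.

# 4-connected components by recursive flood fill on a logical matrix.
flood_fill_cc <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    frontier <- matrix(c(i, j), 1)
    lab[i, j] <- nxt
    while (nrow(frontier) > 0) {
      nbrs <- do.call(rbind, lapply(seq_len(nrow(frontier)), function(r) {
        p <- frontier[r, ]
        rbind(p + c(-1, 0), p + c(1, 0), p + c(0, -1), p + c(0, 1))
      }))
      ok <- nbrs[, 1] >= 1 & nbrs[, 1] <= H & nbrs[, 2] >= 1 & nbrs[, 2] <= W
      nbrs <- nbrs[ok, , drop = FALSE]
      keep <- vapply(seq_len(nrow(nbrs)), function(r)
        mask[nbrs[r, 1], nbrs[r, 2]] && lab[nbrs[r, 1], nbrs[r, 2]] == 0L,
        logical(1))
      nbrs <- unique(nbrs[keep, , drop = FALSE])
      for (r in seq_len(nrow(nbrs))) lab[nbrs[r, 1], nbrs[r, 2]] <- nxt
      frontier <- nbrs
    }
  }
  lab
}

# Weighted heterogeneity of one region (pixel index set, column-major),
# written to use the same arithmetic expressions as the segmenter so that
# results agree exactly on exactly-representable band values.
oracle_heter <- function(idx, bands, w_color) {
  H <- dim(bands)[1]; W <- dim(bands)[2]; nb <- dim(bands)[3]
  n <- length(idx)
  hc <- 0
  for (b in seq_len(nb)) {
    v <- bands[, , b][idx]
    m <- sum(v) / n
    va <- sum(v * v) / n - m * m
    hc <- hc + if (va > 0) sqrt(va) else 0
  }
  inreg <- logical(H * W); inreg[idx] <- TRUE
  per <- 0
  for (id in idx) {
    i <- (id - 1) %% H + 1; j <- (id - 1) %/% H + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ni <- i + d[1]; nj <- j + d[2]
      if (ni < 1 || ni > H || nj < 1 || nj > W) per <- per + 1
      else if (!inreg[ni + H * (nj - 1)]) per <- per + 1
    }
  }
  i <- (idx - 1) %% H + 1; j <- (idx - 1) %/% H + 1
  bb <- 2 * ((max(i) - min(i) + 1) + (max(j) - min(j) + 1))
  compact <- per / (4 * sqrt(n))
  smooth <- per / bb
  hs <- 0.5 * compact + 0.5 * smooth
  n * (w_color * hc + (1 - w_color) * hs)
}

# Brute-force best-merge segmentation: recompute every adjacent pair's fusion
# cost from scratch each round, merge the global minimum (ties: lowest then
# second-lowest region id, where a region's id is its smallest pixel index),
# stop when the minimum exceeds `scale`.  Returns a label matrix relabelled
# 1..K in column-major first-encounter order.
oracle_segment <- function(bands, scale, w_color) {
  if (is.matrix(bands)) bands <- array(bands, c(dim(bands), 1))
  H <- dim(bands)[1]; W <- dim(bands)[2]
  regions <- as.list(seq_len(H * W))
  repeat {
    lab <- integer(H * W)
    for (k in seq_along(regions)) lab[regions[[k]]] <- k
    lm <- matrix(lab, H, W)
    pairs <- rbind(
      cbind(as.vector(lm[-H, , drop = FALSE]), as.vector(lm[-1, , drop = FALSE])),
      cbind(as.vector(lm[, -W, drop = FALSE]), as.vector(lm[, -1, drop = FALSE])))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    pairs <- unique(t(apply(pairs, 1, sort)))
    if (is.null(nrow(pairs)) || nrow(pairs) == 0) break
    best <- NULL
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      f <- oracle_heter(c(regions[[a]], regions[[b]]), bands, w_color) -
        oracle_heter(regions[[a]], bands, w_color) -
        oracle_heter(regions[[b]], bands, w_color)
      rid <- sort(c(min(regions[[a]]), min(regions[[b]])))
      key <- c(f, rid)
      if (is.null(best) ||
          key[1] < best$key[1] ||
          (key[1] == best$key[1] && (key[2] < best$key[2] ||
            (key[2] == best$key[2] && key[3] < best$key[3])))) {
        best <- list(key = key, a = a, b = b)
      }
    }
    if (best$key[1] > scale) break
    regions[[best$a]] <- sort(c(regions[[best$a]], regions[[best$b]]))
    regions[[best$b]] <- NULL
  }
  lab <- integer(H * W)
  for (k in seq_along(regions)) lab[regions[[k]]] <- k
  relab <- integer(length(regions)); nxt <- 0L
  out <- integer(H * W)
  for (id in seq_len(H * W)) {
    if (relab[lab[id]] == 0L) { nxt <- nxt + 1L; relab[lab[id]] <- nxt }
    out[id] <- relab[lab[id]]
  }
  matrix(out, H, W)
}

survey_fixture_path <- function() {
  system.file("extdata", "survey_counts.csv", package = "rheosense")
}
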