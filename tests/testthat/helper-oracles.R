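# Independent brute-force oracles used across the suite.  These are kept
# deliberately naive (explicit loops, direct formula transcription) so
# they stay independent of the package's implementations.

oracle_glcm <- function(win, levels, offsets, symmetric, rng) {
  q <- floor((win - rng[1]) / diff(rng) * levels)
  q[q >= levels] <- levels - 1; q[q < 0] <- 0
  counts <- matrix(0, levels, levels)
  for (o in seq_len(nrow(offsets))) {
    dr <- offsets[o, 1]; dc <- offsets[o, 2]
    for (r in seq_len(nrow(win))) {
      for (c in seq_len(ncol(win))) {
        r2 <- r + dr; c2 <- c + dc
        if (r2 < 1 || r2 > nrow(win) || c2 < 1 || c2 > ncol(win)) next
        counts[q[r, c] + 1, q[r2, c2] + 1] <-
          counts[q[r, c] + 1, q[r2, c2] + 1] + 1
        if (symmetric)
          counts[q[r2, c2] + 1, q[r, c] + 1] <-
            counts[q[r2, c2] + 1, q[r, c] + 1] + 1
      }
    }
  }
  counts / sum(counts)
}

oracle_median3 <- function(m) {
  out <- m
  for (r in seq_len(nrow(m))) {
    for (c in seq_len(ncol(m))) {
      if (is.na(m[r, c])) { out[r, c] <- NA; next }
      vals <- c()
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nrow(m) && cc >= 1 && cc <= ncol(m) &&
            !is.na(m[rr, cc]))
          vals <- c(vals, m[rr, cc])
      }
      out[r, c] <- median(sort(vals))
    }
  }
  out
}

oracle_kw <- function(groups) {
  v <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(v)
  N <- length(v)
  H <- 0
  for (j in seq_along(groups))
    H <- H + sum(r[g == j])^2 / sum(g == j)
  H <- 12 / (N * (N + 1)) * H - 3 * (N + 1)
  tt <- table(v)
  H / (1 - sum(tt^3 - tt) / (N^3 - N))
}

oracle_mood <- function(groups) {
  gm <- median(unlist(groups))
  tab <- t(sapply(groups, function(x) {
    x <- x[x != gm]
    c(sum(x > gm), sum(x <= gm))
  }))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

oracle_confusion_stats <- function(pred, ref, classes) {
  cm <- matrix(0, length(classes), length(classes),
               dimnames = list(classes, classes))
  for (i in seq_along(pred)) cm[ref[i], pred[i]] <- cm[ref[i], pred[i]] + 1
  n <- sum(cm)
  oa <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  list(oa = oa, kappa = (oa - pe) / (1 - pe),
       producers = diag(cm) / rowSums(cm),
       users = ifelse(colSums(cm) > 0, diag(cm) / colSums(cm), 0))
}

# direct argmax of per-class Gaussian log densities
oracle_ml_decide <- function(x, mus, sigmas, priors) {
  scores <- sapply(seq_along(mus), function(k) {
    d <- x - mus[[k]]
    log(priors[k]) - 0.5 * log(det(as.matrix(sigmas[[k]]))) -
      0.5 * as.numeric(t(d) %*% solve(as.matrix(sigmas[[k]])) %*% d)
  })
  which.max(scores)
}

oracle_sam_decide <- function(x, spectra) {
  ang <- apply(spectra, 1, function(r)
    acos(sum(x * r) / (sqrt(sum(x^2)) * sqrt(sum(r^2)))))
  which.min(ang)
}

# point-in-polygon by ray casting (for truth checks)
oracle_in_poly <- function(px, py, coords) {
  n <- nrow(coords); inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- coords[i, 1]; yi <- coords[i, 2]
    xj <- coords[j, 1]; yj <- coords[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# small scenes are reused by several test files; cache them per session
.scene_cache <- new.env(parent = emptyenv())
cached_scene <- function(key, params) {
  if (is.null(.scene_cache[[key]]))
    .scene_cache[[key]] <- generate_scene(params)
  .scene_cache[[key]]
}

small_scene_params <- function(seed = 7, n_trees = 6, ...) {
  sp <- default_species()
  sp$width_min <- pmin(sp$width_min, 8)
  sp$width_max <- pmin(sp$width_max, 14)
  scene_params(extent_m = 80, cell_size_m = 0.5, n_trees = n_trees,
               species_table = sp, seed = seed, ...)
}
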