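# Independent oracles used to check the implementation by a different route.

# brute-force Gaussian fit of a single bump: grid search over center and
# width, closed-form optimal height for each candidate
oracle_gauss_fit <- function(freqs, y,
                             centers = freqs,
                             widths = seq(0.25, 6, by = 0.05)) {
  best <- list(sse = Inf)
  for (c0 in centers) for (w0 in widths) {
    g <- exp(-(freqs - c0)^2 / (2 * w0^2))
    a <- sum(y * g) / sum(g * g)
    sse <- sum((y - a * g)^2)
    if (sse < best$sse)
      best <- list(center = c0, height = a, width = w0, sse = sse)
  }
  best
}

# closed-form pooled-variance two-sample t
oracle_pooled_t <- function(a, b) {
  nA <- length(a); nB <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (nA + nB - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / nA + 1 / nB))
}

# exhaustive max-T null over all group relabellings of rbind(XA, XB)
oracle_maxt_enum <- function(XA, XB) {
  X <- rbind(XA, XB)
  nA <- nrow(XA)
  combs <- utils::combn(nrow(X), nA)
  apply(combs, 2, function(idx) {
    ts <- vapply(seq_len(ncol(X)), function(v)
      oracle_pooled_t(X[idx, v], X[-idx, v]), numeric(1))
    max(ts, na.rm = TRUE)
  })
}

# all permutations of 1..n by filtering the full index grid (independent of
# the package's recursive generator)
oracle_all_perms <- function(n) {
  g <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))[, n:1, drop = FALSE]
  g[apply(g, 1, function(r) length(unique(r)) == n), , drop = FALSE]
}

# exhaustive two-sided permutation p for a Spearman correlation
oracle_spearman_exact_p <- function(x, y) {
  rho0 <- cor(x, y, method = "spearman")
  perms <- oracle_all_perms(length(x))
  rhos <- apply(perms, 1, function(p) cor(x, y[p], method = "spearman"))
  mean(abs(rhos) >= abs(rho0) - 1e-12)
}

# count voxel centers of a grid within radius of a point, by full scan
oracle_sphere_count <- function(center, radius, grid) {
  mm <- oscillonet:::voxel_center_mm(grid)
  sum((mm[, 1] - center[1])^2 + (mm[, 2] - center[2])^2 +
        (mm[, 3] - center[3])^2 <= radius^2)
}

# direct 3-D Gaussian convolution at a single voxel (for delta images)
oracle_gauss3d_peak <- function(sigma_vox) {
  k1 <- function(s) {
    r <- max(1, ceiling(4 * s)); x <- seq(-r, r)
    k <- exp(-x^2 / (2 * s^2)); k / sum(k)
  }
  prod(vapply(sigma_vox, function(s) max(k1(s)), numeric(1)))
}

# per-label means by an explicit loop
oracle_parcel_means <- function(values, labels) {
  out <- c()
  for (l in sort(unique(labels[labels > 0]))) {
    v <- values[labels == l]
    out[as.character(l)] <- mean(v[is.finite(v)])
  }
  out
}

# closed-form 2x2 chi-square (no continuity correction)
oracle_chisq_2x2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# small helper: spectrum truths with well-separated peaks for recovery tests
random_separated_truth <- function(max_peaks = 2) {
  nk <- sample(seq_len(max_peaks), 1)
  pk <- NULL
  while (is.null(pk) || nrow(pk) < nk) {
    c0 <- runif(1, 5, 80); w0 <- runif(1, 1, 3); a0 <- runif(1, 0.3, 0.8)
    if (is.null(pk) || all(abs(c0 - pk$center) > 2 * (w0 + pk$width) + 2))
      pk <- rbind(pk, data.frame(center = c0, height = a0, width = w0))
  }
  spectrum_truth(offset = runif(1, 0, 2), exponent = runif(1, 0.5, 2),
                 peaks = pk)
}
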