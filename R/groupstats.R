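# Voxel-wise two-sample contrasts between dominance groups with
# family-wise error control (permutation max-T, Bonferroni cross-check).

# pooled-variance two-sample t per column; rows = maps. Zero pooled
# variance gives NA.
pooled_t_matrix <- function(XA, XB) {
  nA <- nrow(XA); nB <- nrow(XB)
  mA <- colMeans(XA); mB <- colMeans(XB)
  ssA <- colSums(XA^2) - nA * mA^2
  ssB <- colSums(XB^2) - nB * mB^2
  sp2 <- (ssA + ssB) / (nA + nB - 2)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  t <- (mA - mB) / se
  t[se <= 0 | !is.finite(se)] <- NA_real_
  t
}

as_value_matrix <- function(maps) {
  imgs <- lapply(maps, function(m)
    if (inherits(m, "connectivity_map")) m$image else m)
  g <- imgs[[1]]
  for (im in imgs[-1])
    if (!same_grid(im, g)) stop("all maps must share one grid")
  X <- t(vapply(imgs, function(im) as.numeric(im$values),
                numeric(length(g$values))))
  list(X = X, grid = g)
}

#' Voxel-wise pooled-variance two-sample t-test between two map groups
#'
#' Computes, at every voxel observed in all maps of both groups, the
#' classical pooled-variance two-sample t statistic for the contrast
#' A > B (the B > A map is its exact negation). Voxels with any missing
#' value, or zero pooled variance, are `NA`.
#'
#' @param mapsA,mapsB lists of [connectivity_map()] or `volume_image`
#'   objects (>= 2 each), all on one grid.
#' @return An object of class `t_map`: `image` (t values), `dof`
#'   (`nA + nB - 2`), `nA`, `nB`, and `threshold` (`NULL` until
#'   [fwe_threshold()] is applied).
#' @export
voxelwise_ttest <- function(mapsA, mapsB) {
  if (length(mapsA) < 2 || length(mapsB) < 2)
    stop("each group needs at least 2 maps")
  A <- as_value_matrix(mapsA); B <- as_value_matrix(mapsB)
  if (!same_grid(A$grid, B$grid)) stop("groups must share one grid")
  t <- pooled_t_matrix(A$X, B$X)
  t[colSums(!is.finite(A$X)) > 0 | colSums(!is.finite(B$X)) > 0] <- NA_real_
  structure(list(image = volume_image(array(t, dim(A$grid$values)),
                                      A$grid$affine),
                 dof = nrow(A$X) + nrow(B$X) - 2,
                 nA = nrow(A$X), nB = nrow(B$X),
                 threshold = NULL),
            class = "t_map")
}

#' @export
print.t_map <- function(x, ...) {
  cat(sprintf("<t_map> contrast A > B, nA = %d, nB = %d, dof = %d\n",
              x$nA, x$nB, x$dof))
  tv <- x$image$values[is.finite(x$image$values)]
  if (length(tv)) cat(sprintf("  t range: [%.3f, %.3f] over %d voxels\n",
                              min(tv), max(tv), length(tv)))
  if (!is.null(x$threshold))
    cat(sprintf("  threshold: %s, alpha = %g, critical t = %.3f, %d significant voxels\n",
                x$threshold$method, x$threshold$alpha,
                x$threshold$critical_value, sum(x$significant)))
  invisible(x)
}

# max-T permutation null for the contrast "first nA rows > rest".
# Enumerates all relabellings when their number is small; otherwise draws
# random relabellings (the observed labelling is always included).
perm_maxt_null <- function(X, nA, n_perm = 1000, seed = 1L,
                           exact_limit = 10000) {
  n <- nrow(X); nB <- n - nA
  n_total <- choose(n, nA)
  if (n_total <= exact_limit) {
    combs <- utils::combn(n, nA)
    P <- matrix(0, ncol(combs), n)
    for (j in seq_len(ncol(combs))) P[j, combs[, j]] <- 1
  } else {
    if (n_perm < 100) warning("fewer than 100 permutations is unreliable")
    P <- with_seed(seed, t(vapply(seq_len(n_perm), function(i) {
      z <- numeric(n); z[sample.int(n, nA)] <- 1; z
    }, numeric(n))))
    P <- rbind(c(rep(1, nA), rep(0, nB)), P)     # include observed labelling
  }
  ok <- colSums(!is.finite(X)) == 0
  Xo <- X[, ok, drop = FALSE]
  tot <- colSums(Xo); ss_tot <- colSums(Xo^2)
  SA <- P %*% Xo
  mA <- SA / nA
  mB <- sweep(-SA, 2, tot, "+") / nB
  ssw <- sweep(-(nA * mA^2 + nB * mB^2), 2, ss_tot, "+")
  sp2 <- ssw / (n - 2)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  tmat <- (mA - mB) / se
  tmat[se <= 0 | !is.finite(se)] <- NA_real_
  apply(tmat, 1, max, na.rm = TRUE)
}

#' Family-wise error threshold for a voxel-wise t map
#'
#' Permutation max-T (default): the null distribution of the maximum t over
#' voxels is built from group-label relabellings (exhaustive when at most
#' `exact_limit` relabellings exist, otherwise `n_perm` random draws plus
#' the observed labelling); a voxel is significant when its FWE-corrected
#' p-value, the fraction of null maxima at or above its t, is `<= alpha`.
#' Bonferroni: one-sided parametric p compared against `alpha / V`.
#'
#' @param tmap a `t_map` from [voxelwise_ttest()].
#' @param mapsA,mapsB the source maps (required for `method =
#'   "permutation"`).
#' @param alpha family-wise error level.
#' @param method `"permutation"` or `"bonferroni"`.
#' @param n_perm number of random relabellings.
#' @param seed integer seed for the relabellings.
#' @param exact_limit enumerate all relabellings when their count is at most
#'   this.
#' @return `tmap` with added `significant` (logical array), `p_fwe` (array),
#'   and `threshold` record (method, alpha, n_perm, seed, critical value).
#' @export
fwe_threshold <- function(tmap, mapsA = NULL, mapsB = NULL, alpha = 0.05,
                          method = c("permutation", "bonferroni"),
                          n_perm = 1000, seed = 1L, exact_limit = 10000) {
  method <- match.arg(method)
  stopifnot(inherits(tmap, "t_map"))
  tv <- as.numeric(tmap$image$values)
  tested <- is.finite(tv)
  p_fwe <- rep(NA_real_, length(tv))
  if (method == "permutation") {
    if (is.null(mapsA) || is.null(mapsB))
      stop("permutation thresholding needs the source maps")
    A <- as_value_matrix(mapsA); B <- as_value_matrix(mapsB)
    X <- rbind(A$X, B$X)
    null_max <- perm_maxt_null(X, nrow(A$X), n_perm = n_perm, seed = seed,
                               exact_limit = exact_limit)
    M <- length(null_max)
    ord <- sort(null_max)
    # p_fwe(t) = #{null >= t} / M via binary search on the sorted null
    cnt_ge <- function(t) M - findInterval(t - .Machine$double.eps^0.5, ord)
    p_fwe[tested] <- vapply(tv[tested], cnt_ge, numeric(1)) / M
    k <- floor(alpha * M)
    critical <- if (k >= 1) sort(null_max, decreasing = TRUE)[k] else Inf
    null_dist <- null_max
  } else {
    V <- sum(tested)
    p1 <- stats::pt(tv[tested], df = tmap$dof, lower.tail = FALSE)
    p_fwe[tested] <- pmin(1, p1 * V)
    critical <- stats::qt(alpha / V, df = tmap$dof, lower.tail = FALSE)
    null_dist <- NULL
  }
  sig <- array(FALSE, dim(tmap$image$values))
  sig[tested] <- p_fwe[tested] <= alpha
  tmap$significant <- sig
  tmap$p_fwe <- array(p_fwe, dim(tmap$image$values))
  tmap$threshold <- list(method = method, alpha = alpha,
                         n_perm = if (method == "permutation") n_perm else NA,
                         seed = if (method == "permutation") seed else NA,
                         critical_value = critical)
  tmap$null_max <- null_dist
  tmap
}
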