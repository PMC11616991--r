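# Molecular-map comparison: reslicing, PET aggregation, compound
# parcellation, parcel profiles, and compartment-wise spatial rank
# correlations with permutation significance.

#' Reslice a volume onto another grid
#'
#' Resamples values at the target grid's voxel centers, mapping through both
#' affines. Use `"linear"` (trilinear) for intensity images and
#' `"nearest"` for label images. Target voxels falling outside the source
#' bounding box (or touching missing source voxels, for linear) are `NA`.
#'
#' @param img source `volume_image`.
#' @param target_grid `volume_image` defining the output grid.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return A `volume_image` on the target grid.
#' @export
reslice <- function(img, target_grid, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(is_volume_image(img), is_volume_image(target_grid))
  if (same_grid(img, target_grid)) return(volume_image(img$values, img$affine))
  d_t <- dim(target_grid$values); d_s <- dim(img$values)
  mm <- voxel_center_mm(target_grid)
  v <- mm_to_vox(mm, img$affine)
  out <- rep(NA_real_, prod(d_t))
  if (interpolation == "nearest") {
    vr <- round(v)
    ok <- vr[, 1] >= 0 & vr[, 2] >= 0 & vr[, 3] >= 0 &
      vr[, 1] < d_s[1] & vr[, 2] < d_s[2] & vr[, 3] < d_s[3]
    idx <- 1L + vr[ok, 1] + d_s[1] * (vr[ok, 2] + d_s[2] * vr[ok, 3])
    out[ok] <- img$values[idx]
  } else {
    v0 <- floor(v)
    fr <- v - v0
    ok <- v0[, 1] >= -1 & v0[, 2] >= -1 & v0[, 3] >= -1 &
      v0[, 1] < d_s[1] & v0[, 2] < d_s[2] & v0[, 3] < d_s[3]
    # strict in-bounds for all 8 corners (no extrapolation at the border)
    ok <- ok & v0[, 1] >= 0 & v0[, 2] >= 0 & v0[, 3] >= 0 &
      v0[, 1] + 1 < d_s[1] & v0[, 2] + 1 < d_s[2] & v0[, 3] + 1 < d_s[3]
    if (any(ok)) {
      b <- v0[ok, , drop = FALSE]
      f <- fr[ok, , drop = FALSE]
      acc <- numeric(sum(ok))
      for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        w <- (if (dx) f[, 1] else 1 - f[, 1]) *
          (if (dy) f[, 2] else 1 - f[, 2]) *
          (if (dz) f[, 3] else 1 - f[, 3])
        idx <- 1L + (b[, 1] + dx) + d_s[1] * ((b[, 2] + dy) +
                                                d_s[2] * (b[, 3] + dz))
        acc <- acc + w * img$values[idx]
      }
      out[ok] <- acc
    }
  }
  if (!any(is.finite(out)))
    stop("source and target grids do not overlap")
  volume_image(array(out, d_t), target_grid$affine)
}

#' Aggregate molecular (PET) maps into one normalised image
#'
#' Each map is resliced to the first map's grid (linear), standardised to
#' mean 0 / SD 1 across in-brain (finite, in-mask) voxels — tracer units are
#' not comparable across radioligands, so maps are z-scored before mixing —
#' and then averaged voxel-wise.
#'
#' @param maps list of `volume_image` objects (>= 1).
#' @param mask optional `volume_image`; voxels with value > 0 define the
#'   in-brain set.
#' @return A `volume_image` (the aggregate z map).
#' @export
aggregate_pet <- function(maps, mask = NULL) {
  if (!length(maps)) stop("no maps to aggregate")
  g <- maps[[1]]
  maps <- lapply(maps, function(m)
    if (same_grid(m, g)) m else reslice(m, g, "linear"))
  keep <- array(TRUE, dim(g$values))
  if (!is.null(mask)) {
    if (!same_grid(mask, g)) mask <- reslice(mask, g, "nearest")
    keep <- is.finite(mask$values) & mask$values > 0
  }
  zs <- lapply(maps, function(m) {
    v <- m$values
    inb <- keep & is.finite(v)
    mu <- mean(v[inb]); sdv <- stats::sd(v[inb])
    if (!is.finite(sdv) || sdv == 0)
      stop("constant map cannot be standardised (SD = 0)")
    z <- (v - mu) / sdv
    z[!inb] <- NA_real_
    z
  })
  stack <- vapply(zs, as.numeric, numeric(length(g$values)))
  vals <- rowMeans(stack)
  volume_image(array(vals, dim(g$values)), g$affine)
}

#' Parcellation: integer label image plus lookup table
#'
#' @param image `volume_image` of integer labels (0 = unassigned).
#' @param lookup data frame with columns `label`, `name`, `compartment`
#'   (`"cortex"`, `"basal_ganglia"`, or `"cerebellum"`), and `source`.
#' @return An object of class `parcellation`.
#' @export
parcellation <- function(image, lookup) {
  stopifnot(is_volume_image(image))
  req <- c("label", "name", "compartment", "source")
  if (!all(req %in% names(lookup)))
    stop("lookup needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(lookup$label)) stop("labels must be unique")
  structure(list(image = image, lookup = lookup), class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d regions (%s)\n", nrow(x$lookup),
              paste(sprintf("%s: %d", names(table(x$lookup$compartment)),
                            table(x$lookup$compartment)), collapse = ", ")))
  invisible(x)
}

#' Combine atlases into a compound parcellation
#'
#' Atlases are resliced (nearest-neighbour) to a common grid and voxels are
#' claimed in precedence order: the first atlas listed wins overlapping
#' voxels. Regions whose voxel set ends up empty are dropped; duplicate
#' region names across atlases are suffixed with the atlas id. Labels are
#' renumbered 1..K in claim order.
#'
#' @param atlases list; each element a list with `image` (label
#'   `volume_image`), `lookup` (data frame: label, name), `compartment`
#'   (one compartment for the whole atlas), and `id`.
#' @param grid target grid; defaults to the first atlas's grid.
#' @param precedence ordering of atlases for voxel claiming (indices into
#'   `atlases`); default is the listed order.
#' @return A [parcellation()].
#' @export
build_compound_parcellation <- function(atlases, grid = NULL,
                                        precedence = seq_along(atlases)) {
  if (is.null(grid)) grid <- atlases[[1]]$image
  lab_out <- array(0L, dim(grid$values))
  lut <- NULL
  seen_names <- character()
  next_label <- 1L
  for (ai in precedence) {
    at <- atlases[[ai]]
    img <- if (same_grid(at$image, grid)) at$image
    else reslice(at$image, grid, "nearest")
    lv <- round(img$values)
    lv[!is.finite(lv)] <- 0
    for (l in sort(unique(lv[lv > 0]))) {
      claim <- lv == l & lab_out == 0L
      if (!any(claim)) next                       # fully shadowed: dropped
      nm <- at$lookup$name[match(l, at$lookup$label)]
      if (is.na(nm)) nm <- paste0("region", l)
      if (nm %in% seen_names) {
        nm2 <- paste0(nm, "_", at$id)
        message("duplicate region name '", nm, "' renamed to '", nm2, "'")
        nm <- nm2
      }
      seen_names <- c(seen_names, nm)
      lab_out[claim] <- next_label
      lut <- rbind(lut, data.frame(label = next_label, name = nm,
                                   compartment = at$compartment,
                                   source = at$id,
                                   stringsAsFactors = FALSE))
      next_label <- next_label + 1L
    }
  }
  if (is.null(lut)) stop("no regions claimed any voxels")
  parcellation(volume_image(lab_out, grid$affine), lut)
}

#' Per-parcel mean values of an image
#'
#' The image is resliced (linear) onto the parcellation grid if needed; each
#' parcel's value is the mean of its non-missing voxels. Parcels with no
#' non-missing voxel are flagged missing (`NA` mean).
#'
#' @param img a `volume_image` (or [connectivity_map()]).
#' @param parc a [parcellation()].
#' @param mask optional `volume_image` restricting the voxels used.
#' @return A data frame of class `parcel_profile`: label, name, compartment,
#'   value, n_voxels.
#' @export
parcel_profile <- function(img, parc, mask = NULL) {
  stopifnot(inherits(parc, "parcellation"))
  if (inherits(img, "connectivity_map")) img <- img$image
  if (!same_grid(img, parc$image)) img <- reslice(img, parc$image, "linear")
  v <- as.numeric(img$values)
  lab <- as.integer(round(parc$image$values))
  if (!is.null(mask)) {
    if (!same_grid(mask, parc$image)) mask <- reslice(mask, parc$image, "nearest")
    v[!(is.finite(mask$values) & mask$values > 0)] <- NA_real_
  }
  ok <- is.finite(v) & lab > 0
  sums <- tapply(v[ok], lab[ok], sum)
  cnts <- tapply(v[ok], lab[ok], length)
  out <- parc$lookup[, c("label", "name", "compartment")]
  i <- match(out$label, as.integer(names(sums)))
  out$value <- as.numeric(sums[i]) / as.numeric(cnts[i])
  out$n_voxels <- ifelse(is.na(i), 0L, as.integer(cnts[i]))
  class(out) <- c("parcel_profile", "data.frame")
  out
}

align_profiles <- function(a, b) {
  if (inherits(a, "parcel_profile") && inherits(b, "parcel_profile")) {
    common <- intersect(a$label, b$label)
    ia <- match(common, a$label); ib <- match(common, b$label)
    list(x = a$value[ia], y = b$value[ib], compartment = a$compartment[ia])
  } else {
    x <- if (inherits(a, "parcel_profile")) a$value else as.numeric(a)
    y <- if (inherits(b, "parcel_profile")) b$value else as.numeric(b)
    if (length(x) != length(y)) stop("profiles differ in length")
    comp <- if (inherits(a, "parcel_profile")) a$compartment
    else if (inherits(b, "parcel_profile")) b$compartment
    else rep(NA_character_, length(x))
    list(x = x, y = y, compartment = comp)
  }
}

#' Spatial Spearman correlation between two parcel profiles
#'
#' Spearman's rho on the (optionally compartment-restricted) common
#' non-missing parcels, with a two-sided permutation p-value: parcel values
#' of one profile are permuted without restriction, and
#' `p = (1 + #permutations with |rho| >= |observed|) / (1 + n_perm)` (the
#' add-one estimator; the minimum attainable p is `1 / (n_perm + 1)`). With
#' `exact = TRUE` (only for small n) all `n!` permutations are enumerated
#' and `p = #{|rho_perm| >= |rho|} / n!`.
#'
#' @param profile_a,profile_b [parcel_profile()] objects (aligned by label)
#'   or bare numeric vectors of equal length.
#' @param compartment optional compartment name to restrict to.
#' @param n_perm number of random permutations.
#' @param seed integer seed.
#' @param exact enumerate all permutations (requires n <= 8).
#' @return List: `rho`, `p_value`, `n` (parcels used), `n_perm`, `method`.
#' @export
spatial_spearman <- function(profile_a, profile_b, compartment = NULL,
                             n_perm = 9999, seed = 1L, exact = FALSE) {
  al <- align_profiles(profile_a, profile_b)
  x <- al$x; y <- al$y
  if (!is.null(compartment)) {
    sel <- al$compartment == compartment
    x <- x[sel]; y <- y[sel]
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("need at least 5 common non-missing parcels")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant profile; rank correlation undefined")
  rx <- rank(x); ry <- rank(y)
  a0 <- rx - mean(rx); b0 <- ry - mean(ry)
  denom <- sqrt(sum(a0^2) * sum(b0^2))
  rho <- sum(a0 * b0) / denom
  eps <- 1e-12
  if (exact) {
    if (n > 8) stop("exact enumeration limited to n <= 8")
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(p) sum(a0 * b0[p]) / denom)
    p <- mean(abs(rhos) >= abs(rho) - eps)
    list(rho = rho, p_value = p, n = n, n_perm = nrow(perms),
         method = "exact permutation")
  } else {
    hits <- with_seed(seed, {
      h <- 0L
      for (i in seq_len(n_perm)) {
        r <- sum(a0 * b0[sample.int(n)]) / denom
        if (abs(r) >= abs(rho) - eps) h <- h + 1L
      }
      h
    })
    p <- (1 + hits) / (1 + n_perm)
    list(rho = rho, p_value = p, n = n, n_perm = n_perm,
         method = "permutation")
  }
}

# all n! permutations of 1..n as rows (recursion; small n only)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, matrix(c(seq_len(n)[-k])[sub], nrow(sub)))
    out <- rbind(out, block)
  }
  out
}

#' Cross-correlate connectivity maps with molecular maps by compartment
#'
#' Full cross of connectivity maps x tracer maps x compartments: each pair
#' is profiled on the parcellation and compared with [spatial_spearman()];
#' a Benjamini-Hochberg adjusted p-value column spans the whole report.
#'
#' @param conn_maps named list of connectivity images (`volume_image` or
#'   [connectivity_map()]).
#' @param pet_maps named list of molecular images (`volume_image`).
#' @param parc a [parcellation()].
#' @param compartments compartment names to report.
#' @param n_perm,seed permutation settings for each correlation.
#' @param mask optional mask for profiling.
#' @return Data frame: map, tracer, compartment, n_parcels, rho, p_value,
#'   p_adj.
#' @export
compartment_report <- function(conn_maps, pet_maps, parc,
                               compartments = c("cortex", "basal_ganglia",
                                                "cerebellum"),
                               n_perm = 9999, seed = 1L, mask = NULL) {
  conn_prof <- lapply(conn_maps, parcel_profile, parc = parc, mask = mask)
  pet_prof <- lapply(pet_maps, parcel_profile, parc = parc, mask = mask)
  rows <- list()
  k <- 0L
  for (cm in names(conn_prof)) for (tr in names(pet_prof))
    for (cp in compartments) {
      k <- k + 1L
      # degenerate pairs (constant or near-empty compartment profile) are
      # reported as missing rather than aborting the whole report
      res <- tryCatch(
        spatial_spearman(conn_prof[[cm]], pet_prof[[tr]],
                         compartment = cp, n_perm = n_perm,
                         seed = seed + k),
        error = function(e) list(n = NA_integer_, rho = NA_real_,
                                 p_value = NA_real_))
      rows[[k]] <- data.frame(map = cm, tracer = tr, compartment = cp,
                              n_parcels = res$n, rho = res$rho,
                              p_value = res$p_value,
                              stringsAsFactors = FALSE)
    }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
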