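# Seed-based connectivity mapping: spherical seed images, Gaussian
# smoothing, normative functional maps (Fisher-z averaged across subjects),
# grey-matter masking, streamline-count structural maps, group aggregation.

#' Binary spherical seed image around an MNI coordinate
#'
#' A voxel is set to 1 iff its center lies within `radius_mm` of the
#' coordinate (with `radius_mm = 0`, exactly the containing voxel).
#'
#' @param mni_xyz length-3 mm coordinate.
#' @param radius_mm sphere radius in mm.
#' @param grid template `volume_image` defining shape and affine.
#' @return A binary `volume_image`.
#' @export
make_seed_image <- function(mni_xyz, radius_mm = 5, grid = mni_grid()) {
  stopifnot(is_volume_image(grid))
  d <- dim(grid$values)
  v0 <- mm_to_vox(mni_xyz, grid$affine)
  if (any(v0 < -0.5) || any(v0 > d - 0.5))
    stop("seed coordinate outside the template bounding box")
  vals <- array(0, d)
  if (radius_mm <= 0) {
    v <- pmin(pmax(round(v0), 0), d - 1L)
    vals[v[1] + 1L, v[2] + 1L, v[3] + 1L] <- 1
  } else {
    # restrict the search to the bounding cube of the sphere
    vs <- voxel_sizes(grid$affine)
    lo <- pmax(floor(v0 - radius_mm / vs - 1), 0)
    hi <- pmin(ceiling(v0 + radius_mm / vs + 1), d - 1L)
    ii <- seq.int(lo[1], hi[1]); jj <- seq.int(lo[2], hi[2])
    kk <- seq.int(lo[3], hi[3])
    idx <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
    mm <- vox_to_mm(idx, grid$affine)
    inside <- (mm[, 1] - mni_xyz[1])^2 + (mm[, 2] - mni_xyz[2])^2 +
      (mm[, 3] - mni_xyz[3])^2 <= radius_mm^2
    if (!any(inside)) stop("sphere contains no voxel center inside the grid")
    sel <- idx[inside, , drop = FALSE] + 1L
    vals[sel] <- 1
  }
  volume_image(vals, grid$affine)
}

# 1-D Gaussian kernel, discretely normalised to sum 1
gauss_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# convolve along one array axis with zero padding at the borders
conv_axis <- function(a, k, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  r <- (length(k) - 1L) / 2L
  n <- nrow(m)
  padded <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
  out <- matrix(0, n, ncol(m))
  for (s in seq_along(k))
    out <- out + k[s] * padded[seq.int(s, s + n - 1L), , drop = FALSE]
  res <- array(out, dim = d[perm])
  aperm(res, order(perm))
}

#' Gaussian smoothing of a volume (SD in mm)
#'
#' Separable convolution with a discretely normalised Gaussian kernel; the
#' SD in mm is converted per axis using the voxel sizes from the affine.
#' Border handling is edge-renormalised: the convolution is divided by the
#' convolution of an all-ones image, so constant images pass through
#' unchanged, and total intensity is conserved for images whose support
#' stays clear of the borders.
#'
#' @param img a `volume_image` (finite values; missing voxels are treated
#'   as 0 and restored to missing afterwards).
#' @param sigma_mm Gaussian SD in mm.
#' @return Smoothed `volume_image`.
#' @export
smooth_volume <- function(img, sigma_mm = 8) {
  stopifnot(is_volume_image(img))
  if (sigma_mm <= 0) return(img)
  vs <- voxel_sizes(img$affine)
  vals <- img$values
  na_mask <- !is.finite(vals)
  if (any(na_mask)) vals[na_mask] <- 0
  ones <- array(1, dim(vals))
  for (ax in 1:3) {
    k <- gauss_kernel(sigma_mm / vs[ax])
    vals <- conv_axis(vals, k, ax)
    ones <- conv_axis(ones, k, ax)
  }
  vals <- vals / ones
  if (any(na_mask)) vals[na_mask] <- NA_real_
  volume_image(vals, img$affine)
}

#' Connectivity map container
#' @param image a `volume_image`.
#' @param modality `"functional"` or `"structural"`.
#' @param seed_channel_id optional channel identifier.
#' @param group optional group tag (e.g. dominant band).
#' @return An object of class `connectivity_map`.
#' @export
connectivity_map <- function(image, modality = c("functional", "structural"),
                             seed_channel_id = NULL, group = NULL) {
  modality <- match.arg(modality)
  stopifnot(is_volume_image(image))
  if (modality == "structural") {
    v <- image$values[is.finite(image$values)]
    if (length(v) && any(v < 0))
      stop("structural connectivity values must be non-negative counts")
  }
  structure(list(image = image, modality = modality,
                 seed_channel_id = seed_channel_id, group = group),
            class = "connectivity_map")
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat(sprintf("<connectivity_map> %s%s%s\n", x$modality,
              if (!is.null(x$seed_channel_id))
                paste0(", seed ", x$seed_channel_id) else "",
              if (!is.null(x$group)) paste0(", group ", x$group) else ""))
  print(x$image)
  invisible(x)
}

# cap |r| below 1 so the Fisher transform stays finite
fisher_z <- function(r, cap = 0.999999) atanh(pmin(pmax(r, -cap), cap))

#' Seed-based functional connectivity map from a normative connectome
#'
#' Per subject, the seed time series is the mean signal over in-brain seed
#' voxels; its Pearson correlation with every in-brain voxel is Fisher
#' z-transformed, and z maps are averaged across subjects.
#'
#' @param seed_img binary `volume_image` on the connectome grid (e.g. from
#'   [make_seed_image()]).
#' @param connectome a `connectome` (see [gen_connectome()]).
#' @param seed_channel_id,group passed through to the result.
#' @return A functional [connectivity_map()] (z values; out-of-brain voxels
#'   `NA`).
#' @export
functional_map <- function(seed_img, connectome, seed_channel_id = NULL,
                           group = NULL) {
  stopifnot(inherits(connectome, "connectome"))
  if (length(connectome$data) < 2) stop("connectome must hold >= 2 subjects")
  if (!same_grid(seed_img, connectome$grid))
    stop("seed image must live on the connectome grid")
  seed_in <- seed_img$values[connectome$mask] > 0
  if (!any(seed_in)) stop("seed overlaps no in-brain voxels")
  zsum <- 0
  for (X in connectome$data) {
    seed_ts <- rowMeans(X[, seed_in, drop = FALSE])
    r <- suppressWarnings(stats::cor(seed_ts, X))
    r[!is.finite(r)] <- 0                  # zero-variance voxels
    zsum <- zsum + fisher_z(as.numeric(r))
  }
  zbar <- zsum / length(connectome$data)
  vals <- array(NA_real_, dim(connectome$grid$values))
  vals[connectome$mask] <- zbar
  connectivity_map(volume_image(vals, connectome$grid$affine), "functional",
                   seed_channel_id, group)
}

#' Mask a map to grey matter
#'
#' Voxels outside the mask become missing (`NA`). A mask on a different grid
#' is resliced to the map's grid with nearest-neighbour interpolation first.
#'
#' @param map a [connectivity_map()] or `volume_image`.
#' @param gm_mask `volume_image`; voxels with value > 0 are kept.
#' @return Same class as `map`.
#' @export
apply_gm_mask <- function(map, gm_mask) {
  img <- if (inherits(map, "connectivity_map")) map$image else map
  if (!same_grid(gm_mask, img))
    gm_mask <- reslice(gm_mask, img, interpolation = "nearest")
  keep <- is.finite(gm_mask$values) & gm_mask$values > 0
  if (!any(keep)) stop("grey-matter mask is empty")
  vals <- img$values
  vals[!keep] <- NA_real_
  out <- volume_image(vals, img$affine)
  if (inherits(map, "connectivity_map")) {
    map$image <- out
    map
  } else out
}

# unique voxel indices (1-based matrix rows) traversed by a polyline,
# sampled at sub-voxel steps along each segment
streamline_voxels <- function(sl, grid) {
  d <- dim(grid$values)
  step <- min(voxel_sizes(grid$affine)) / 2
  pts <- list()
  for (s in seq_len(nrow(sl) - 1L)) {
    a <- sl[s, ]; b <- sl[s + 1L, ]
    len <- sqrt(sum((b - a)^2))
    n <- max(2L, ceiling(len / step) + 1L)
    tt <- seq(0, 1, length.out = n)
    pts[[s]] <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]),
                      a[3] + tt * (b[3] - a[3]))
  }
  mm <- do.call(rbind, pts)
  v <- round(mm_to_vox(mm, grid$affine))
  ok <- v[, 1] >= 0 & v[, 2] >= 0 & v[, 3] >= 0 &
    v[, 1] < d[1] & v[, 2] < d[2] & v[, 3] < d[3]
  v <- v[ok, , drop = FALSE]
  if (!nrow(v)) return(integer())
  unique(1L + v[, 1] + d[1] * (v[, 2] + d[2] * v[, 3]))
}

# shortest distance from point p to segment a-b
point_segment_dist <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab^2)
  t <- min(max(t, 0), 1)
  sqrt(sum((a + t * ab - p)^2))
}

#' Structural connectivity map: streamlines through a spherical seed
#'
#' Selects streamlines passing within `radius_mm` of the seed center and
#' returns the per-voxel count of selected streamlines traversing each voxel
#' (each streamline counted once per voxel). Seed inclusion is point-based
#' by default (any polyline vertex within the radius); with
#' `selection = "segment"`, a segment crossing the sphere between two
#' vertices also counts.
#'
#' @param seed_xyz length-3 mm seed center.
#' @param radius_mm selection radius in mm.
#' @param streamlines a [streamline_set()].
#' @param grid template `volume_image`.
#' @param selection `"point"` or `"segment"`.
#' @param seed_channel_id,group passed through to the result.
#' @return A structural [connectivity_map()] (counts; an empty selection
#'   gives an all-zero map).
#' @export
structural_map <- function(seed_xyz, radius_mm = 5, streamlines,
                           grid = mni_grid(),
                           selection = c("point", "segment"),
                           seed_channel_id = NULL, group = NULL) {
  selection <- match.arg(selection)
  stopifnot(inherits(streamlines, "streamline_set"))
  counts <- array(0, dim(grid$values))
  for (sl in streamlines) {
    d2 <- (sl[, 1] - seed_xyz[1])^2 + (sl[, 2] - seed_xyz[2])^2 +
      (sl[, 3] - seed_xyz[3])^2
    hit <- any(d2 <= radius_mm^2)
    if (!hit && selection == "segment") {
      for (s in seq_len(nrow(sl) - 1L)) {
        if (point_segment_dist(seed_xyz, sl[s, ], sl[s + 1L, ]) <= radius_mm) {
          hit <- TRUE; break
        }
      }
    }
    if (!hit) next
    vox <- streamline_voxels(sl, grid)
    counts[vox] <- counts[vox] + 1
  }
  connectivity_map(volume_image(counts, grid$affine), "structural",
                   seed_channel_id, group)
}

#' Aggregate connectivity maps of one modality
#'
#' Functional maps are averaged voxel-wise (missing-aware); structural maps
#' are summed (streamline counts are additive across seeds).
#'
#' @param maps list of [connectivity_map()] objects, all on one grid and of
#'   one modality.
#' @param modality expected modality; mixing modalities is an error.
#' @return A `volume_image`.
#' @export
group_aggregate <- function(maps, modality = c("functional", "structural")) {
  modality <- match.arg(modality)
  if (!length(maps)) stop("no maps to aggregate")
  mods <- vapply(maps, function(m) m$modality, character(1))
  if (!all(mods == modality))
    stop("mixed or unexpected modalities in `maps`")
  g <- maps[[1]]$image
  for (m in maps[-1])
    if (!same_grid(m$image, g)) stop("all maps must share one grid")
  stack <- vapply(maps, function(m) as.numeric(m$image$values),
                  numeric(length(g$values)))
  vals <- if (modality == "functional") rowMeans(stack, na.rm = TRUE)
  else rowSums(stack)
  vals[is.nan(vals)] <- NA_real_
  volume_image(array(vals, dim(g$values)), g$affine)
}
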