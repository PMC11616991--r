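# Network mapping: seed spheres, smoothing, functional and structural
# connectivity maps, masking, group aggregation.

test_that("make_seed_image matches brute-force voxel enumeration", {
  grid <- mni_grid(c(20, 20, 20), voxel_mm = 2)
  ctr <- vox_to_mm(c(10, 10, 10), grid$affine)

  seed <- make_seed_image(ctr, 5, grid)
  expect_equal(sum(seed$values), oracle_sphere_count(ctr, 5, grid))
  expect_equal(sum(seed$values), 81)   # 2 mm grid, r = 5, center on a voxel

  # degenerate radius selects exactly the containing voxel
  expect_equal(sum(make_seed_image(ctr, 0, grid)$values), 1)

  # translating by one full voxel leaves the count unchanged
  ctr2 <- vox_to_mm(c(11, 10, 10), grid$affine)
  expect_equal(sum(make_seed_image(ctr2, 5, grid)$values), 81)

  expect_error(make_seed_image(c(500, 0, 0), 5, grid), "bounding box")
})

test_that("smooth_volume conserves intensity and preserves constants", {
  grid <- mni_grid(c(33, 33, 33), voxel_mm = 2)

  delta <- grid; delta$values[17, 17, 17] <- 1
  sm <- smooth_volume(delta, sigma_mm = 4)
  expect_equal(max(sm$values), oracle_gauss3d_peak(rep(4 / 2, 3)),
               tolerance = 1e-9)
  expect_equal(which.max(sm$values), which.max(delta$values))
  expect_equal(sum(sm$values), 1, tolerance = 1e-6)   # interior support

  const <- volume_image(array(3.7, c(33, 33, 33)), grid$affine)
  smc <- smooth_volume(const, sigma_mm = 8)
  expect_lt(max(abs(smc$values - 3.7)), 1e-9)
})

test_that("functional_map equals a closed-form correlation oracle on a toy", {
  grid <- mni_grid(c(3, 1, 1), voxel_mm = 2)
  comm <- volume_image(array(1L, c(3, 1, 1)), grid$affine)
  X <- matrix(c(1, 2, 3, 4,
                2, 1, 4, 3,
                4, 3, 2, 1), ncol = 3)
  cn <- structure(list(grid = comm, mask = array(TRUE, c(3, 1, 1)),
                       voxel_labels = rep(1L, 3), data = list(X, X)),
                  class = "connectome")
  seed <- volume_image(array(c(1, 0, 0), c(3, 1, 1)), grid$affine)
  m <- functional_map(seed, cn)
  r_oracle <- as.numeric(cor(X[, 1], X))
  expect_equal(tanh(m$image$values[2, 1, 1]), r_oracle[2], tolerance = 1e-9)
  # perfectly (anti)correlated voxels are capped before the Fisher transform
  expect_equal(tanh(m$image$values[3, 1, 1]), -0.999999, tolerance = 1e-9)
  expect_equal(r_oracle[3], -1, tolerance = 1e-12)
  expect_equal(tanh(m$image$values[1, 1, 1]), 0.999999, tolerance = 1e-9)

  # invariance to positive rescaling of a subject's signals
  cn2 <- cn; cn2$data[[2]] <- 5.3 * cn2$data[[2]]
  m2 <- functional_map(seed, cn2)
  expect_equal(m2$image$values, m$image$values, tolerance = 1e-12)

  expect_error(functional_map(volume_image(array(0, c(3, 1, 1)),
                                           grid$affine), cn),
               "no in-brain voxels")
})

test_that("functional_map recovers the designed network correlation", {
  grid <- mni_grid(c(8, 8, 4), voxel_mm = 2)
  lab <- array(1L, c(8, 8, 4)); lab[, 5:8, ] <- 2L
  comm <- volume_image(lab, grid$affine)
  cn <- gen_connectome(20, comm, n_timepoints = 100, within_r = 0.6,
                       seed = 31)
  seed_img <- volume_image(array(as.numeric(lab == 1L & seq_along(lab) <= 4),
                                 dim(lab)), grid$affine)
  m <- functional_map(seed_img, cn)
  # a single-voxel seed's own-network voxels should sit near z(0.6)
  seed1 <- volume_image(array(0, dim(lab)), grid$affine)
  seed1$values[1, 1, 1] <- 1
  m1 <- functional_map(seed1, cn)
  inA <- lab == 1L; inA[1, 1, 1] <- FALSE
  expect_lt(abs(mean(m1$image$values[inA]) - atanh(0.6)), 0.05)
  expect_lt(abs(mean(m1$image$values[lab == 2L])), 0.05)
})

test_that("apply_gm_mask keeps exactly the masked voxels", {
  grid <- mni_grid(c(6, 6, 6), voxel_mm = 2)
  img <- volume_image(array(rnorm(216), c(6, 6, 6)), grid$affine)

  full <- volume_image(array(1, c(6, 6, 6)), grid$affine)
  expect_equal(apply_gm_mask(img, full)$values, img$values)

  half <- volume_image(array(rep(c(1, 0), each = 108), c(6, 6, 6)),
                       grid$affine)
  masked <- apply_gm_mask(img, half)
  expect_equal(sum(is.finite(masked$values)), 108)
  expect_equal(masked$values[half$values > 0], img$values[half$values > 0])
  expect_true(all(is.na(masked$values[half$values == 0])))

  expect_error(apply_gm_mask(img, volume_image(array(0, c(6, 6, 6)),
                                               grid$affine)), "empty")
})

test_that("structural_map counts selected streamlines per voxel", {
  grid <- mni_grid(c(21, 21, 21), voxel_mm = 2)
  straight <- cbind(seq(-18, 18, length.out = 40), 0, 0)

  m <- structural_map(c(0, 0, 0), 5, streamline_set(list(straight)), grid)
  vals <- m$image$values
  expect_true(all(vals %in% c(0, 1)))
  # traversed voxels lie along the x axis at y = z = 0
  hit <- which(vals == 1, arr.ind = TRUE)
  expect_true(all(hit[, 2] == 11 & hit[, 3] == 11))
  expect_gt(nrow(hit), 15)

  # 50 near-identical copies through the seed + 50 far away:
  # the seed-line voxels count exactly the selected bundle
  far <- cbind(seq(-18, 18, length.out = 40), 16, 16)
  tg <- gen_tractogram(list(straight, far), n_per_bundle = 50,
                       jitter_mm = 0.05, seed = 2)
  m2 <- structural_map(c(0, 0, 0), 5, tg, grid)
  expect_equal(max(m2$image$values), 50)
  # far bundle contributes nothing
  expect_equal(sum(m2$image$values[, 17:21, 17:21]), 0)

  # a sparse polyline crossing the sphere between vertices: excluded by the
  # point-based rule, included by segment-sphere intersection
  sparse <- rbind(c(-30, 0, 0), c(30, 0, 0))
  mp <- structural_map(c(0, 0, 8), 9, streamline_set(list(sparse)), grid,
                       selection = "point")
  ms <- structural_map(c(0, 0, 8), 9, streamline_set(list(sparse)), grid,
                       selection = "segment")
  expect_equal(sum(mp$image$values), 0)
  expect_gt(sum(ms$image$values), 0)
})

test_that("group_aggregate means functional and sums structural maps", {
  grid <- mni_grid(c(5, 5, 5), voxel_mm = 2)
  img <- function(v) volume_image(array(v, c(5, 5, 5)), grid$affine)
  f1 <- connectivity_map(img(rnorm(125)), "functional")
  fm <- group_aggregate(list(f1, f1), "functional")
  expect_equal(fm$values, f1$image$values)

  s1 <- connectivity_map(img(rep(2, 125)), "structural")
  s2 <- connectivity_map(img(rep(3, 125)), "structural")
  sm <- group_aggregate(list(s1, s2), "structural")
  expect_equal(unique(as.numeric(sm$values)), 5)

  # structural aggregation is exactly additive and order-invariant
  set.seed(3)
  maps <- lapply(1:4, function(i)
    connectivity_map(img(rpois(125, 2)), "structural"))
  agg <- group_aggregate(maps, "structural")
  expect_equal(sum(agg$values),
               sum(vapply(maps, function(m) sum(m$image$values), numeric(1))))
  expect_equal(group_aggregate(rev(maps), "structural")$values, agg$values)

  expect_error(group_aggregate(list(f1, s1), "functional"), "modalit")
})

test_that("the pipeline order smooth-then-mask differs from mask-then-smooth", {
  grid <- mni_grid(c(15, 15, 15), voxel_mm = 2)
  img <- volume_image(array(0, c(15, 15, 15)), grid$affine)
  img$values[8, 8, 8] <- 1
  mask <- volume_image(array(rep(c(1, 0), length.out = 15^3),
                             c(15, 15, 15)), grid$affine)
  a <- apply_gm_mask(smooth_volume(img, 6), mask)
  b <- smooth_volume(apply_gm_mask(img, mask), 6)
  ok <- is.finite(a$values) & is.finite(b$values)
  expect_gt(max(abs(a$values[ok] - b$values[ok])), 1e-6)
})
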