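# Molecular mapping: reslicing, PET aggregation, compound parcellation,
# parcel profiles, spatial Spearman with permutation nulls.

test_that("reslice is exact on identity, constants, and linear ramps", {
  grid <- mni_grid(c(8, 8, 8), voxel_mm = 2)
  img <- volume_image(array(rnorm(512), c(8, 8, 8)), grid$affine)
  expect_equal(reslice(img, grid)$values, img$values, tolerance = 1e-9)

  cst <- volume_image(array(2.5, c(8, 8, 8)), grid$affine)
  tgt <- mni_grid(c(3, 3, 3), voxel_mm = 4)
  expect_equal(unique(as.numeric(reslice(cst, tgt, "linear")$values[
    is.finite(reslice(cst, tgt, "linear")$values)])), 2.5, tolerance = 1e-9)

  # linear ramp in x: trilinear interpolation reproduces ramp values at the
  # coarser grid's voxel centers (closed form)
  mmsrc <- oscillonet:::voxel_center_mm(grid)
  ramp <- volume_image(array(mmsrc[, 1], c(8, 8, 8)), grid$affine)
  down <- mni_grid(c(4, 4, 4), voxel_mm = 4)
  got <- reslice(ramp, down, "linear")
  mmtgt <- oscillonet:::voxel_center_mm(down)
  ok <- is.finite(got$values)
  expect_equal(as.numeric(got$values)[ok], mmtgt[ok, 1], tolerance = 1e-9)

  # nearest keeps label values intact
  lab <- volume_image(array(sample(1:5, 512, TRUE), c(8, 8, 8)),
                      grid$affine)
  near <- reslice(lab, grid, "nearest")
  expect_equal(near$values, lab$values)

  far <- volume_image(array(1, c(4, 4, 4)),
                      rbind(c(2, 0, 0, 500), c(0, 2, 0, 500),
                            c(0, 0, 2, 500), c(0, 0, 0, 1)))
  expect_error(reslice(far, grid, "linear"), "overlap")
})

test_that("aggregate_pet standardises each tracer before averaging", {
  grid <- mni_grid(c(6, 6, 6), voxel_mm = 2)
  set.seed(41)
  x <- array(rnorm(216, 5, 2), c(6, 6, 6))
  m1 <- volume_image(x, grid$affine)

  agg1 <- aggregate_pet(list(m1))
  expect_equal(agg1$values, (x - mean(x)) / sd(x), tolerance = 1e-9)

  # maps that are affine transforms of one another aggregate to z(x)
  m2 <- volume_image(3 * x + 10, grid$affine)
  agg <- aggregate_pet(list(m1, m2))
  expect_equal(agg$values, (x - mean(x)) / sd(x), tolerance = 1e-9)

  # a designed shared component dominates the aggregate
  shared <- array(rnorm(216), c(6, 6, 6))
  better <- 0L
  for (i in 1:20) {
    maps <- lapply(1:4, function(k)
      volume_image(shared + array(rnorm(216, sd = 1.5), c(6, 6, 6)),
                   grid$affine))
    ag <- aggregate_pet(maps)
    r_ag <- cor(as.numeric(ag$values), as.numeric(shared))
    r_single <- max(vapply(maps, function(m)
      cor(as.numeric(m$values), as.numeric(shared)), numeric(1)))
    if (r_ag > r_single) better <- better + 1L
  }
  expect_gte(better, 18L)

  expect_error(aggregate_pet(list(volume_image(array(1, c(6, 6, 6)),
                                               grid$affine))), "constant")
})

test_that("build_compound_parcellation claims voxels by precedence", {
  grid <- mni_grid(c(10, 10, 4), voxel_mm = 2)
  blank <- array(0L, c(10, 10, 4))
  atlas <- function(blocks, id, compartment) {
    lab <- blank
    for (i in seq_along(blocks)) lab[blocks[[i]]] <- i
    list(image = volume_image(lab, grid$affine),
         lookup = data.frame(label = seq_along(blocks),
                             name = paste0(id, "_r", seq_along(blocks))),
         compartment = compartment, id = id)
  }
  # non-overlapping atlases: counts add
  a1 <- atlas(list(1:50, 51:100, 101:150), "ctx", "cortex")
  a2 <- atlas(list(151:180, 181:220, 221:260, 261:300), "bg",
              "basal_ganglia")
  p <- build_compound_parcellation(list(a1, a2))
  expect_equal(nrow(p$lookup), 7)

  # a region fully shadowed by an earlier atlas is dropped
  a3 <- atlas(list(1:50), "dup", "cerebellum")       # same voxels as ctx_r1
  p2 <- build_compound_parcellation(list(a1, a3))
  expect_equal(nrow(p2$lookup), 3)
  expect_false(any(p2$lookup$source == "dup"))

  # three partially overlapping atlases match a brute-force voxel-set oracle
  set.seed(43)
  mk <- sample(1:400, 360)
  a4 <- atlas(list(mk[1:120], mk[121:200]), "A", "cortex")
  a5 <- atlas(list(mk[81:240]), "B", "basal_ganglia")
  a6 <- atlas(list(mk[201:360], 380:399), "C", "cerebellum")
  p3 <- build_compound_parcellation(list(a4, a5, a6))
  # oracle: first-atlas-wins voxel claiming
  claimed <- integer(400)
  owner <- rep(NA_character_, 400)
  for (at in list(a4, a5, a6)) {
    lv <- at$image$values
    for (l in sort(unique(lv[lv > 0]))) {
      vox <- which(lv == l)
      vox <- vox[vox <= 400]
      free <- vox[claimed[vox] == 0]
      if (length(free)) {
        claimed[free] <- 1L
        owner[free] <- paste0(at$id, "_r", l)
      }
    }
  }
  surviving <- unique(stats::na.omit(owner))
  expect_equal(nrow(p3$lookup), length(surviving))
  expect_setequal(p3$lookup$name, surviving)
  # the result is a partition: labelled voxels carry exactly one label
  expect_true(all(p3$image$values[p3$image$values > 0] %in% p3$lookup$label))

  # every claimed voxel count matches
  expect_equal(sum(p3$image$values > 0), sum(claimed))
})

test_that("parcel_profile equals brute-force per-label means", {
  grid <- mni_grid(c(8, 8, 8), voxel_mm = 2)
  parc <- gen_parcellation(grid, 16)
  cst <- volume_image(array(4.2, c(8, 8, 8)), grid$affine)
  expect_equal(parcel_profile(cst, parc)$value, rep(4.2, 16),
               tolerance = 1e-12)

  labimg <- volume_image(array(as.numeric(parc$image$values), c(8, 8, 8)),
                         grid$affine)
  expect_equal(parcel_profile(labimg, parc)$value, as.numeric(1:16),
               tolerance = 1e-12)

  set.seed(47)
  rnd <- volume_image(array(rnorm(512), c(8, 8, 8)), grid$affine)
  rnd$values[1:30] <- NA
  prof <- parcel_profile(rnd, parc)
  oracle <- oracle_parcel_means(rnd$values, parc$image$values)
  expect_equal(prof$value, unname(oracle[as.character(prof$label)]),
               tolerance = 1e-12)
  expect_equal(sum(prof$n_voxels), sum(is.finite(rnd$values)))
})

test_that("spatial_spearman matches exhaustive enumeration and its p floor", {
  # identical profiles: rho 1, minimum attainable p (n large enough that no
  # random permutation reproduces |rho| = 1)
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8, seq_len(22) + 0.1)
  r <- spatial_spearman(x, x, n_perm = 9999, seed = 1)
  expect_equal(r$rho, 1)
  expect_equal(r$p_value, 1e-4)        # 1 / (n_perm + 1)

  # n = 6: exact enumeration equals an independent oracle
  set.seed(53)
  a <- rnorm(6); b <- 0.5 * a + rnorm(6)
  ex <- spatial_spearman(a, b, exact = TRUE)
  expect_equal(ex$n_perm, 720)
  expect_equal(ex$p_value, oracle_spearman_exact_p(a, b), tolerance = 1e-12)
  expect_equal(ex$rho, cor(a, b, method = "spearman"), tolerance = 1e-12)

  # rho is invariant under strictly monotone transforms
  set.seed(59)
  u <- rnorm(40); v <- rnorm(40)
  r1 <- spatial_spearman(u, v, n_perm = 99, seed = 2)
  r2 <- spatial_spearman(exp(u), v^3 + 2 * v, n_perm = 99, seed = 2)
  expect_equal(r2$rho, r1$rho, tolerance = 1e-12)

  expect_error(spatial_spearman(rep(1, 10), rnorm(10)), "constant")
  expect_error(spatial_spearman(rnorm(4), rnorm(4)), "at least 5")
})

test_that("permutation p is uniform under independence", {
  set.seed(61)
  reject <- 0L; n_rep <- 500L
  for (i in seq_len(n_rep)) {
    p <- spatial_spearman(rnorm(30), rnorm(30), n_perm = 199,
                          seed = 1000L + i)$p_value
    if (p <= 0.05) reject <- reject + 1L
  }
  rate <- reject / n_rep
  expect_gt(rate, 0.03); expect_lt(rate, 0.07)
})

test_that("compartment_report isolates planted compartment structure", {
  grid <- mni_grid(c(10, 10, 10), voxel_mm = 2)
  parc <- gen_parcellation(grid, 60)
  # connectivity map whose cortex parcels carry signal, others pure noise
  set.seed(67)
  base <- rnorm(60)
  conn_vals <- base[as.integer(parc$image$values)]
  conn <- volume_image(array(conn_vals, c(10, 10, 10)), grid$affine)
  pet_parcel <- ifelse(parc$lookup$compartment == "cortex",
                       base, rnorm(60))
  pet <- volume_image(array(pet_parcel[as.integer(parc$image$values)],
                            c(10, 10, 10)), grid$affine)
  rep1 <- compartment_report(list(net = conn), list(tracer = pet), parc,
                             n_perm = 499, seed = 3)
  ctx <- rep1[rep1$compartment == "cortex", ]
  cbl <- rep1[rep1$compartment == "cerebellum", ]
  expect_equal(ctx$rho, 1, tolerance = 1e-9)
  expect_lt(ctx$p_value, 0.01)
  expect_lt(abs(cbl$rho), 0.6)
  expect_gt(cbl$p_value, 0.05)
  expect_true(all(rep1$p_adj >= rep1$p_value - 1e-12))

  # determinism under a fixed seed
  rep2 <- compartment_report(list(net = conn), list(tracer = pet), parc,
                             n_perm = 499, seed = 3)
  expect_identical(rep1, rep2)
})
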