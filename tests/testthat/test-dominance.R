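# Dominance module: band peaks, standardisation, winner-takes-all
# classification, region assignment, tabulation, hemisphere comparison.

fake_fit <- function(peaks) structure(list(peaks = peaks),
                                      class = "spectral_fit")

test_that("band_max_peak picks the tallest in-band peak with ties to lower center", {
  pk <- data.frame(center = c(20, 28), height = c(0.5, 0.3), width = c(2, 2))
  got <- band_max_peak(pk, 13, 30)
  expect_equal(got$center, 20)
  expect_null(band_max_peak(pk, 4, 8))
  # half-open interval: a peak exactly at the upper edge is excluded
  expect_null(band_max_peak(data.frame(center = 30, height = 1, width = 2),
                            13, 30))
  tie <- data.frame(center = c(18, 25), height = c(0.4, 0.4), width = c(2, 2))
  expect_equal(band_max_peak(tie, 13, 30)$center, 18)
})

test_that("sequential z-scoring standardises heights as defined", {
  pt <- data.frame(channel_id = c("a", "a", "b", "b"),
                   subject_id = "s1", electrode_id = "e1",
                   band = c("alpha", "beta", "alpha", "beta"),
                   center = c(10, 20, 9, 22), height = c(2, 2, 2, 2))
  z <- zscore_peak_heights(pt)
  expect_equal(z$height_z, rep(0, 4))   # degenerate: centred only

  pt2 <- pt; pt2$height <- c(1, 3, 1, 3)
  z2 <- zscore_peak_heights(pt2, levels = "electrode")
  expect_equal(z2$height_z, c(-1, 1, -1, 1))   # population SD

  # dataset-level stage leaves mean 0, SD 1 (population)
  set.seed(5)
  pt3 <- data.frame(channel_id = rep(sprintf("c%02d", 1:40), each = 2),
                    subject_id = rep(sprintf("s%d", 1:8), each = 10),
                    electrode_id = rep(sprintf("e%d", 1:20), each = 4),
                    band = rep(c("alpha", "beta"), 40),
                    center = runif(80, 5, 30), height = runif(80, 0.1, 1))
  z3 <- zscore_peak_heights(pt3)
  expect_lt(abs(mean(z3$height_z)), 1e-9)
  expect_lt(abs(sqrt(mean((z3$height_z - mean(z3$height_z))^2)) - 1), 1e-9)

  expect_error(zscore_peak_heights(pt3[0, ]), "empty")
})

test_that("dominant_band is the winner-takes-all argmax and matches exemplars", {
  ch <- data.frame(channel_id = c("c1", "c2"), subject_id = "s",
                   electrode_id = "e")
  fits <- list(c1 = fake_fit(data.frame(center = 9, height = 0.5, width = 2)),
               c2 = fake_fit(data.frame(center = c(9, 20),
                                        height = c(0.3, 0.6),
                                        width = c(2, 2))))
  pt <- cohort_band_peaks(fits, ch)
  dom <- dominant_band(pt, use_z = FALSE)
  expect_equal(dom$dominant_band[dom$channel_id == "c1"], "alpha")
  expect_equal(dom$dominant_band[dom$channel_id == "c2"], "beta")
  # a channel without peaks gets NA
  dom2 <- dominant_band(pt, channel_ids = c("c1", "c2", "c3"))
  expect_true(is.na(dom2$dominant_band[dom2$channel_id == "c3"]))
})

test_that("winner-takes-all is invariant to monotone transforms and z-scoring", {
  coh <- gen_cohort(cohort_truth(n_channels = 40), seed = 13)
  fits <- lapply(coh$truths, function(tr) spectral_fit(gen_spectrum(tr)))
  names(fits) <- coh$channels$channel_id
  pt <- cohort_band_peaks(fits, coh$channels)

  raw <- dominant_band(pt, use_z = FALSE)
  zed <- dominant_band(zscore_peak_heights(pt), use_z = TRUE)
  expect_equal(raw$dominant_band, zed$dominant_band)

  # monotone transform of all heights leaves the argmax untouched
  pt_t <- pt; pt_t$height <- exp(3 * pt_t$height) - 0.5
  expect_equal(dominant_band(pt_t, use_z = FALSE)$dominant_band,
               raw$dominant_band)

  # and classification recovers the generator truth on noiseless spectra
  expect_equal(raw$dominant_band[match(coh$channels$channel_id,
                                       raw$channel_id)],
               coh$channels$true_band)
})

test_that("assign_region maps coordinates through the parcellation", {
  grid <- mni_grid(c(12, 12, 12), voxel_mm = 2)
  lab <- array(0L, c(12, 12, 12))
  lab[2:5, 2:5, 2:5] <- 1L       # region A block
  lab[8:11, 8:11, 8:11] <- 2L    # region B block
  lut <- data.frame(label = 1:2, name = c("A", "B"),
                    compartment = "cortex", source = "toy",
                    lobe = c("Frontal", "Occipital"))
  parc <- parcellation(volume_image(lab, grid$affine), lut)

  # coordinate exactly at a labelled voxel center
  mmA <- vox_to_mm(c(2, 2, 2), grid$affine)
  expect_equal(as.character(assign_region(mmA, parc)[1]), "A")

  # 3-4 mm outside the block: nearest labelled voxel within 5 mm wins
  mm_near <- vox_to_mm(c(6.5, 3, 3), grid$affine)   # 3 mm past region A edge
  got <- assign_region(mm_near, parc)
  expect_equal(as.character(got[1]), "A")
  # brute-force check that region A has the nearest labelled voxel
  mmL <- vox_to_mm(which(lab > 0, arr.ind = TRUE) - 1L, grid$affine)
  d2 <- colSums((t(mmL) - as.numeric(mm_near))^2)
  expect_equal(lab[which(lab > 0)][which.min(d2)], 1L)

  # far (> 5 mm) from any label but inside the box: unlabelled
  mid <- vox_to_mm(c(6, 6, 0), grid$affine)
  mmAll <- vox_to_mm(which(lab > 0, arr.ind = TRUE) - 1L, grid$affine)
  expect_gt(min(colSums((t(mmAll) - as.numeric(mid))^2)), 25)
  expect_equal(as.character(assign_region(mid, parc)[1]), "unlabelled")

  # outside the bounding box entirely
  expect_warning(out <- assign_region(c(0, 0, 200), parc), "bounding box")
  expect_equal(as.character(out[1]), "unlabelled")
})

test_that("tabulate_dominance conserves counts and matches generator truth", {
  coh <- gen_cohort(cohort_truth(n_channels = 120), seed = 17)
  fits <- lapply(coh$truths, function(tr) spectral_fit(gen_spectrum(tr)))
  names(fits) <- coh$channels$channel_id
  dom <- classify_dominance(fits, coh$channels)

  tab <- tabulate_dominance(dom, "true_lobe")
  expect_equal(sum(tab$n_channels), 120)
  # band counts across lobes equal the cohort truth
  for (b in names(coh$band_counts))
    expect_equal(sum(tab[[paste0(b, "_n")]]), unname(coh$band_counts[b]))
  # within-group percentages are consistent and bounded
  for (b in band_scheme()$band)
    expect_equal(tab[[paste0(b, "_pct")]],
                 round(100 * tab[[paste0(b, "_n")]] / tab$n_channels, 2))
  band_cols <- paste0(band_scheme()$band, "_n")
  expect_true(all(rowSums(tab[band_cols]) <= tab$n_channels))

  # counts are conserved across grouping choices
  tab2 <- tabulate_dominance(dom, "hemisphere")
  expect_equal(sum(tab2$beta_n), sum(tab$beta_n))

  # empty groups are omitted
  dom$true_lobe[1] <- "Amygdala"
  dom2 <- dom[dom$true_lobe != "Amygdala", ]
  expect_false("Amygdala" %in% tabulate_dominance(dom2, "true_lobe")$true_lobe)
})

test_that("hemisphere_test matches the closed-form chi-square", {
  mk <- function(nL_beta, nL_other, nR_beta, nR_other) {
    data.frame(hemisphere = c(rep("L", nL_beta + nL_other),
                              rep("R", nR_beta + nR_other)),
               dominant_band = c(rep("beta", nL_beta),
                                 rep("alpha", nL_other),
                                 rep("beta", nR_beta),
                                 rep("alpha", nR_other)))
  }
  # identical proportions: chi-square 0, p = 1
  eq <- hemisphere_test(mk(30, 70, 30, 70), "beta")
  expect_equal(eq$statistic, 0, tolerance = 1e-12)
  expect_equal(eq$p_value, 1, tolerance = 1e-12)

  # hand-computed 30/70 vs 50/50
  ht <- hemisphere_test(mk(30, 70, 50, 50), "beta")
  tab <- matrix(c(30, 50, 70, 50), 2)
  expect_equal(ht$statistic, oracle_chisq_2x2(tab), tolerance = 1e-9)
  expect_equal(ht$p_value, pchisq(oracle_chisq_2x2(tab), 1,
                                  lower.tail = FALSE), tolerance = 1e-9)

  expect_error(hemisphere_test(mk(30, 70, 0, 0)[1:100, ], "beta"),
               "hemispheres")
})

test_that("hemisphere test is calibrated under hemisphere-independent dominance", {
  set.seed(29)
  reject <- 0L; n_rep <- 500L
  for (i in seq_len(n_rep)) {
    coh <- data.frame(hemisphere = rep(c("L", "R"), each = 200),
                      dominant_band = sample(c("beta", "alpha"), 400,
                                             replace = TRUE))
    p <- hemisphere_test(coh, "beta")$p_value
    if (p < 0.05) reject <- reject + 1L
  }
  rate <- reject / n_rep
  expect_gt(rate, 0.03); expect_lt(rate, 0.07)
})
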