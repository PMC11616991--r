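# Synthetic-data generators: every input the pipeline consumes, with known
# ground truth. All randomness flows through an explicit integer seed and the
# caller's RNG state is restored afterwards (no global state).

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Default analysis frequency grid
#'
#' Linear 1-100 Hz in 0.5 Hz steps. The grid is a free analysis choice; the
#' default covers the four canonical bands (theta through gamma) with a
#' resolution finer than the narrowest admissible peak.
#' @return Numeric vector of frequencies in Hz.
#' @export
default_freq_grid <- function() seq(1, 100, by = 0.5)

#' Ground-truth description of one channel's power spectrum
#'
#' The generating model is, in log10 power,
#' \deqn{\log_{10} P(f) = b - \chi \log_{10} f +
#'   \sum_i a_i \exp\{-(f - c_i)^2 / (2 w_i^2)\} + \epsilon,}
#' an aperiodic 1/f background (offset `b`, exponent `chi`) plus Gaussian
#' oscillatory peaks (center `c` Hz, height `a` in log10-power units above
#' background, width `w` Hz as the Gaussian SD) and optional iid Gaussian
#' noise of SD `noise_sd` (log10-power units).
#'
#' @param offset log10-power intercept `b`.
#' @param exponent aperiodic slope `chi` (>= 0, unitless).
#' @param peaks data frame with columns `center`, `height`, `width` (may have
#'   zero rows).
#' @param noise_sd SD of additive log10-power noise.
#' @param seed integer RNG seed used when noise is drawn.
#' @return An object of class `spectrum_truth`.
#' @export
spectrum_truth <- function(offset = 1, exponent = 1,
                           peaks = data.frame(center = numeric(),
                                              height = numeric(),
                                              width = numeric()),
                           noise_sd = 0, seed = 1L) {
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) && !all(c("center", "height", "width") %in% names(peaks)))
    stop("`peaks` needs columns center, height, width")
  if (exponent < 0) stop("`exponent` must be >= 0")
  if (nrow(peaks) && any(peaks$width <= 0)) stop("peak widths must be > 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(list(offset = offset, exponent = exponent, peaks = peaks,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "spectrum_truth")
}

# noiseless log10-power curve of a spectrum_truth on an arbitrary grid
truth_log_power <- function(truth, freqs) {
  y <- truth$offset - truth$exponent * log10(freqs)
  if (nrow(truth$peaks)) {
    for (i in seq_len(nrow(truth$peaks))) {
      p <- truth$peaks[i, ]
      y <- y + p$height * exp(-(freqs - p$center)^2 / (2 * p$width^2))
    }
  }
  y
}

#' Generate a power spectrum from a ground-truth description
#'
#' @param truth a [spectrum_truth()].
#' @param freqs strictly increasing positive frequency grid (Hz).
#' @return A [power_spectrum()] with linear power values.
#' @export
gen_spectrum <- function(truth, freqs = default_freq_grid()) {
  stopifnot(inherits(truth, "spectrum_truth"))
  if (any(freqs <= 0)) stop("frequencies must be positive (log undefined at f <= 0)")
  if (any(diff(freqs) <= 0)) stop("`freqs` must be strictly increasing")
  if (nrow(truth$peaks) &&
      any(truth$peaks$center < min(freqs) | truth$peaks$center > max(freqs)))
    stop("peak centers must lie within the frequency range")
  lp <- truth_log_power(truth, freqs)
  if (truth$noise_sd > 0)
    lp <- lp + with_seed(truth$seed, stats::rnorm(length(freqs), 0, truth$noise_sd))
  power_spectrum(freqs, 10^lp)
}

#' Synthesise a time series whose PSD matches a spectral ground truth
#'
#' White Gaussian noise is shaped in the frequency domain: the amplitude of
#' each Fourier component is set to the square root of the target power
#' `10^(b - chi log10 f + peaks)`, so the expected PSD of the output follows
#' the generating spectral model (1/f-coloured noise plus band-limited
#' oscillatory components at each peak center).
#'
#' @param truth a [spectrum_truth()] (its `noise_sd` is ignored here; PSD
#'   estimation noise arises naturally).
#' @param fs sampling rate in Hz (>= 200, mirroring the recording-inclusion
#'   criterion of the source atlas).
#' @param duration length in seconds.
#' @param seed integer RNG seed.
#' @param lowest_freq lowest frequency intended for later wavelet analysis;
#'   the signal must hold at least two wavelet supports at this frequency.
#' @return Numeric vector of `fs * duration` samples.
#' @export
gen_timeseries <- function(truth, fs = 200, duration = 60, seed = 1L,
                           lowest_freq = 1) {
  stopifnot(inherits(truth, "spectrum_truth"))
  if (fs < 200) stop("`fs` must be >= 200 Hz")
  n <- round(fs * duration)
  if (duration < 2 * 7 / lowest_freq)
    stop("signal shorter than twice the longest wavelet support")
  with_seed(seed, {
    w <- stats::rnorm(n)
    W <- stats::fft(w)
    fr <- seq(0, fs / 2, by = fs / n)            # rfft bin frequencies
    amp <- numeric(length(fr))
    pos <- fr > 0
    amp[pos] <- sqrt(10^truth_log_power(truth, fr[pos]))
    nh <- length(fr)                             # bins 1..nh cover [0, fs/2]
    full <- numeric(n)
    full[seq_len(nh)] <- amp
    if (n %% 2 == 0) full[seq(nh + 1L, n)] <- rev(amp[2:(nh - 1L)])
    else full[seq(nh + 1L, n)] <- rev(amp[2:nh])
    x <- Re(stats::fft(W * full, inverse = TRUE)) / n
    x
  })
}

#' Ground truth for a synthetic channel cohort
#'
#' @param n_channels number of channels.
#' @param dominance_probs named probabilities (theta, alpha, beta, gamma) of a
#'   channel's true dominant rhythm; must sum to 1. Defaults are the observed
#'   resting-cohort fractions 277/397/1005/93 out of 1772 channels
#'   (15.6/22.4/56.6/5.2%).
#' @param n_subjects number of subjects channels are spread over.
#' @param channels_per_electrode channels grouped per electrode shaft/grid.
#' @param prob_second_peak probability a channel carries a second, weaker peak
#'   in another band.
#' @param regions data frame of sampling regions (name, lobe, center x/y/z,
#'   spread); `NULL` for a built-in cortical set.
#' @return An object of class `cohort_truth`.
#' @export
cohort_truth <- function(n_channels = 1772,
                         dominance_probs = c(theta = 277, alpha = 397,
                                             beta = 1005, gamma = 93) / 1772,
                         n_subjects = 106,
                         channels_per_electrode = 8,
                         prob_second_peak = 0.5,
                         regions = NULL) {
  if (abs(sum(dominance_probs) - 1) > 1e-12)
    stop("`dominance_probs` must sum to 1")
  if (is.null(names(dominance_probs)) ||
      !identical(sort(names(dominance_probs)),
                 sort(c("theta", "alpha", "beta", "gamma"))))
    stop("`dominance_probs` must be named theta/alpha/beta/gamma")
  if (is.null(regions)) regions <- default_regions()
  structure(list(n_channels = as.integer(n_channels),
                 dominance_probs = dominance_probs[c("theta", "alpha", "beta", "gamma")],
                 n_subjects = as.integer(n_subjects),
                 channels_per_electrode = as.integer(channels_per_electrode),
                 prob_second_peak = prob_second_peak,
                 regions = regions),
            class = "cohort_truth")
}

default_regions <- function() {
  base <- data.frame(
    name   = c("frontal_sup", "precentral", "temporal_mid", "parietal_inf",
               "occipital_mid", "cingulate_ant", "insula"),
    lobe   = c("Frontal", "Frontal", "Temporal", "Parietal",
               "Occipital", "Cingulate", "Insula"),
    x = c(25, 40, 55, 45, 35, 8, 38),
    y = c(40, -10, -20, -45, -85, 35, 5),
    z = c(35, 50, -10, 45, 10, 15, 5),
    spread = c(8, 8, 8, 8, 7, 5, 4))
  left <- base; left$x <- -left$x; left$name <- paste0(base$name, "_L")
  right <- base; right$name <- paste0(base$name, "_R")
  rbind(left, right)
}

# draw one channel's spectral truth given its dominant band; secondary peaks
# are weaker by a fixed margin and well separated so noiseless fitting is
# exactly identifiable
band_center_range <- list(theta = c(5, 7), alpha = c(8.5, 11.5),
                          beta = c(15, 28), gamma = c(35, 75))
band_width_range  <- list(theta = c(0.8, 1.2), alpha = c(0.8, 1.5),
                          beta = c(1.5, 2.5), gamma = c(2, 4))

draw_channel_truth <- function(band) {
  cr <- band_center_range[[band]]; wr <- band_width_range[[band]]
  c0 <- stats::runif(1, cr[1], cr[2])
  w0 <- stats::runif(1, wr[1], wr[2])
  a0 <- stats::runif(1, 0.5, 0.8)
  peaks <- data.frame(center = c0, height = a0, width = w0)
  list(peaks = peaks,
       offset = stats::runif(1, 0.5, 1.5),
       exponent = stats::runif(1, 0.8, 1.5))
}

add_secondary_peak <- function(peaks, band) {
  others <- setdiff(names(band_center_range), band)
  for (k in 1:20) {
    b2 <- sample(others, 1)
    cr <- band_center_range[[b2]]; wr <- band_width_range[[b2]]
    c2 <- stats::runif(1, cr[1], cr[2])
    w2 <- stats::runif(1, wr[1], wr[2])
    if (abs(c2 - peaks$center[1]) > 2 * (w2 + peaks$width[1]) + 2) {
      a2 <- peaks$height[1] * stats::runif(1, 0.4, 0.7)
      return(rbind(peaks, data.frame(center = c2, height = a2, width = w2)))
    }
  }
  peaks
}

#' Generate a synthetic channel cohort with known dominant rhythms
#'
#' True dominant-band counts are one multinomial draw from
#' `dominance_probs`; each channel's spectrum carries a peak in its true band
#' whose height is strictly the largest, so a correct classifier recovers the
#' truth exactly on noiseless spectra.
#'
#' @param truth a [cohort_truth()].
#' @param seed integer RNG seed.
#' @param noise_sd log10-power noise SD for the generated spectra.
#' @return List with `channels` (data frame: channel_id, subject_id,
#'   electrode_id, x/y/z mm, electrode_type, fs_hz, true_band, true_region,
#'   true_lobe), `truths` (list of [spectrum_truth()]), and `band_counts`
#'   (the multinomial draw).
#' @export
gen_cohort <- function(truth, seed = 1L, noise_sd = 0) {
  stopifnot(inherits(truth, "cohort_truth"))
  n <- truth$n_channels
  bands <- c("theta", "alpha", "beta", "gamma")
  if (n == 0L) {
    return(list(channels = data.frame(channel_id = character(),
                                      subject_id = character(),
                                      electrode_id = character(),
                                      x_mm = numeric(), y_mm = numeric(),
                                      z_mm = numeric(),
                                      electrode_type = character(),
                                      fs_hz = numeric(),
                                      true_band = character(),
                                      true_region = character(),
                                      true_lobe = character()),
                truths = list(),
                band_counts = stats::setNames(rep(0L, 4), bands)))
  }
  with_seed(seed, {
    counts <- as.integer(stats::rmultinom(1, n, truth$dominance_probs))
    names(counts) <- bands
    band_of <- sample(rep(bands, counts))
    reg_idx <- sample(nrow(truth$regions), n, replace = TRUE)
    reg <- truth$regions[reg_idx, ]
    xyz <- cbind(stats::rnorm(n, reg$x, reg$spread),
                 stats::rnorm(n, reg$y, reg$spread),
                 stats::rnorm(n, reg$z, reg$spread))
    subj <- sample(truth$n_subjects, n, replace = TRUE)
    elec <- paste0("S", subj, "E",
                   ((stats::ave(seq_len(n), subj, FUN = seq_along) - 1L) %/%
                      truth$channels_per_electrode) + 1L)
    etype <- ifelse(stats::runif(n) < 258 / 1772, "ECoG", "sEEG")
    truths <- vector("list", n)
    for (i in seq_len(n)) {
      ch <- draw_channel_truth(band_of[i])
      pk <- ch$peaks
      if (stats::runif(1) < truth$prob_second_peak)
        pk <- add_secondary_peak(pk, band_of[i])
      truths[[i]] <- spectrum_truth(offset = ch$offset, exponent = ch$exponent,
                                    peaks = pk, noise_sd = noise_sd,
                                    seed = sample.int(.Machine$integer.max, 1))
    }
    channels <- data.frame(
      channel_id = sprintf("ch%04d", seq_len(n)),
      subject_id = sprintf("sub%03d", subj),
      electrode_id = paste0("sub", sprintf("%03d", subj), "_", elec),
      x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3],
      electrode_type = etype, fs_hz = 200,
      true_band = band_of, true_region = reg$name, true_lobe = reg$lobe,
      stringsAsFactors = FALSE)
    list(channels = channels, truths = truths, band_counts = counts)
  })
}

#' Generate a multi-subject functional connectome with community structure
#'
#' Voxels sharing a latent network id receive a shared latent signal mixed
#' with iid noise so the designed within-network Pearson correlation is
#' `within_r`; cross-network correlation is 0 in expectation.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param community_map `volume_image` of integer network labels (0 = outside
#'   brain).
#' @param n_timepoints time points per subject.
#' @param within_r designed within-network correlation in `[0, 1]`; 1 means
#'   noise-free.
#' @param seed integer RNG seed.
#' @return An object of class `connectome`: the template grid, a logical
#'   in-brain mask, per-voxel network labels, and one timepoints-by-voxel
#'   matrix per subject.
#' @export
gen_connectome <- function(n_subjects, community_map, n_timepoints = 100,
                           within_r = 0.6, seed = 1L) {
  if (n_subjects < 2) stop("`n_subjects` must be >= 2 (group averaging undefined)")
  stopifnot(is_volume_image(community_map))
  if (within_r < 0 || within_r > 1) stop("`within_r` must be in [0, 1]")
  labels <- round(community_map$values)
  mask <- is.finite(labels) & labels > 0
  vlab <- labels[mask]
  nets <- sort(unique(vlab))
  V <- sum(mask)
  with_seed(seed, {
    data <- lapply(seq_len(n_subjects), function(s) {
      L <- matrix(stats::rnorm(n_timepoints * length(nets)), n_timepoints)
      X <- sqrt(within_r) * L[, match(vlab, nets), drop = FALSE]
      if (within_r < 1)
        X <- X + sqrt(1 - within_r) * matrix(stats::rnorm(n_timepoints * V),
                                             n_timepoints)
      X
    })
    structure(list(grid = community_map, mask = mask, voxel_labels = vlab,
                   data = data),
              class = "connectome")
  })
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d subjects, %d in-brain voxels, %d timepoints, %d networks\n",
              length(x$data), sum(x$mask), nrow(x$data[[1]]),
              length(unique(x$voxel_labels))))
  invisible(x)
}

#' Generate a toy tractogram from polyline bundle templates
#'
#' Each generated streamline is a bundle template rigidly displaced by a
#' Gaussian offset of SD `jitter_mm` (shape-preserving scatter around the
#' template course).
#'
#' @param bundles list of n-by-3 matrices of MNI mm points (each a template
#'   polyline with >= 2 points).
#' @param n_per_bundle streamlines per bundle.
#' @param jitter_mm SD of the per-streamline rigid offset.
#' @param seed integer RNG seed.
#' @return An object of class `streamline_set` (list of n-by-3 matrices).
#' @export
gen_tractogram <- function(bundles, n_per_bundle = 50, jitter_mm = 1,
                           seed = 1L) {
  stopifnot(all(vapply(bundles, function(b) nrow(b) >= 2, logical(1))))
  with_seed(seed, {
    sl <- list()
    for (b in bundles) {
      b <- as.matrix(b)
      for (i in seq_len(n_per_bundle)) {
        off <- stats::rnorm(3, 0, jitter_mm)
        sl[[length(sl) + 1L]] <- sweep(b, 2, -off)
      }
    }
    streamline_set(sl)
  })
}

#' Streamline set container
#' @param streamlines list of n-by-3 numeric matrices (MNI mm polylines).
#' @return An object of class `streamline_set`.
#' @export
streamline_set <- function(streamlines) {
  ok <- vapply(streamlines, function(s) is.matrix(s) && ncol(s) == 3 &&
                 nrow(s) >= 2, logical(1))
  if (length(streamlines) && !all(ok))
    stop("each streamline must be an n-by-3 matrix with >= 2 points")
  structure(streamlines, class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("<streamline_set> %d streamlines, %d vertices total\n",
              length(x), sum(vapply(x, nrow, integer(1)))))
  invisible(x)
}

#' Generate a PET-like uptake map with a designed spatial correlation
#'
#' Parcel means of the output have (approximately) a target Spearman
#' correlation with a given network profile. The profile is rank-normalised
#' and mixed with Gaussian noise at the Pearson level
#' `r = 2 sin(pi * target_rho / 6)` — the bivariate-normal inversion of the
#' Spearman/Pearson relation — so the realised Spearman correlation
#' concentrates on `target_rho`.
#'
#' @param parcellation a [parcellation()] object.
#' @param network_profile numeric vector of per-parcel values (the map to
#'   correlate against), length = number of parcels; must not be constant.
#' @param target_rho target Spearman correlation in `[-1, 1]`.
#' @param voxel_noise_sd SD of additional iid voxel-level noise.
#' @param seed integer RNG seed.
#' @return A `volume_image` of synthetic tracer uptake.
#' @export
gen_pet <- function(parcellation, network_profile, target_rho,
                    voxel_noise_sd = 0, seed = 1L) {
  stopifnot(inherits(parcellation, "parcellation"))
  if (abs(target_rho) > 1) stop("`target_rho` must be in [-1, 1]")
  x <- as.numeric(network_profile)
  np <- nrow(parcellation$lookup)
  if (length(x) != np)
    stop("`network_profile` length must equal the number of parcels")
  fin <- is.finite(x)                  # parcels with no data stay missing
  if (sum(fin) < 3 || stats::sd(x[fin]) == 0)
    stop("`network_profile` is constant; correlation undefined")
  z <- rep(NA_real_, length(x))
  z[fin] <- stats::qnorm((rank(x[fin]) - 0.5) / sum(fin))
  r <- 2 * sin(pi * target_rho / 6)
  with_seed(seed, {
    eps <- stats::rnorm(length(x))
    y <- r * z + sqrt(max(0, 1 - r^2)) * eps
    lab <- round(parcellation$image$values)
    vals <- array(NA_real_, dim(lab))
    idx <- match(lab, parcellation$lookup$label)
    inb <- !is.na(idx)
    vals[inb] <- y[idx[inb]]
    if (voxel_noise_sd > 0)
      vals[inb] <- vals[inb] + stats::rnorm(sum(inb), 0, voxel_noise_sd)
    volume_image(vals, parcellation$image$affine)
  })
}
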