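# Spectral parameterisation: Morlet-wavelet power spectra decomposed into an
# aperiodic 1/f background plus Gaussian oscillatory peaks. `spectral_fit()`
# is the package's central estimator and returns a classed model object.

#' Power spectrum container
#' @param freqs strictly increasing positive frequencies (Hz).
#' @param power linear power per bin (positive where used for fitting).
#' @return An object of class `power_spectrum`.
#' @export
power_spectrum <- function(freqs, power) {
  freqs <- as.numeric(freqs); power <- as.numeric(power)
  if (length(freqs) != length(power))
    stop("`freqs` and `power` must have equal length")
  if (any(diff(freqs) <= 0)) stop("`freqs` must be strictly increasing")
  if (any(freqs <= 0)) stop("`freqs` must be positive")
  structure(list(freqs = freqs, power = power), class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, %.3g-%.3g Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Delete runs of exact zeros from a signal
#'
#' Recordings assembled from signal fragments may contain zero-padded
#' intervals between fragments; these are removed before spectral analysis by
#' deleting every run of exact zeros of at least `min_run_length` samples and
#' concatenating the remainder in order.
#'
#' @param signal numeric vector.
#' @param min_run_length shortest zero-run treated as padding (>= 1).
#' @param min_samples minimum acceptable output length; shorter output is an
#'   error (default 0 disables the check).
#' @param channel_id optional identifier used in error messages.
#' @return The signal with padding runs removed.
#' @export
remove_zero_runs <- function(signal, min_run_length = 1L, min_samples = 0L,
                             channel_id = NULL) {
  if (min_run_length < 1) stop("`min_run_length` must be >= 1")
  r <- rle(signal == 0)
  drop <- r$values & r$lengths >= min_run_length
  keep <- rep.int(!drop, r$lengths)
  out <- signal[keep]
  if (length(out) < min_samples)
    stop(sprintf("channel %s: only %d samples remain after zero-run removal (minimum %d)",
                 if (is.null(channel_id)) "<unnamed>" else channel_id,
                 length(out), as.integer(min_samples)))
  out
}

#' Morlet-wavelet power spectrum of a single-channel signal
#'
#' Convolves the signal with complex Morlet wavelets (`n_cycles` cycles; the
#' Gaussian envelope SD is `n_cycles / (2 pi f)` seconds) and averages
#' squared magnitude over time, excluding samples within half the wavelet
#' support of either edge. Wavelets are amplitude (L1) normalised so a unit
#' sinusoid yields power 1/4 at its own frequency regardless of frequency.
#'
#' @param signal numeric vector.
#' @param fs sampling rate (Hz); must satisfy `fs >= 2 * max(freqs)`.
#' @param freqs analysis frequencies (Hz).
#' @param n_cycles wavelet width in cycles.
#' @return A [power_spectrum()].
#' @export
morlet_psd <- function(signal, fs, freqs = default_freq_grid(), n_cycles = 7) {
  if (fs < 2 * max(freqs))
    stop(sprintf("fs = %g Hz violates Nyquist for max frequency %g Hz",
                 fs, max(freqs)))
  n <- length(signal)
  sigma_t <- n_cycles / (2 * pi * min(freqs))
  max_half <- ceiling(4 * sigma_t * fs)
  if (n < 2 * (2 * max_half + 1))
    stop("signal shorter than twice the wavelet support at the lowest frequency")
  nfft <- stats::nextn(n + 2 * max_half, 2)
  S <- stats::fft(c(signal, numeric(nfft - n)))
  power <- numeric(length(freqs))
  for (k in seq_along(freqs)) {
    f <- freqs[k]
    st <- n_cycles / (2 * pi * f)
    half <- ceiling(4 * st * fs)
    tt <- seq(-half, half) / fs
    env <- exp(-tt^2 / (2 * st^2))
    w <- env * exp(2i * pi * f * tt) / sum(env)
    W <- stats::fft(c(w, complex(real = numeric(nfft - length(w)))))
    conv <- stats::fft(S * W, inverse = TRUE) / nfft
    # full convolution: sample i of the signal aligns with conv[i + half]
    valid <- seq.int(2 * half + 1, n)       # >= half support from both edges
    power[k] <- mean(Mod(conv[valid])^2)
  }
  power_spectrum(freqs, power)
}

#' Settings for spectral parameterisation
#'
#' Defaults follow the standard parameterisation convention for resting iEEG:
#' peak width limits `[0.5, 12]` Hz (interpreted, as in the reference
#' convention, as limits on twice the Gaussian SD), an unbounded number of
#' peaks, minimum peak height 0, and a detection threshold of 2 SD of the
#' flattened spectrum.
#'
#' @param peak_width_limits length-2 limits (Hz) on `2 * width`.
#' @param peak_threshold_sd detection threshold in SDs of the flattened
#'   spectrum.
#' @param min_peak_height minimum absolute height (log10 power) of a peak.
#' @param max_n_peaks maximum number of peaks (`Inf` = unbounded).
#' @param freq_range optional length-2 fit range (Hz); `NULL` fits the whole
#'   spectrum.
#' @return An object of class `spectral_settings`.
#' @export
spectral_settings <- function(peak_width_limits = c(0.5, 12),
                              peak_threshold_sd = 2,
                              min_peak_height = 0,
                              max_n_peaks = Inf,
                              freq_range = NULL) {
  if (length(peak_width_limits) != 2 || peak_width_limits[1] <= 0 ||
      diff(peak_width_limits) <= 0)
    stop("`peak_width_limits` must be positive and increasing")
  structure(list(peak_width_limits = peak_width_limits,
                 peak_threshold_sd = peak_threshold_sd,
                 min_peak_height = min_peak_height,
                 max_n_peaks = max_n_peaks,
                 freq_range = freq_range),
            class = "spectral_settings")
}

# sum of Gaussians in log10-power, vectorised over the grid
gaussian_sum <- function(freqs, peaks) {
  y <- numeric(length(freqs))
  if (!is.null(peaks) && nrow(peaks)) {
    for (i in seq_len(nrow(peaks)))
      y <- y + peaks$height[i] *
        exp(-(freqs - peaks$center[i])^2 / (2 * peaks$width[i]^2))
  }
  y
}

aperiodic_curve <- function(freqs, offset, exponent) offset - exponent * log10(freqs)

# drop Gaussians whose 0.75-SD bands overlap, keeping the taller of each
# overlapping pair; stray subtraction artefacts otherwise split one true
# peak into several Gaussians
prune_overlaps <- function(peaks) {
  if (nrow(peaks) < 2) return(peaks)
  peaks <- peaks[order(peaks$center), , drop = FALSE]
  repeat {
    if (nrow(peaks) < 2) break
    ov <- which(peaks$center[-1] - 0.75 * peaks$width[-1] <
                  peaks$center[-nrow(peaks)] +
                  0.75 * peaks$width[-nrow(peaks)])
    if (!length(ov)) break
    i <- ov[1]
    drop_i <- if (peaks$height[i] < peaks$height[i + 1]) i else i + 1
    peaks <- peaks[-drop_i, , drop = FALSE]
  }
  peaks
}

# bounded LM refinement of a peak set against a flattened target
refit_gaussians <- function(freqs, target, peaks, wlim) {
  if (!nrow(peaks)) return(peaks)
  par0 <- as.vector(t(as.matrix(peaks[, c("center", "height", "width")])))
  lower <- as.vector(t(cbind(peaks$center - 2 * peaks$width, 0, wlim[1])))
  upper <- as.vector(t(cbind(peaks$center + 2 * peaks$width, Inf, wlim[2])))
  fn <- function(p) {
    pk <- as.data.frame(matrix(p, ncol = 3, byrow = TRUE))
    names(pk) <- c("center", "height", "width")
    gaussian_sum(freqs, pk) - target
  }
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper, fn = fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  pk <- as.data.frame(matrix(fit$par, ncol = 3, byrow = TRUE))
  names(pk) <- c("center", "height", "width")
  pk
}

#' Fit the aperiodic (1/f) background of a power spectrum
#'
#' Knee-free form `log10 P = b - chi * log10 f`. The fit is peak-resistant:
#' an initial least-squares line is refit using only the bins lying at or
#' below it, so bins elevated by oscillatory peaks do not drag the slope.
#'
#' @param spectrum a [power_spectrum()].
#' @param freq_range optional length-2 range (Hz) to restrict the fit.
#' @return List with `offset`, `exponent`, and `resid_sd` (log10 units).
#' @export
fit_aperiodic <- function(spectrum, freq_range = NULL) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  f <- spectrum$freqs; p <- spectrum$power
  if (!is.null(freq_range)) {
    sel <- f >= freq_range[1] & f <= freq_range[2]
    f <- f[sel]; p <- p[sel]
  }
  if (length(f) < 5) stop("need at least 5 bins to fit the aperiodic component")
  if (any(p <= 0)) stop("power must be positive on the fitted range")
  lf <- log10(f); lp <- log10(p)
  fit0 <- stats::lm.fit(cbind(1, lf), lp)
  res <- fit0$residuals
  keep <- res <= pmax(0, stats::quantile(pmax(res, 0), 0.0025))
  if (sum(keep) < 5) keep <- rank(res, ties.method = "first") <= 5
  fit1 <- stats::lm.fit(cbind(1, lf[keep]), lp[keep])
  b <- unname(fit1$coefficients[1]); chi <- unname(-fit1$coefficients[2])
  list(offset = b, exponent = chi,
       resid_sd = stats::sd(lp - aperiodic_curve(f, b, chi)))
}

#' Detect and fit Gaussian peaks in a flattened spectrum
#'
#' Iteratively takes the largest maximum of the residual spectrum that
#' exceeds `peak_threshold_sd` SDs of the current residual (and
#' `min_peak_height`), seeds a Gaussian there with a half-height width
#' estimate (clipped to the width limits), subtracts it, and repeats; the
#' collected Gaussians are then refined jointly by bounded
#' Levenberg-Marquardt least squares.
#'
#' @param freqs frequency grid (Hz).
#' @param flattened log10-power residual spectrum (observed minus aperiodic).
#' @param settings a [spectral_settings()].
#' @return Data frame with columns `center`, `height`, `width` (possibly 0
#'   rows), sorted by center.
#' @export
detect_and_fit_peaks <- function(freqs, flattened,
                                 settings = spectral_settings()) {
  wlim <- settings$peak_width_limits / 2     # limits apply to 2*width
  df <- stats::median(diff(freqs))
  flat <- flattened
  guesses <- NULL
  while (is.null(guesses) || nrow(guesses) < settings$max_n_peaks) {
    i <- which.max(flat)
    h <- flat[i]
    # absolute floor guards against machine-precision residual structure
    thr <- max(settings$peak_threshold_sd * stats::sd(flat),
               settings$min_peak_height, 1e-6)
    if (!(h > thr)) break
    c0 <- freqs[i]
    # half-height crossing width estimate
    half_h <- h / 2
    li <- which(flat[seq_len(i)] <= half_h)
    ri <- which(flat[seq.int(i, length(flat))] <= half_h)
    dl <- if (length(li)) i - max(li) else NA_real_
    dr <- if (length(ri)) min(ri) - 1 else NA_real_
    hwhm <- if (all(is.na(c(dl, dr)))) 2 * df else min(dl, dr, na.rm = TRUE) * df
    if (!is.finite(hwhm) || hwhm <= 0) hwhm <- 2 * df
    w0 <- max(min(hwhm / sqrt(2 * log(2)), wlim[2]), wlim[1])
    guesses <- rbind(guesses, data.frame(center = c0, height = h, width = w0))
    flat <- flat - h * exp(-(freqs - c0)^2 / (2 * w0^2))
  }
  if (is.null(guesses) || !nrow(guesses))
    return(data.frame(center = numeric(), height = numeric(),
                      width = numeric()))
  # drop guesses hugging the edge of the fitted range (unresolvable)
  edge_ok <- guesses$center - guesses$width >= min(freqs) &
    guesses$center + guesses$width <= max(freqs)
  guesses <- guesses[edge_ok, , drop = FALSE]
  guesses <- prune_overlaps(guesses)
  if (!nrow(guesses))
    return(data.frame(center = numeric(), height = numeric(),
                      width = numeric()))
  pk <- guesses
  for (it in 1:3) {                      # joint fit; re-prune until stable
    pk <- refit_gaussians(freqs, flattened, pk, wlim)
    pk <- pk[pk$height > max(settings$min_peak_height, 1e-6), , drop = FALSE]
    pruned <- prune_overlaps(pk)
    if (nrow(pruned) == nrow(pk)) { pk <- pruned; break }
    pk <- pruned
  }
  pk <- pk[order(pk$center), , drop = FALSE]
  rownames(pk) <- NULL
  pk
}

#' Parameterise a power spectrum into aperiodic and periodic components
#'
#' Fits the model
#' \deqn{\log_{10} P(f) = b - \chi \log_{10} f +
#'   \sum_i a_i \exp\{-(f - c_i)^2 / (2 w_i^2)\}}
#' in stages: peak-resistant aperiodic fit, flattening, iterative Gaussian
#' peak detection with joint refinement, aperiodic refit on the peak-removed
#' spectrum, and a final joint polish of all parameters by bounded
#' Levenberg-Marquardt. `fit_error` is the mean absolute log10 residual of
#' the full model.
#'
#' @param spectrum a [power_spectrum()], or a numeric vector of linear power
#'   (then `freqs` must be given).
#' @param settings a [spectral_settings()].
#' @param freqs frequency grid when `spectrum` is a bare vector.
#' @return An object of class `spectral_fit` with components `aperiodic`
#'   (list: offset, exponent), `peaks` (data frame: center, height, width),
#'   `fit_error`, `settings`, and the data used.
#' @export
spectral_fit <- function(spectrum, settings = spectral_settings(),
                         freqs = NULL) {
  if (!inherits(spectrum, "power_spectrum")) {
    if (is.null(freqs)) stop("`freqs` required when `spectrum` is a bare vector")
    spectrum <- power_spectrum(freqs, spectrum)
  }
  f <- spectrum$freqs; p <- spectrum$power
  if (!is.null(settings$freq_range)) {
    sel <- f >= settings$freq_range[1] & f <= settings$freq_range[2]
    f <- f[sel]; p <- p[sel]
  }
  if (any(p <= 0)) stop("power must be positive on the fitted range")
  lp <- log10(p)
  sub <- power_spectrum(f, p)

  ap0 <- fit_aperiodic(sub)
  flat <- lp - aperiodic_curve(f, ap0$offset, ap0$exponent)
  peaks <- detect_and_fit_peaks(f, flat, settings)

  peak_removed <- lp - gaussian_sum(f, peaks)
  fit1 <- stats::lm.fit(cbind(1, log10(f)), peak_removed)
  ap1 <- list(offset = unname(fit1$coefficients[1]),
              exponent = unname(-fit1$coefficients[2]))

  wlim <- settings$peak_width_limits / 2
  for (it in 1:3) {                         # final joint polish (+ re-prune)
    if (!nrow(peaks)) break
    par0 <- c(ap1$offset, ap1$exponent,
              as.vector(t(as.matrix(peaks[, c("center", "height", "width")]))))
    lower <- c(-Inf, -Inf,
               as.vector(t(cbind(peaks$center - 2 * peaks$width, 0, wlim[1]))))
    upper <- c(Inf, Inf,
               as.vector(t(cbind(peaks$center + 2 * peaks$width, Inf, wlim[2]))))
    fn <- function(q) {
      pk <- as.data.frame(matrix(q[-(1:2)], ncol = 3, byrow = TRUE))
      names(pk) <- c("center", "height", "width")
      aperiodic_curve(f, q[1], q[2]) + gaussian_sum(f, pk) - lp
    }
    fit2 <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                               fn = fn,
                               control = minpack.lm::nls.lm.control(maxiter = 200))
    ap1 <- list(offset = fit2$par[1], exponent = fit2$par[2])
    peaks <- as.data.frame(matrix(fit2$par[-(1:2)], ncol = 3, byrow = TRUE))
    names(peaks) <- c("center", "height", "width")
    peaks <- peaks[peaks$height > max(settings$min_peak_height, 1e-6), ,
                   drop = FALSE]
    pruned <- prune_overlaps(peaks)
    done <- nrow(pruned) == nrow(peaks)
    peaks <- pruned[order(pruned$center), , drop = FALSE]
    rownames(peaks) <- NULL
    if (done) break
  }

  fitted_lp <- aperiodic_curve(f, ap1$offset, ap1$exponent) +
    gaussian_sum(f, peaks)
  structure(list(freqs = f, power = p, log_power = lp,
                 aperiodic = ap1, peaks = peaks,
                 fit_error = mean(abs(lp - fitted_lp)),
                 fitted_log_power = fitted_lp,
                 settings = settings),
            class = "spectral_fit")
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat("Spectral parameterisation (aperiodic + Gaussian peaks)\n")
  cat(sprintf("  range: %.3g-%.3g Hz (%d bins)\n", min(x$freqs), max(x$freqs),
              length(x$freqs)))
  cat(sprintf("  aperiodic: offset = %.4f, exponent = %.4f\n",
              x$aperiodic$offset, x$aperiodic$exponent))
  cat(sprintf("  peaks: %d;  fit error (mean |log10 resid|): %.3g\n",
              nrow(x$peaks), x$fit_error))
  invisible(x)
}

#' @export
summary.spectral_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.spectral_fit")
}

#' @export
print.summary.spectral_fit <- function(x, ...) {
  print(x$fit)
  if (nrow(x$fit$peaks)) {
    cat("  peak table (center Hz / height log10-power / width Hz):\n")
    print(format(x$fit$peaks, digits = 4), row.names = TRUE)
  }
  invisible(x)
}

#' @export
coef.spectral_fit <- function(object, ...) {
  out <- c(offset = object$aperiodic$offset,
           exponent = object$aperiodic$exponent)
  if (nrow(object$peaks)) {
    for (i in seq_len(nrow(object$peaks))) {
      v <- unlist(object$peaks[i, c("center", "height", "width")])
      names(v) <- paste0(c("center", "height", "width"), i)
      out <- c(out, v)
    }
  }
  out
}

#' Predict model log10 power (or components) on a frequency grid
#' @param object a `spectral_fit`.
#' @param freqs frequencies (Hz); defaults to the fitted grid.
#' @param component `"full"`, `"aperiodic"`, or `"periodic"`.
#' @param ... unused.
#' @return Numeric vector of log10 power (periodic component is relative to
#'   the background).
#' @export
predict.spectral_fit <- function(object, freqs = object$freqs,
                                 component = c("full", "aperiodic", "periodic"),
                                 ...) {
  component <- match.arg(component)
  ap <- aperiodic_curve(freqs, object$aperiodic$offset,
                        object$aperiodic$exponent)
  pe <- gaussian_sum(freqs, object$peaks)
  switch(component, full = ap + pe, aperiodic = ap, periodic = pe)
}

#' @export
fitted.spectral_fit <- function(object, ...) object$fitted_log_power

#' @export
residuals.spectral_fit <- function(object, ...)
  object$log_power - object$fitted_log_power

#' @export
plot.spectral_fit <- function(x, ...) {
  graphics::plot(x$freqs, x$log_power, type = "l", col = "grey40",
                 xlab = "Frequency (Hz)", ylab = "log10 power",
                 main = "Spectral parameterisation", ...)
  graphics::lines(x$freqs, x$fitted_log_power, col = "firebrick", lwd = 2)
  graphics::lines(x$freqs, predict(x, component = "aperiodic"),
                  col = "steelblue", lty = 2)
  if (nrow(x$peaks))
    graphics::abline(v = x$peaks$center, col = "grey70", lty = 3)
  graphics::legend("topright", c("observed", "model", "aperiodic"),
                   col = c("grey40", "firebrick", "steelblue"),
                   lty = c(1, 1, 2), bty = "n")
  invisible(x)
}

#' Simulate spectra from a fitted spectral model
#' @param object a `spectral_fit`.
#' @param nsim number of spectra.
#' @param seed integer seed.
#' @param ... unused.
#' @return List of [power_spectrum()] objects with noise matching the
#'   residual SD of the fit.
#' @export
simulate.spectral_fit <- function(object, nsim = 1, seed = 1L, ...) {
  sdv <- stats::sd(residuals(object))
  lapply(seq_len(nsim), function(i) {
    tr <- spectrum_truth(offset = object$aperiodic$offset,
                         exponent = max(0, object$aperiodic$exponent),
                         peaks = object$peaks, noise_sd = sdv,
                         seed = seed + i - 1L)
    gen_spectrum(tr, object$freqs)
  })
}
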