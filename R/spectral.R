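#' Welch power spectral density
#'
#' One-sided PSD averaged over Hann-tapered, overlapping segments,
#' trimmed to the fitting range. Default settings segment the recording
#' into 3.072 s windows with 50% overlap, giving a frequency resolution
#' of 1/3.072 = 0.32552 Hz, and retain 0.5-40 Hz.
#'
#' @param recording a [ts_recording()].
#' @param segment_s segment length in seconds.
#' @param overlap fractional overlap between consecutive segments.
#' @param fmin,fmax retained frequency range in Hz.
#' @return a `power_spectrum` list with `freqs` (Hz, strictly
#'   increasing) and `power` (units^2/Hz).
#' @export
welch_psd <- function(recording, segment_s = 3.072, overlap = 0.5,
                      fmin = 0.5, fmax = 40) {
  stopifnot(inherits(recording, "ts_recording"))
  fs <- recording$fs
  x <- recording$samples
  nseg <- round(segment_s * fs)
  if (length(x) < nseg) {
    stop_data("insufficient data: recording shorter than one Welch segment")
  }
  if (overlap < 0 || overlap >= 1) stop_invalid("`overlap` must be in [0,1)")
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  k <- 0:(nseg - 1)
  w <- 0.5 * (1 - cos(2 * pi * k / nseg))     # periodic Hann
  U <- sum(w^2)
  nhalf <- floor(nseg / 2)
  acc <- numeric(nhalf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)
    p <- (Mod(X[2:(nhalf + 1)])^2) * 2 / (fs * U)
    if (nseg %% 2 == 0) p[nhalf] <- p[nhalf] / 2   # Nyquist not doubled
    acc <- acc + p
  }
  pwr <- acc / length(starts)
  freqs <- (1:nhalf) * fs / nseg
  keep <- freqs >= fmin & freqs <= fmax
  structure(list(freqs = freqs[keep], power = pwr[keep]),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, %.3f-%.1f Hz (df = %.5f Hz)\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              x$freqs[2] - x$freqs[1]))
  invisible(x)
}

gaussian_bump <- function(f, centre, height, sigma) {
  height * exp(-(f - centre)^2 / (2 * sigma^2))
}

peaks_model <- function(f, peaks) {
  out <- numeric(length(f))
  if (!is.null(peaks) && nrow(peaks)) {
    for (i in seq_len(nrow(peaks))) {
      out <- out + gaussian_bump(f, peaks$centre_freq[i], peaks$height[i],
                                 peaks$bandwidth[i] / 2)
    }
  }
  out
}

# Simple then robust log-log aperiodic fit. The robust refit keeps only
# bins whose residual lies below the 2.5th percentile of the positive
# residuals, discarding oscillatory peak bins.
aperiodic_fit <- function(lf, lp) {
  co <- coef(lm(lp ~ lf))
  pred <- co[1] + co[2] * lf
  r <- lp - pred
  thr <- quantile(pmax(r, 0), 0.025, names = FALSE)
  keep <- r <= thr
  if (sum(keep) >= 5) co <- coef(lm(lp[keep] ~ lf[keep]))
  c(offset = unname(co[1]), exponent = unname(-co[2]))
}

#' Parameterize a power spectrum into aperiodic and periodic components
#'
#' Decomposes the log10 PSD into an aperiodic power-law component
#' (offset `b` and exponent `chi`, fitted as a log-log linear
#' regression, "fixed" mode without a knee) plus up to `max_peaks`
#' Gaussian oscillatory peaks. The procedure: robust aperiodic fit;
#' flatten; iteratively extract peak guesses until the largest residual
#' falls below `max(peak_threshold_sd * SD, min_peak_height)`; jointly
#' refine all Gaussians by bounded least squares; refit the aperiodic
#' component on the peak-subtracted spectrum. Peaks whose refined centre
#' drifts within one bandwidth of the spectrum edge are dropped as
#' unidentifiable.
#'
#' @param psd a `power_spectrum` from [welch_psd()].
#' @param max_peaks maximum number of Gaussian peaks.
#' @param peak_threshold_sd iterative stopping threshold in SD units of
#'   the flattened spectrum.
#' @param min_peak_height minimum peak height in log10 power.
#' @param bw_limits allowed bandwidth range (Hz, 2 standard deviations).
#' @return a `spectral_fit` list: `offset`, `exponent`, `peaks`
#'   (`data.frame` with `centre_freq`, `height`, `bandwidth`),
#'   `r_squared`, and the selected `alpha_peak` / `beta_peak` (or
#'   `NULL` when the band holds no peak).
#' @export
fit_spectral_model <- function(psd, max_peaks = 8, peak_threshold_sd = 2,
                               min_peak_height = 0.05,
                               bw_limits = c(0.75, 12)) {
  stopifnot(inherits(psd, "power_spectrum"))
  if (any(!is.finite(psd$power)) || any(psd$power <= 0)) {
    stop_invalid("PSD must be finite and strictly positive")
  }
  if (length(psd$freqs) < 20) stop_invalid("PSD needs at least 20 bins")
  f <- psd$freqs
  lp <- log10(psd$power)
  lf <- log10(f)
  slo <- bw_limits[1] / 2
  shi <- bw_limits[2] / 2

  ap <- aperiodic_fit(lf, lp)
  flat <- lp - (ap["offset"] - ap["exponent"] * lf)

  # iterative peak guesses on the flattened spectrum
  guesses <- NULL
  work <- flat
  for (i in seq_len(max_peaks)) {
    j <- which.max(work)
    h <- work[j]
    if (h < max(peak_threshold_sd * sd(work), min_peak_height)) break
    half <- h / 2
    le <- j; while (le > 1 && work[le - 1] > half) le <- le - 1
    ri <- j; while (ri < length(work) && work[ri + 1] > half) ri <- ri + 1
    side <- max(f[j] - f[le], f[ri] - f[j])
    sigma <- max(slo, min(shi, (2 * side) / 2.355))
    guesses <- rbind(guesses, c(f[j], h, sigma))
    work <- work - gaussian_bump(f, f[j], h, sigma)
  }

  peaks <- NULL
  if (!is.null(guesses)) {
    np <- nrow(guesses)
    par0 <- as.numeric(t(guesses))
    lower <- rep(c(min(f), 0, slo), np)
    upper <- rep(c(max(f), Inf, shi), np)
    obj <- function(p) {
      m <- matrix(p, ncol = 3, byrow = TRUE)
      pk <- data.frame(centre_freq = m[, 1], height = m[, 2],
                       bandwidth = 2 * m[, 3])
      sum((flat - peaks_model(f, pk))^2)
    }
    fit <- tryCatch(
      optim(par0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL
    )
    pm <- matrix(if (is.null(fit)) par0 else fit$par, ncol = 3, byrow = TRUE)
    peaks <- data.frame(centre_freq = pm[, 1], height = pm[, 2],
                        bandwidth = 2 * pm[, 3])
    # drop unidentifiable edge peaks and vanished peaks
    keep <- peaks$centre_freq >= min(f) + peaks$bandwidth &
      peaks$centre_freq <= max(f) - peaks$bandwidth &
      peaks$height >= min_peak_height / 2
    peaks <- peaks[keep, , drop = FALSE]
    if (nrow(peaks)) {
      peaks <- peaks[order(peaks$centre_freq), , drop = FALSE]
      rownames(peaks) <- NULL
    } else {
      peaks <- NULL
    }
  }
  if (is.null(peaks)) {
    peaks <- data.frame(centre_freq = numeric(0), height = numeric(0),
                        bandwidth = numeric(0))
  }

  # final aperiodic fit on the peak-subtracted spectrum
  ap <- aperiodic_fit(lf, lp - peaks_model(f, peaks))
  model <- (ap["offset"] - ap["exponent"] * lf) + peaks_model(f, peaks)
  r2 <- if (sd(lp) == 0) 1 else suppressWarnings(stats::cor(model, lp)^2)
  if (!is.finite(r2)) r2 <- 0

  fit <- structure(
    list(offset = unname(ap["offset"]), exponent = unname(ap["exponent"]),
         peaks = peaks, r_squared = r2,
         alpha_peak = NULL, beta_peak = NULL),
    class = "spectral_fit"
  )
  fit$alpha_peak <- select_band_peak(fit, c(8, 12))
  fit$beta_peak <- select_band_peak(fit, c(13, 30))
  fit
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf(
    "<spectral_fit> offset %.3f, exponent %.3f, %d peak(s), R2 = %.3f\n",
    x$offset, x$exponent, nrow(x$peaks), x$r_squared))
  invisible(x)
}

#' Select the dominant fitted peak within a frequency band
#'
#' Among fitted peaks whose centre lies inside the band, returns the one
#' with the greatest height (ties broken by the lowest centre
#' frequency). Returns `NULL` when the band holds no peak; downstream
#' models must then treat the subject as missing for that band's
#' features.
#'
#' @param fit a `spectral_fit`.
#' @param band `c(low, high)` in Hz, canonically `c(8, 12)` (alpha) or
#'   `c(13, 30)` (beta).
#' @return a one-row `data.frame` (`centre_freq`, `height`,
#'   `bandwidth`) or `NULL`.
#' @export
select_band_peak <- function(fit, band) {
  stopifnot(inherits(fit, "spectral_fit"), length(band) == 2)
  p <- fit$peaks
  inb <- p$centre_freq >= band[1] & p$centre_freq <= band[2]
  if (!any(inb)) return(NULL)
  p <- p[inb, , drop = FALSE]
  p <- p[order(-p$height, p$centre_freq), , drop = FALSE]
  out <- p[1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Band peak from the uncorrected PSD
#'
#' The maximum raw PSD value inside a band and its frequency, with no
#' aperiodic correction (the study's sensitivity variant of the band
#' power and centre-frequency features).
#'
#' @param psd a `power_spectrum`.
#' @param band `c(low, high)` in Hz.
#' @return list with `power` and `centre_freq`.
#' @export
raw_band_peak <- function(psd, band) {
  stopifnot(inherits(psd, "power_spectrum"), length(band) == 2)
  idx <- which(psd$freqs >= band[1] & psd$freqs <= band[2])
  if (!length(idx)) stop_invalid("band contains no PSD bins")
  j <- idx[which.max(psd$power[idx])]
  list(power = psd$power[j], centre_freq = psd$freqs[j])
}
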