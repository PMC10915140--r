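#' Burst detection settings
#'
#' @param band band-pass range in Hz; the mu-beta default combines the
#'   alpha/mu and beta bands.
#' @param threshold_factor multiplier `k` of the envelope median
#'   defining the detection threshold `T = k * median(envelope)`.
#' @param edge_rule `"half_max"` (event spans the half-maximum extent
#'   around the peak) or `"threshold"` (event spans the suprathreshold
#'   excursion itself).
#' @param threshold_abs optional absolute envelope threshold overriding
#'   the median rule, for recordings whose baseline is known (e.g.
#'   noise-free simulations, where the envelope median is degenerate).
#' @return a `burst_settings` list.
#' @export
burst_settings <- function(band = c(8, 30), threshold_factor = 2,
                           edge_rule = c("half_max", "threshold"),
                           threshold_abs = NULL) {
  edge_rule <- match.arg(edge_rule)
  if (band[1] >= band[2]) stop_invalid("band low must be below band high")
  if (is.null(threshold_abs) && threshold_factor <= 1) {
    stop_invalid("`threshold_factor` must exceed 1")
  }
  structure(list(band = band, threshold_factor = threshold_factor,
                 edge_rule = edge_rule, threshold_abs = threshold_abs),
            class = "burst_settings")
}

# Linear-phase windowed-sinc band-pass (Hamming window), unit gain at
# the band centre. Order = 3 cycles of the band's low frequency.
fir_bandpass <- function(fs, band, order = NULL) {
  if (is.null(order)) order <- round(3 * fs / band[1])
  if (order %% 2 == 1) order <- order + 1   # even order, odd length
  m <- -(order / 2):(order / 2)
  sinc <- function(fc) {
    h <- sin(2 * pi * fc * m / fs) / (pi * m)
    h[m == 0] <- 2 * fc / fs
    h
  }
  h <- sinc(band[2]) - sinc(band[1])
  k <- seq_along(h) - 1
  h <- h * (0.54 - 0.46 * cos(2 * pi * k / (length(h) - 1)))
  fc <- mean(band)
  gain <- Mod(sum(h * exp(-2i * pi * fc * m / fs)))
  h / gain
}

# Centered (zero-phase) FFT convolution with a symmetric kernel.
conv_centered <- function(x, h) {
  n <- length(x)
  L <- length(h)
  half <- (L - 1) / 2
  nf <- stats::nextn(n + L - 1, 2)
  y <- Re(fft(fft(c(x, numeric(nf - n))) *
                fft(c(h, numeric(nf - L))), inverse = TRUE)) / nf
  y[(half + 1):(half + n)]
}

#' Band-passed Hilbert envelope
#'
#' Zero-phase FIR band-pass (Hamming windowed-sinc, order three cycles
#' of the band's low frequency, applied forward and backward) followed
#' by the magnitude of the analytic signal. Same length as the input.
#'
#' @param recording a [ts_recording()].
#' @param band band-pass range in Hz, default mu-beta 8-30 Hz.
#' @return a [ts_recording()] holding the envelope.
#' @export
mu_beta_envelope <- function(recording, band = c(8, 30)) {
  stopifnot(inherits(recording, "ts_recording"))
  fs <- recording$fs
  if (fs <= 2 * band[2]) stop_invalid("`fs` must exceed twice the band high")
  order <- round(3 * fs / band[1])
  if (length(recording$samples) < 3 * order) {
    stop_data("insufficient data: recording shorter than 3 filter orders")
  }
  h <- fir_bandpass(fs, band, order)
  y <- conv_centered(conv_centered(recording$samples, h), h)
  env <- Mod(analytic_signal(y))
  ts_recording(env, fs, recording$subject_id, recording$truth_events)
}

# Analytic signal via the FFT (negative frequencies zeroed).
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  u <- numeric(n)
  if (n %% 2 == 0) {
    u[1] <- 1; u[n / 2 + 1] <- 1; u[2:(n / 2)] <- 2
  } else {
    u[1] <- 1; u[2:((n + 1) / 2)] <- 2
  }
  fft(X * u, inverse = TRUE) / n
}

#' Detect transient burst events in an envelope
#'
#' The detection threshold is `T = k * median(envelope)` over the whole
#' analysed series (or `threshold_abs` when given). Every maximal
#' strictly-suprathreshold excursion seeds a candidate whose peak
#' amplitude `P` is the envelope maximum within the excursion. With
#' `edge_rule = "half_max"` the event spans from the last upward
#' crossing of `P/2` before the peak to the first downward crossing of
#' `P/2` after the peak; candidates whose spans touch or overlap are
#' merged (peak = maximum of the merged candidates). With
#' `edge_rule = "threshold"` the event spans the suprathreshold
#' excursion itself. Events clipped by either recording edge are
#' discarded, since their duration and amplitude are censored.
#'
#' @param envelope a [ts_recording()] holding a non-negative envelope.
#' @param settings a [burst_settings()] object.
#' @return a `data.frame` of events, sorted and non-overlapping:
#'   `onset_s`, `offset_s`, `peak_time_s`, `peak_amplitude`, with the
#'   threshold as attribute `"threshold"`.
#' @export
detect_bursts <- function(envelope, settings = burst_settings()) {
  stopifnot(inherits(envelope, "ts_recording"),
            inherits(settings, "burst_settings"))
  env <- envelope$samples
  if (any(env < 0)) stop_invalid("envelope must be non-negative")
  fs <- envelope$fs
  n <- length(env)
  thr <- settings$threshold_abs %||%
    (settings$threshold_factor * median(env))
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      peak_time_s = numeric(0), peak_amplitude = numeric(0))
  attr(empty, "threshold") <- thr
  above <- env > thr
  if (!any(above)) return(empty)

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])

  ev <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    s <- runs[i, 1]; e <- runs[i, 2]
    j <- s + which.max(env[s:e]) - 1L
    P <- env[j]
    if (settings$edge_rule == "half_max") {
      half <- P / 2
      a <- j; while (a > 1L && env[a - 1L] >= half) a <- a - 1L
      clipL <- (a == 1L && env[1L] >= half)
      b <- j; while (b < n && env[b + 1L] >= half) b <- b + 1L
      clipR <- (b == n)
      # onset: first sample at/above half-max; offset: first sample
      # back below it
      ev[[i]] <- c(on = a, off = b + 1L, pk = j, P = P,
                   clip = as.numeric(clipL || clipR))
    } else {
      clip <- (s == 1L || e == n)
      ev[[i]] <- c(on = s, off = e + 1L, pk = j, P = P,
                   clip = as.numeric(clip))
    }
  }
  ev <- do.call(rbind, ev)

  # merge candidates whose spans touch or overlap: interval-union sweep
  # over spans sorted by onset (half-max spans of later excursions can
  # start earlier than those of preceding ones)
  ev <- ev[order(ev[, "on"], ev[, "off"]), , drop = FALSE]
  merged <- list()
  cur <- ev[1, ]
  if (nrow(ev) > 1) {
    for (i in 2:nrow(ev)) {
      nx <- ev[i, ]
      if (nx["on"] <= cur["off"]) {
        cur["off"] <- max(cur["off"], nx["off"])
        if (nx["P"] > cur["P"]) { cur["P"] <- nx["P"]; cur["pk"] <- nx["pk"] }
        cur["clip"] <- max(cur["clip"], nx["clip"])
      } else {
        merged[[length(merged) + 1]] <- cur
        cur <- nx
      }
    }
  }
  merged[[length(merged) + 1]] <- cur
  ev <- do.call(rbind, merged)
  ev <- ev[ev[, "clip"] == 0 & ev[, "off"] <= n, , drop = FALSE]
  if (!nrow(ev)) return(empty)

  out <- data.frame(onset_s = (ev[, "on"] - 1) / fs,
                    offset_s = (ev[, "off"] - 1) / fs,
                    peak_time_s = (ev[, "pk"] - 1) / fs,
                    peak_amplitude = ev[, "P"])
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Summarize burst events for one subject
#'
#' Rate in events per minute, median duration (ms), median
#' between-burst interval (ms, from one event's offset to the next
#' event's onset, within a contiguous segment only), and median peak
#' amplitude. An empty event list yields rate 0 and missing medians.
#'
#' @param events event `data.frame` from [detect_bursts()].
#' @param analyzed_s length of the analysed series in seconds.
#' @return a `data.frame` row: `burst_rate`, `burst_duration_ms`,
#'   `burst_interval_ms`, `burst_amplitude`, `n_events`, `analyzed_s`.
#' @export
summarize_bursts <- function(events, analyzed_s) {
  if (!is.numeric(analyzed_s) || analyzed_s <= 0) {
    stop_invalid("`analyzed_s` must be positive")
  }
  n <- nrow(events)
  if (n == 0) {
    return(data.frame(burst_rate = 0, burst_duration_ms = NA_real_,
                      burst_interval_ms = NA_real_,
                      burst_amplitude = NA_real_,
                      n_events = 0L, analyzed_s = analyzed_s))
  }
  dur <- (events$offset_s - events$onset_s) * 1000
  iv <- if (n > 1) {
    (events$onset_s[-1] - events$offset_s[-n]) * 1000
  } else {
    NA_real_
  }
  data.frame(burst_rate = n / (analyzed_s / 60),
             burst_duration_ms = median(dur),
             burst_interval_ms = median(iv),
             burst_amplitude = median(events$peak_amplitude),
             n_events = n, analyzed_s = analyzed_s)
}
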