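# Independent reference implementations used as oracles. These are
# deliberately written as literal sample-by-sample scans, structured
# differently from the package's rle/vectorized code paths.

# Exhaustive sample-scan burst detector following the published event
# definition: threshold = k * median (or an absolute override); each
# maximal strictly-suprathreshold excursion seeds a candidate; half_max
# edges span the half-maximum extent around the excursion peak,
# threshold edges span the excursion itself; touching/overlapping spans
# merge; edge-clipped events are dropped.
ref_detect_bursts <- function(env, fs, threshold_factor = 2,
                              edge_rule = "half_max",
                              threshold_abs = NULL) {
  n <- length(env)
  thr <- if (is.null(threshold_abs)) threshold_factor * median(env) else
    threshold_abs
  cands <- list()
  i <- 1L
  while (i <= n) {
    if (env[i] > thr) {
      j <- i
      while (j < n && env[j + 1L] > thr) j <- j + 1L
      pk <- i
      for (q in i:j) if (env[q] > env[pk]) pk <- q
      P <- env[pk]
      if (edge_rule == "half_max") {
        a <- pk
        while (a > 1L && env[a - 1L] >= P / 2) a <- a - 1L
        b <- pk
        while (b < n && env[b + 1L] >= P / 2) b <- b + 1L
        clip <- (a == 1L && env[1L] >= P / 2) || b == n
        cands[[length(cands) + 1L]] <-
          list(on = a, off = b + 1L, pk = pk, P = P, clip = clip)
      } else {
        cands[[length(cands) + 1L]] <-
          list(on = i, off = j + 1L, pk = pk, P = P,
               clip = i == 1L || j == n)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(cands)) {
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      peak_time_s = numeric(0),
                      peak_amplitude = numeric(0)))
  }
  # merge to fixpoint: while any two spans touch or overlap, replace
  # them by their union (peak = larger of the two)
  repeat {
    hit <- FALSE
    for (a in seq_along(cands)) {
      for (b in seq_along(cands)) {
        if (a >= b) next
        ca <- cands[[a]]; cb <- cands[[b]]
        if (ca$on <= cb$off && cb$on <= ca$off) {
          un <- list(on = min(ca$on, cb$on), off = max(ca$off, cb$off),
                     pk = if (ca$P >= cb$P) ca$pk else cb$pk,
                     P = max(ca$P, cb$P), clip = ca$clip || cb$clip)
          cands[[a]] <- un
          cands[[b]] <- NULL
          hit <- TRUE
          break
        }
      }
      if (hit) break
    }
    if (!hit) break
  }
  out <- cands[order(vapply(cands, function(e) e$on, numeric(1)))]
  out <- Filter(function(e) !e$clip && e$off <= n, out)
  if (!length(out)) {
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      peak_time_s = numeric(0),
                      peak_amplitude = numeric(0)))
  }
  data.frame(
    onset_s = vapply(out, function(e) (e$on - 1) / fs, numeric(1)),
    offset_s = vapply(out, function(e) (e$off - 1) / fs, numeric(1)),
    peak_time_s = vapply(out, function(e) (e$pk - 1) / fs, numeric(1)),
    peak_amplitude = vapply(out, function(e) e$P, numeric(1))
  )
}

# Random non-negative test envelopes: a mix of smoothed noise (smooth,
# realistic) and coarse integer-valued traces (ties and plateaus).
random_envelope <- function(n, style = c("smooth", "plateau")) {
  style <- match.arg(style)
  if (style == "smooth") {
    x <- stats::filter(rnorm(n + 40), rep(1 / 15, 15), sides = 2)
    abs(x[!is.na(x)])[1:n]
  } else {
    sample(0:6, n, replace = TRUE, prob = c(4, 8, 6, 3, 2, 1, 1)) / 2
  }
}

# Dense grid-search fit of a single Gaussian bump on a flattened
# log-power spectrum; oracle for the peak-fitting route.
ref_grid_peak <- function(freqs, flat, centres, heights, sigmas) {
  best <- NULL
  best_ss <- Inf
  for (cc in centres) for (h in heights) for (s in sigmas) {
    ss <- sum((flat - h * exp(-(freqs - cc)^2 / (2 * s^2)))^2)
    if (ss < best_ss) {
      best_ss <- ss
      best <- c(centre = cc, height = h, sigma = s)
    }
  }
  best
}

# Brute-force burst summary oracle.
ref_summarize <- function(events, analyzed_s) {
  n <- nrow(events)
  if (n == 0) {
    return(list(rate = 0, dur = NA_real_, iv = NA_real_, amp = NA_real_))
  }
  durs <- numeric(n); amps <- numeric(n)
  for (i in 1:n) {
    durs[i] <- (events$offset_s[i] - events$onset_s[i]) * 1000
    amps[i] <- events$peak_amplitude[i]
  }
  ivs <- c()
  if (n > 1) {
    for (i in 1:(n - 1)) {
      ivs <- c(ivs, (events$onset_s[i + 1] - events$offset_s[i]) * 1000)
    }
  }
  list(rate = n * 60 / analyzed_s, dur = median(durs),
       iv = if (length(ivs)) median(ivs) else NA_real_,
       amp = median(amps))
}

# Synthetic model-matched PSD on the study's frequency grid.
powerlaw_psd <- function(offset = -20, exponent = 1.5, peaks = NULL,
                         df = 1 / 3.072, fmin = 0.5, fmax = 40) {
  f <- seq(ceiling(fmin / df) * df, fmax, by = df)
  lp <- offset - exponent * log10(f)
  if (!is.null(peaks)) {
    for (p in peaks) {
      lp <- lp + p[2] * exp(-(f - p[1])^2 / (2 * p[3]^2))
    }
  }
  structure(list(freqs = f, power = 10^lp), class = "power_spectrum")
}
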