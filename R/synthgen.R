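#' Parameters of a synthetic sensorimotor signal
#'
#' Describes a simulated region-of-interest resting-state signal: a
#' power-law (1/f) aperiodic background, optional oscillatory peaks, and
#' optional transient mu-beta bursts. Defaults emulate a three-minute
#' resting-state recording sampled at 1000 Hz.
#'
#' The aperiodic background obeys, in expectation,
#' `log10 P(f) = aperiodic_offset - aperiodic_exponent * log10(f)`;
#' oscillations add Gaussian bumps in log10 power. Bursts are
#' Hann-windowed sinusoids placed by a Poisson process.
#'
#' @param duration_s recording length in seconds.
#' @param fs sampling rate in Hz.
#' @param aperiodic_offset log10-power intercept of the background; `NA`
#'   for no background at all (bursts on a silent trace).
#' @param aperiodic_exponent decay exponent of the background (>= 0).
#' @param oscillations list of oscillatory peaks, each
#'   `c(centre_freq, height, bandwidth)` with height in log10 power and
#'   bandwidth in Hz (2 standard deviations of the Gaussian).
#' @param burst_rate expected burst events per minute.
#' @param burst_duration_mean_ms,burst_duration_sd_ms burst duration
#'   distribution (normal, truncated at +-2 SD and at 20 ms).
#' @param burst_amplitude peak envelope amplitude of each burst.
#' @param burst_centre_freq carrier frequency of the bursts in Hz.
#' @param seed integer seed; identical parameters and seed give
#'   bit-identical signals.
#' @return a `signal_params` list.
#' @export
signal_params <- function(duration_s = 180, fs = 1000,
                          aperiodic_offset = -20, aperiodic_exponent = 1.5,
                          oscillations = list(),
                          burst_rate = 0,
                          burst_duration_mean_ms = 100,
                          burst_duration_sd_ms = 30,
                          burst_amplitude = 1,
                          burst_centre_freq = 20,
                          seed = 1L) {
  assert_scalar_pos(duration_s, "duration_s")
  assert_scalar_pos(fs, "fs")
  if (burst_rate < 0) stop_invalid("`burst_rate` must be >= 0")
  assert_scalar_pos(burst_duration_mean_ms, "burst_duration_mean_ms")
  if (length(oscillations)) {
    fmax <- max(vapply(oscillations, `[`, numeric(1), 1L))
    if (fs <= 2 * fmax) {
      stop_invalid("`fs` must exceed twice the highest oscillation frequency")
    }
  }
  structure(
    list(duration_s = duration_s, fs = fs,
         aperiodic_offset = aperiodic_offset,
         aperiodic_exponent = aperiodic_exponent,
         oscillations = oscillations,
         burst_rate = burst_rate,
         burst_duration_mean_ms = burst_duration_mean_ms,
         burst_duration_sd_ms = burst_duration_sd_ms,
         burst_amplitude = burst_amplitude,
         burst_centre_freq = burst_centre_freq,
         seed = as.integer(seed)),
    class = "signal_params"
  )
}

# Target one-sided PSD (units^2/Hz) at frequencies f, in log10 power:
# offset - exponent*log10(f) plus Gaussian oscillatory bumps.
target_log10_psd <- function(f, offset, exponent, oscillations = list()) {
  lp <- offset - exponent * log10(f)
  for (o in oscillations) {
    sigma <- o[3] / 2
    lp <- lp + o[2] * exp(-(f - o[1])^2 / (2 * sigma^2))
  }
  lp
}

#' Generate a spectrally shaped Gaussian background signal
#'
#' Produces Gaussian noise whose one-sided PSD follows, in expectation,
#' the power law `log10 P(f) = offset - exponent * log10(f)`, plus any
#' oscillatory Gaussian bumps in `params$oscillations`. Shaping is done
#' in the frequency domain: independent complex-Gaussian Fourier
#' coefficients with amplitude proportional to the square root of the
#' target PSD, DC and Nyquist set to zero, inverse transformed. This
#' gives the exact expected spectrum with no filter transients.
#'
#' @param params a [signal_params()] object (burst fields are ignored).
#' @return a [ts_recording()].
#' @export
generate_aperiodic_signal <- function(params) {
  stopifnot(inherits(params, "signal_params"))
  n <- round(params$duration_s * params$fs)
  if (n < 4) stop_invalid("recording too short")
  if (is.na(params$aperiodic_offset)) {
    return(ts_recording(numeric(n), params$fs))
  }
  local_seed(params$seed, {
    fs <- params$fs
    nhalf <- floor(n / 2)
    f <- (1:nhalf) * fs / n                 # positive frequencies
    lp <- target_log10_psd(f, params$aperiodic_offset,
                           params$aperiodic_exponent, params$oscillations)
    psd <- 10^lp
    # E|X_k|^2 = P_k * fs * n / 2 gives a one-sided periodogram with
    # expectation P_k; complex-Gaussian coefficients keep the signal
    # Gaussian.
    amp <- sqrt(psd * fs * n / 4)
    re <- rnorm(nhalf) * amp
    im <- rnorm(nhalf) * amp
    X <- complex(real = re, imaginary = im)
    if (n %% 2 == 0) X[nhalf] <- 0          # Nyquist bin zeroed
    spec <- complex(length.out = n)
    spec[2:(nhalf + 1)] <- X
    idx <- if (n %% 2 == 0) 2:nhalf else 2:(nhalf + 1)
    spec[n + 2 - idx] <- Conj(spec[idx])
    x <- Re(fft(spec, inverse = TRUE)) / n
    ts_recording(x, fs)
  })
}

# Truncated-normal burst durations (seconds): normal(mean, sd) truncated
# at +-2 SD and at a 20 ms floor.
rtrunc_duration <- function(k, mean_ms, sd_ms) {
  lo <- max(20, mean_ms - 2 * sd_ms)
  hi <- mean_ms + 2 * sd_ms
  if (lo >= hi) return(rep(mean_ms / 1000, k))
  out <- numeric(k)
  for (i in seq_len(k)) {
    repeat {
      d <- rnorm(1, mean_ms, sd_ms)
      if (d >= lo && d <= hi) break
    }
    out[i] <- d
  }
  out / 1000
}

#' Generate a transient mu-beta burst train
#'
#' Places burst events by a Poisson process at `burst_rate` per minute.
#' Each event is a Hann-windowed sinusoid at `burst_centre_freq` with a
#' truncated-normal duration and the requested peak envelope amplitude.
#' Placement is non-overlapping by rejection sampling (at most 1e4
#' attempts). The train is superposed on the aperiodic background unless
#' `aperiodic_offset` is `NA`.
#'
#' @param params a [signal_params()] object.
#' @param gap_s minimum silent gap enforced between bursts, keeping
#'   ground-truth events unambiguous for recovery tests.
#' @param n_bursts optional fixed event count overriding the Poisson
#'   draw (the placement itself stays random).
#' @return a [ts_recording()] with `truth_events` populated
#'   (`onset_s`, `offset_s`, `peak_time_s`, `peak_amplitude`).
#' @export
generate_burst_train <- function(params, gap_s = 0.2, n_bursts = NULL) {
  stopifnot(inherits(params, "signal_params"))
  dur_min <- params$duration_s / 60
  mean_dur_s <- params$burst_duration_mean_ms / 1000
  if (params$burst_rate * dur_min * mean_dur_s > 0.8 * params$duration_s) {
    stop_invalid("infeasible placement: requested bursts would occupy more ",
                 "than 80% of the recording")
  }
  background <- generate_aperiodic_signal(params)
  n <- length(background$samples)
  fs <- params$fs
  truth <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      peak_time_s = numeric(0), peak_amplitude = numeric(0))
  if (params$burst_rate == 0) {
    background$truth_events <- truth
    return(background)
  }
  x <- background$samples
  local_seed(params$seed + 1L, {
    k <- n_bursts %||% rpois(1, params$burst_rate * dur_min)
    if (k > 0) {
      durs <- rtrunc_duration(k, params$burst_duration_mean_ms,
                              params$burst_duration_sd_ms)
      onsets <- numeric(0)
      offsets <- numeric(0)
      attempts <- 0L
      placed <- 0L
      while (placed < k) {
        attempts <- attempts + 1L
        if (attempts > 1e4) {
          stop_invalid("infeasible placement: could not place ", k,
                       " non-overlapping bursts in 1e4 attempts")
        }
        d <- durs[placed + 1L]
        on <- runif(1, 0, params$duration_s - d)
        if (!any(on < offsets + gap_s & on + d > onsets - gap_s)) {
          onsets <- c(onsets, on)
          offsets <- c(offsets, on + d)
          placed <- placed + 1L
        }
      }
      ord <- order(onsets)
      onsets <- onsets[ord]; offsets <- offsets[ord]; durs <- durs[ord]
      for (i in seq_len(k)) {
        i0 <- floor(onsets[i] * fs) + 1L
        i1 <- min(n, i0 + round(durs[i] * fs) - 1L)
        tt <- (seq(i0, i1) - i0) / fs
        d <- durs[i]
        hann <- 0.5 * (1 - cos(2 * pi * tt / d))
        # carrier phased to peak at the burst centre, so the planted
        # peak envelope amplitude is exact even for one-cycle bursts
        x[i0:i1] <- x[i0:i1] + params$burst_amplitude * hann *
          cos(2 * pi * params$burst_centre_freq * (tt - d / 2))
      }
      truth <- data.frame(onset_s = onsets, offset_s = offsets,
                          peak_time_s = (onsets + offsets) / 2,
                          peak_amplitude = params$burst_amplitude)
    }
  })
  ts_recording(x, fs, background$subject_id, truth)
}

#' Parameters of a synthetic cohort
#'
#' Describes a two-group cohort (healthy controls and PD patients) with
#' demographics matched to the study population and a configurable
#' linear effect structure on ten sensorimotor signal features. Effects
#' are specified on the predictors' natural scales: group and sex are
#' 0/1 indicators (0 = healthy control / female), age and cortical
#' thickness enter centred at their population means (units: years, mm),
#' age squared is the square of centred age, and interactions are
#' products of these columns. Gaussian features take the coefficients
#' directly (the three log-scale burst features on their natural-log
#' scale); the burst count takes them on the log-rate (per minute)
#' scale with exposure equal to the analysed minutes.
#'
#' @param n_pd,n_hc group sizes (>= 2).
#' @param age_mean,age_sd named vectors `c(pd=, hc=)` in years; ages are
#'   truncated to the 44-85 y recruitment span.
#' @param sex_ratio proportion female per group, `c(pd=, hc=)`.
#' @param thickness_mean,thickness_sd cortical thickness (mm).
#' @param analyzed_s analysed recording length per subject (seconds).
#' @param coefficients named list: feature name -> named numeric vector
#'   of true effects over predictor keys from
#'   `c("group","age","age2","sex","thickness")` and their two-way
#'   interactions written `"a:b"`.
#' @param intercepts named numeric vector of feature intercepts
#'   (overrides the defaults; burst count intercept on log rate/min).
#' @param noise_sd named numeric vector of residual SDs per feature
#'   (Gaussian features only; burst counts are Poisson).
#' @param clinical_coefficients named list: subscale name -> named
#'   vector of effects of z-scored features (within the PD group).
#' @param clinical_noise_sd residual SD of the subscale scores.
#' @param alpha_missing_prob probability that a subject lacks an alpha
#'   peak (alpha features set missing), as observed in real cohorts.
#' @param seed integer seed.
#' @return a `cohort_params` list.
#' @export
cohort_params <- function(n_pd = 78, n_hc = 60,
                          age_mean = c(pd = 65.6, hc = 63.93),
                          age_sd = c(pd = 9.5, hc = 8.4),
                          sex_ratio = c(pd = 29 / 78, hc = 27 / 60),
                          thickness_mean = 2.5, thickness_sd = 0.12,
                          analyzed_s = 180,
                          coefficients = list(),
                          intercepts = numeric(0),
                          noise_sd = numeric(0),
                          clinical_coefficients = list(),
                          clinical_noise_sd = 1,
                          alpha_missing_prob = 0.13,
                          seed = 1L) {
  if (n_pd < 2 || n_hc < 2) stop_invalid("group sizes must be >= 2")
  if (any(unlist(noise_sd) < 0)) stop_invalid("`noise_sd` must be >= 0")
  keys <- cohort_predictor_keys()
  for (f in names(coefficients)) {
    bad <- setdiff(names(coefficients[[f]]), keys)
    if (length(bad)) {
      stop_invalid("unknown predictor key(s) for feature `", f, "`: ",
                   paste(bad, collapse = ", "))
    }
  }
  structure(
    list(n_pd = n_pd, n_hc = n_hc, age_mean = age_mean, age_sd = age_sd,
         sex_ratio = sex_ratio, thickness_mean = thickness_mean,
         thickness_sd = thickness_sd, analyzed_s = analyzed_s,
         coefficients = coefficients, intercepts = intercepts,
         noise_sd = noise_sd,
         clinical_coefficients = clinical_coefficients,
         clinical_noise_sd = clinical_noise_sd,
         alpha_missing_prob = alpha_missing_prob,
         seed = as.integer(seed)),
    class = "cohort_params"
  )
}

cohort_predictor_keys <- function() {
  mains <- c("group", "age", "age2", "sex", "thickness")
  ints <- c("group:age", "group:sex", "group:thickness",
            "age:sex", "age:thickness", "sex:thickness")
  c(mains, ints)
}

#' Names of the ten sensorimotor signal features
#' @return character vector of feature column names.
#' @export
feature_names <- function() {
  c("alpha_power", "alpha_cf", "beta_power", "beta_cf",
    "aperiodic_offset", "aperiodic_exponent",
    "burst_rate", "burst_duration_ms", "burst_interval_ms",
    "burst_amplitude")
}

#' Names of the motor-symptom subscales
#' @return character vector of subscale column names.
#' @export
subscale_names <- function() {
  c("midline_function", "rest_tremor", "rigidity",
    "upper_bradykinesia_contra", "upper_bradykinesia_ipsi",
    "postural_kinetic_tremor", "lower_limb_bradykinesia", "updrs3_total")
}

# Features generated (and later analysed) on the natural-log scale.
log_scale_features <- function() {
  c("burst_duration_ms", "burst_interval_ms", "burst_amplitude")
}

default_feature_intercepts <- function() {
  c(alpha_power = 0.6, alpha_cf = 10, beta_power = 0.4, beta_cf = 20,
    aperiodic_offset = -20, aperiodic_exponent = 1.3,
    burst_rate = log(60),                       # log events/min
    burst_duration_ms = log(120), burst_interval_ms = log(500),
    burst_amplitude = log(2))
}

default_feature_noise_sd <- function() {
  c(alpha_power = 0.25, alpha_cf = 1, beta_power = 0.15, beta_cf = 2,
    aperiodic_offset = 0.3, aperiodic_exponent = 0.3,
    burst_rate = 0,                              # Poisson, no extra noise
    burst_duration_ms = 0.25, burst_interval_ms = 0.3,
    burst_amplitude = 0.3)
}

# Natural-scale design columns for the effect structure.
cohort_design <- function(d, age_centre, thickness_centre) {
  age_c <- d$age - age_centre
  th_c <- d$cortical_thickness - thickness_centre
  g <- as.numeric(d$group == "pd")
  s <- as.numeric(d$sex == "male")
  cbind(group = g, age = age_c, age2 = age_c^2, sex = s, thickness = th_c,
        `group:age` = g * age_c, `group:sex` = g * s,
        `group:thickness` = g * th_c, `age:sex` = age_c * s,
        `age:thickness` = age_c * th_c, `sex:thickness` = s * th_c)
}

#' Generate a synthetic cohort feature table
#'
#' Draws demographics per group, then each signal feature from a
#' Gaussian linear model (burst counts from a Poisson model with log
#' link and exposure equal to analysed minutes) with the effect
#' structure in `params$coefficients`, and finally the PD motor-symptom
#' subscales from a linear model on the z-scored features. Deterministic
#' given the seed.
#'
#' @param params a [cohort_params()] object.
#' @return a `data.frame` (feature table), one row per subject, with
#'   covariates, features, `n_events`, `analyzed_s`, and PD clinical
#'   columns; true coefficients are attached as attribute
#'   `"true_coefficients"`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  local_seed(params$seed, {
    n <- params$n_pd + params$n_hc
    grp <- c(rep("pd", params$n_pd), rep("hc", params$n_hc))
    age <- numeric(n)
    sex <- character(n)
    for (g in c("pd", "hc")) {
      idx <- which(grp == g)
      a <- rnorm(length(idx), params$age_mean[[g]], params$age_sd[[g]])
      # recruitment span truncation
      while (any(a < 44 | a > 85)) {
        bad <- a < 44 | a > 85
        a[bad] <- rnorm(sum(bad), params$age_mean[[g]], params$age_sd[[g]])
      }
      age[idx] <- a
      sex[idx] <- ifelse(runif(length(idx)) < params$sex_ratio[[g]],
                         "female", "male")
    }
    thick <- rnorm(n, params$thickness_mean, params$thickness_sd)
    d <- data.frame(
      subject_id = sprintf("sub-%03d", seq_len(n)),
      group = grp, age = age, sex = sex, cortical_thickness = thick,
      stringsAsFactors = FALSE
    )
    X <- cohort_design(d, mean(params$age_mean), params$thickness_mean)
    inter <- default_feature_intercepts()
    inter[names(params$intercepts)] <- params$intercepts
    nsd <- default_feature_noise_sd()
    nsd[names(params$noise_sd)] <- params$noise_sd
    minutes <- params$analyzed_s / 60
    d$analyzed_s <- params$analyzed_s

    for (f in feature_names()) {
      eta <- rep(inter[[f]], n)
      b <- params$coefficients[[f]]
      if (!is.null(b)) eta <- eta + as.numeric(X[, names(b), drop = FALSE] %*% b)
      if (f == "burst_rate") {
        counts <- rpois(n, exp(eta) * minutes)
        d$n_events <- counts
        d$burst_rate <- counts / minutes
      } else if (f %in% log_scale_features()) {
        d[[f]] <- exp(eta + rnorm(n, 0, nsd[[f]]))
      } else {
        d[[f]] <- eta + rnorm(n, 0, nsd[[f]])
      }
    }
    # missing alpha peaks
    miss <- runif(n) < params$alpha_missing_prob
    d$alpha_power[miss] <- NA_real_
    d$alpha_cf[miss] <- NA_real_

    # PD-only clinical columns
    pd <- d$group == "pd"
    d$disease_duration <- NA_real_
    d$ledd <- NA_real_
    dd <- rnorm(sum(pd), 4.4, 3.7); dd[dd < 0] <- 0
    le <- rnorm(sum(pd), 548, 273); le[le < 0] <- 0
    d$disease_duration[pd] <- dd
    d$ledd[pd] <- le
    d$moca <- c(rnorm(params$n_pd, 26.1, 2.8), rnorm(params$n_hc, 26.2, 2.1))

    sub_inter <- c(midline_function = 3, rest_tremor = 3, rigidity = 4,
                   upper_bradykinesia_contra = 3, upper_bradykinesia_ipsi = 3,
                   postural_kinetic_tremor = 2, lower_limb_bradykinesia = 2,
                   updrs3_total = 19)
    zfeat <- function(f) {
      v <- d[[f]][pd]
      if (f %in% log_scale_features()) v <- log(v)
      as.numeric(scale(v))
    }
    for (s in subscale_names()) {
      d[[s]] <- NA_real_
      eta <- rep(sub_inter[[s]], sum(pd))
      g <- params$clinical_coefficients[[s]]
      if (!is.null(g)) {
        bad <- setdiff(names(g), feature_names())
        if (length(bad)) {
          stop_invalid("unknown clinical predictor(s): ",
                       paste(bad, collapse = ", "))
        }
        for (f in names(g)) eta <- eta + g[[f]] * zfeat(f)
      }
      d[[s]][pd] <- eta + rnorm(sum(pd), 0, params$clinical_noise_sd)
    }
    attr(d, "true_coefficients") <- params$coefficients
    d
  })
}
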