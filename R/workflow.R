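#' Default pipeline configuration
#'
#' Every threshold and tolerance defaults to the study's stated value
#' where one exists: 3.072 s Welch segments with 50% overlap over
#' 0.5-40 Hz; spectral fit with at most 8 peaks, peak threshold 2 SD,
#' minimum peak height 0.05, bandwidth 0.75-12 Hz; burst detection on
#' the 8-30 Hz envelope at 2x the envelope median.
#'
#' @param ... named overrides merged (recursively) into the defaults.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    version = 1L,
    seed = 1L,
    simulate = list(mode = "signals", n_subjects = 4L,
                    signal = list(duration_s = 180, fs = 1000,
                                  aperiodic_offset = -20,
                                  aperiodic_exponent = 1.5,
                                  burst_rate = 60,
                                  burst_duration_mean_ms = 100,
                                  burst_duration_sd_ms = 30,
                                  burst_amplitude = 1,
                                  burst_centre_freq = 20),
                    cohort = list()),
    inputs = list(recordings = character(0), subjects_csv = NULL),
    welch = list(segment_s = 3.072, overlap = 0.5, fmin = 0.5, fmax = 40),
    spectral_fit = list(max_peaks = 8L, peak_threshold_sd = 2,
                        min_peak_height = 0.05, bw_limits = c(0.75, 12)),
    bands = list(alpha = c(8, 12), beta = c(13, 30)),
    burst = list(band = c(8, 30), threshold_factor = 2,
                 edge_rule = "half_max"),
    stats = list(order = default_predictor_order(),
                 bf_cutoff = 3,
                 features = feature_names(),
                 subscales = subscale_names()),
    output_dir = "mubeta-output"
  )
  ov <- list(...)
  if (length(ov)) cfg <- utils::modifyList(cfg, ov)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file path.
#' @return a `pipeline_config` (file values merged over the defaults).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Write the settings actually used by a run
#' @param config a `pipeline_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Extract all signal features from one recording
#'
#' Runs the full per-subject feature pipeline: Welch PSD, spectral
#' parameterization, corrected and uncorrected band peaks, mu-beta
#' envelope, burst detection, and burst summary.
#'
#' @param recording a [ts_recording()].
#' @param config a [pipeline_config()].
#' @return list with `features` (one-row `data.frame`) and `events`
#'   (burst event table).
#' @export
extract_features <- function(recording, config = pipeline_config()) {
  w <- config$welch
  psd <- welch_psd(recording, w$segment_s, w$overlap, w$fmin, w$fmax)
  sf <- config$spectral_fit
  fit <- fit_spectral_model(psd, sf$max_peaks, sf$peak_threshold_sd,
                            sf$min_peak_height, sf$bw_limits)
  raw_a <- raw_band_peak(psd, config$bands$alpha)
  raw_b <- raw_band_peak(psd, config$bands$beta)
  env <- mu_beta_envelope(recording, config$burst$band)
  bs <- burst_settings(band = config$burst$band,
                       threshold_factor = config$burst$threshold_factor,
                       edge_rule = config$burst$edge_rule,
                       threshold_abs = config$burst$threshold_abs)
  events <- detect_bursts(env, bs)
  analyzed_s <- recording_duration(recording)
  bsum <- summarize_bursts(events, analyzed_s)
  pk <- function(p, what) if (is.null(p)) NA_real_ else p[[what]]
  feats <- data.frame(
    subject_id = recording$subject_id,
    alpha_power = pk(fit$alpha_peak, "height"),
    alpha_cf = pk(fit$alpha_peak, "centre_freq"),
    beta_power = pk(fit$beta_peak, "height"),
    beta_cf = pk(fit$beta_peak, "centre_freq"),
    aperiodic_offset = fit$offset,
    aperiodic_exponent = fit$exponent,
    alpha_power_raw = raw_a$power, alpha_cf_raw = raw_a$centre_freq,
    beta_power_raw = raw_b$power, beta_cf_raw = raw_b$centre_freq,
    r_squared = fit$r_squared,
    stringsAsFactors = FALSE
  )
  feats <- cbind(feats, bsum)
  if (nrow(events)) events <- cbind(subject_id = recording$subject_id, events)
  list(features = feats, events = events)
}

resolve_recordings <- function(config) {
  sim <- config$simulate
  if (length(config$inputs$recordings)) {
    recs <- lapply(config$inputs$recordings, read_recording)
  } else if (identical(sim$mode, "signals")) {
    n <- sim$n_subjects
    recs <- lapply(seq_len(n), function(i) {
      sp <- do.call(signal_params,
                    c(sim$signal, list(seed = config$seed + i)))
      r <- if (sp$burst_rate > 0) generate_burst_train(sp) else
        generate_aperiodic_signal(sp)
      r$subject_id <- sprintf("sim-%03d", i)
      r
    })
  } else {
    recs <- list()
  }
  recs
}

#' Run the feature-extraction stage over all subjects
#'
#' Resolves the subject recordings (input files, or simulated signals
#' when none are configured), extracts features per subject, and joins
#' any subject covariate table. Per-subject failures are recorded and
#' the run continues; the error list is attached as attribute
#' `"errors"`.
#'
#' @param config a [pipeline_config()].
#' @return a feature table (`data.frame`, one row per subject) with the
#'   burst event table attached as attribute `"events"`.
#' @export
run_features <- function(config = pipeline_config()) {
  recs <- resolve_recordings(config)
  rows <- list(); events <- list(); errors <- list()
  for (r in recs) {
    res <- tryCatch(extract_features(r, config), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[r$subject_id]] <- conditionMessage(res)
      message("subject ", r$subject_id, " failed: ", conditionMessage(res))
      next
    }
    message(sprintf("subject %s: R2 = %.3f, %d burst events",
                    r$subject_id, res$features$r_squared,
                    res$features$n_events))
    rows[[length(rows) + 1]] <- res$features
    if (nrow(res$events)) events[[length(events) + 1]] <- res$events
  }
  if (length(recs) && !length(rows)) {
    stop_data("all subjects failed feature extraction")
  }
  tab <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (!is.null(config$inputs$subjects_csv)) {
    cov <- utils::read.csv(config$inputs$subjects_csv,
                           stringsAsFactors = FALSE)
    tab <- merge(tab, cov, by = "subject_id", all.x = TRUE, sort = FALSE)
  }
  attr(tab, "events") <- if (length(events)) do.call(rbind, events) else NULL
  attr(tab, "errors") <- errors
  tab
}

#' Run the statistical stage on a feature table
#'
#' Runs the sequential Bayes-factor model comparison for every
#' available signal feature and, when the table carries PD clinical
#' columns, the clinical symptom regressions, plus the demographic
#' group tests (Welch t on age, continuity-corrected chi-square on the
#' group-by-sex table). Flags every predictor with BF above the
#' evidence cut-off.
#'
#' @param features a feature table.
#' @param config a [pipeline_config()].
#' @param output_dir directory for the CSV/JSON outputs; `NULL` skips
#'   writing.
#' @return a report list: `feature_models`, `clinical_models`,
#'   `flagged` (data.frame of outcome/predictor with BF > cut-off),
#'   `demographics`, `settings`.
#' @export
run_stats <- function(features, config = pipeline_config(),
                      output_dir = NULL) {
  need <- c("group", "age", "sex", "cortical_thickness")
  miss <- setdiff(need, names(features))
  if (length(miss)) {
    stop_data("schema error: missing required column(s): ",
              paste(miss, collapse = ", "))
  }
  cutoff <- config$stats$bf_cutoff
  fm <- list()
  for (f in intersect(config$stats$features, names(features))) {
    fm[[f]] <- tryCatch(sequential_bf(features, f, config$stats$order),
                        error = function(e) e)
    if (inherits(fm[[f]], "error")) {
      message("feature model `", f, "` failed: ",
              conditionMessage(fm[[f]]))
    }
  }
  fm <- Filter(function(x) inherits(x, "model_comparison"), fm)

  cm <- list()
  have_clin <- all(c("disease_duration", "ledd") %in% names(features)) &&
    any(config$stats$subscales %in% names(features))
  if (have_clin) {
    for (s in intersect(config$stats$subscales, names(features))) {
      cm[[s]] <- tryCatch(clinical_regression(features, s),
                          error = function(e) e)
      if (inherits(cm[[s]], "error")) {
        message("clinical model `", s, "` failed: ",
                conditionMessage(cm[[s]]))
      }
    }
    cm <- Filter(function(x) inherits(x, "model_comparison"), cm)
  } else {
    message("no PD clinical columns found; clinical analysis skipped")
  }

  all_rows <- do.call(rbind, c(
    lapply(fm, function(m) cbind(outcome = m$outcome, m$table,
                                 analysis = "features")),
    lapply(cm, function(m) cbind(outcome = m$outcome, m$table,
                                 analysis = "clinical"))
  ))
  flagged <- if (is.null(all_rows)) NULL else
    all_rows[all_rows$bf10 > cutoff, c("analysis", "outcome", "predictor",
                                       "bf10")]

  grp <- tolower(as.character(features$group))
  is_pd <- grp %in% c("pd", "1")
  demo <- list()
  if (length(unique(is_pd)) == 2) {
    a1 <- features$age[is_pd]; a0 <- features$age[!is_pd]
    demo$age <- welch_t_test(mean(a1), sd(a1), length(a1),
                             mean(a0), sd(a0), length(a0))
    sx <- table(factor(ifelse(is_pd, "pd", "hc"), c("pd", "hc")),
                factor(tolower(as.character(features$sex)),
                       c("female", "male")))
    demo$sex <- yates_chi_square(sx)
    demo$sex_table <- as.data.frame.matrix(sx)
  }

  report <- list(feature_models = fm, clinical_models = cm,
                 results = all_rows, flagged = flagged,
                 demographics = demo, settings = unclass(config),
                 r_version = R.version.string)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(all_rows)) {
      utils::write.csv(all_rows, file.path(output_dir, "results.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      list(flagged = flagged, demographics = demo,
           settings = unclass(config), r_version = R.version.string),
      file.path(output_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE
    )
    write_pipeline_config(config, file.path(output_dir,
                                            "settings-used.yaml"))
  }
  report
}

#' Run the full pipeline (simulate/read, features, stats)
#'
#' @param config a [pipeline_config()].
#' @param output_dir directory for outputs; `NULL` skips writing.
#' @return the [run_stats()] report with the feature table attached as
#'   `$features`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  if (identical(config$simulate$mode, "cohort") &&
      !length(config$inputs$recordings)) {
    cp <- do.call(cohort_params,
                  c(config$simulate$cohort, list(seed = config$seed)))
    features <- generate_cohort(cp)
  } else {
    features <- run_features(config)
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(features, file.path(output_dir, "features.csv"),
                     row.names = FALSE)
    ev <- attr(features, "events")
    if (!is.null(ev)) {
      utils::write.table(
        ev[, c("subject_id", "onset_s", "offset_s", "peak_amplitude")],
        file.path(output_dir, "events.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE
      )
    }
  }
  report <- run_stats(features, config, output_dir)
  report$features <- features
  report
}
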