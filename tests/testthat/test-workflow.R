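small_cfg <- function(...) {
  pipeline_config(
    simulate = list(mode = "signals", n_subjects = 2L,
                    signal = list(duration_s = 30, fs = 250,
                                  aperiodic_offset = -20,
                                  aperiodic_exponent = 1.5,
                                  burst_rate = 20,
                                  burst_amplitude = 5e-9)),
    seed = 7L, ...
  )
}

test_that("run_features composes the per-stage calls exactly", {
  cfg <- small_cfg()
  tab <- suppressMessages(run_features(cfg))
  expect_identical(nrow(tab), 2L)
  # stage-by-stage oracle for the first subject
  sp <- do.call(signal_params,
                c(cfg$simulate$signal, list(seed = cfg$seed + 1)))
  rec <- generate_burst_train(sp)
  rec$subject_id <- "sim-001"
  psd <- welch_psd(rec, cfg$welch$segment_s, cfg$welch$overlap,
                   cfg$welch$fmin, cfg$welch$fmax)
  fit <- fit_spectral_model(psd)
  env <- mu_beta_envelope(rec, cfg$burst$band)
  ev <- detect_bursts(env, burst_settings())
  bs <- summarize_bursts(ev, recording_duration(rec))
  expect_equal(tab$aperiodic_exponent[1], fit$exponent)
  expect_equal(tab$aperiodic_offset[1], fit$offset)
  expect_equal(tab$n_events[1], bs$n_events)
  expect_equal(tab$burst_rate[1], bs$burst_rate)
  expect_equal(tab$r_squared[1], fit$r_squared)
  # determinism: identical reruns
  tab2 <- suppressMessages(run_features(cfg))
  attr(tab, "errors") <- NULL; attr(tab2, "errors") <- NULL
  expect_identical(tab, tab2)
})

test_that("run_features handles empty subject lists and bad inputs", {
  cfg <- pipeline_config(simulate = list(mode = "none"))
  tab <- suppressMessages(run_features(cfg))
  expect_identical(nrow(tab), 0L)
  # unreadable input is recorded per subject, the run continues
  cfg2 <- small_cfg()
  cfg2$simulate$signal$duration_s <- 30
  recs <- mubeta:::resolve_recordings(cfg2)
  short <- ts_recording(rnorm(100), 250, "bad")
  tmp <- tempfile(); tmp2 <- tempfile()
  write_recording(short, tmp); write_recording(recs[[1]], tmp2)
  cfg2$inputs$recordings <- c(tmp, tmp2)
  tab2 <- suppressMessages(run_features(cfg2))
  expect_identical(nrow(tab2), 1L)
  expect_length(attr(tab2, "errors"), 1L)
})

test_that("recording round-trips preserve the signal", {
  r <- ts_recording(rnorm(500), 250, "roundtrip")
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".f64")
  write_recording(r, p1, "tsv")
  b1 <- read_recording(p1)
  expect_equal(b1$samples, r$samples, tolerance = 1e-6)
  expect_equal(b1$fs, 250)
  write_recording(r, p2, "raw")
  b2 <- read_recording(p2)
  expect_identical(b2$samples, r$samples)
  expect_identical(b2$subject_id, "roundtrip")
})

test_that("pipeline config round-trips through YAML", {
  cfg <- pipeline_config(seed = 42L, burst = list(threshold_factor = 2.5))
  p <- tempfile(fileext = ".yaml")
  write_pipeline_config(cfg, p)
  cfg2 <- read_pipeline_config(p)
  expect_equal(cfg2$seed, 42L)
  expect_equal(cfg2$burst$threshold_factor, 2.5)
  expect_equal(cfg2$welch$segment_s, 3.072)
  expect_error(read_pipeline_config(tempfile()), "not found")
})

test_that("run_stats reports planted effects and demographics", {
  cfg <- pipeline_config(
    simulate = list(mode = "cohort",
                    cohort = list(n_pd = 100, n_hc = 100,
                                  coefficients = list(
                                    beta_power = c(group = 0.8)),
                                  noise_sd = c(beta_power = 1))),
    seed = 11L,
    stats = list(features = c("beta_power", "burst_rate"))
  )
  out <- tempfile()
  rep <- suppressMessages(run_pipeline(cfg, output_dir = out))
  expect_true("beta_power" %in% names(rep$feature_models))
  flagged <- rep$flagged
  expect_true(any(flagged$outcome == "beta_power" &
                    flagged$predictor == "group"))
  # demographics reproduce the module-level tests on the same table
  feats <- rep$features
  sx <- table(factor(feats$group, c("pd", "hc")),
              factor(feats$sex, c("female", "male")))
  expect_equal(rep$demographics$sex$chi2, yates_chi_square(sx)$chi2)
  expect_true(file.exists(file.path(out, "results.csv")))
  expect_true(file.exists(file.path(out, "report.json")))
  expect_true(file.exists(file.path(out, "features.csv")))
  # stats on the saved feature table equals the in-memory run
  saved <- read.csv(file.path(out, "features.csv"))
  rep2 <- suppressMessages(run_stats(saved, cfg))
  expect_equal(rep2$feature_models$beta_power$table$bf10,
               rep$feature_models$beta_power$table$bf10, tolerance = 1e-8)
  # clinical columns absent from this config subset: skipped cleanly
  expect_message(
    run_stats(feats[, setdiff(names(feats), c("disease_duration", "ledd"))],
              cfg),
    "skipped"
  )
  # schema errors name the missing columns
  expect_error(run_stats(feats[, c("beta_power", "age", "sex")], cfg),
               "group")
})

test_that("the CLI runs end to end with exit code 0", {
  out <- tempfile()
  cfgp <- tempfile(fileext = ".yaml")
  cfg <- pipeline_config(
    simulate = list(mode = "cohort", cohort = list(n_pd = 40, n_hc = 40)),
    stats = list(features = c("beta_power")), seed = 3L
  )
  write_pipeline_config(cfg, cfgp)
  status <- suppressMessages(
    mubeta_cli(c("all", "--config", cfgp, "--out", out))
  )
  expect_identical(status, 0L)
  expect_true(file.exists(file.path(out, "report.json")))
  expect_identical(suppressMessages(mubeta_cli(character(0))), 2L)
})
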