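make_table <- function(n = 60, seed = 1) {
  generate_cohort(cohort_params(n_pd = n / 2, n_hc = n / 2,
                                alpha_missing_prob = 0, seed = seed))
}

test_that("prepare_design builds the documented design", {
  d <- make_table(seed = 2)
  des <- prepare_design(d, "beta_power")
  dd <- des$data
  # hand-built oracle columns
  expect_equal(dd$group, as.numeric(d$group == "pd"))
  expect_equal(dd$sex, as.numeric(d$sex == "male"))
  expect_equal(dd$age, as.numeric(scale(d$age)))
  expect_equal(dd$age2, as.numeric(scale(d$age))^2)
  expect_equal(dd$thickness, as.numeric(scale(d$cortical_thickness)))
  expect_equal(dd$y, as.numeric(scale(d$beta_power)))
  # log-transform before z-scoring: {e, e^2, e^3} -> z of {1,2,3}
  d3 <- d[1:12, ]
  d3$burst_duration_ms <- rep(exp(1:3), 4)
  des3 <- prepare_design(d3, "burst_duration_ms")
  expect_equal(des3$data$y, as.numeric(scale(rep(1:3, 4))))
  # burst counts stay counts with minute exposure
  desb <- prepare_design(d, "burst_rate")
  expect_identical(desb$family, "poisson")
  expect_equal(desb$data$y, d$n_events)
  expect_equal(desb$data$exposure_min, d$analyzed_s / 60)
  # degenerate designs error
  d4 <- d; d4$age <- 70
  expect_error(prepare_design(d4, "beta_power"), "degenerate")
  # missing outcomes are dropped
  d5 <- d; d5$alpha_power[1:10] <- NA
  expect_equal(prepare_design(d5, "alpha_power")$n, nrow(d) - 10)
})

test_that("bic_bayes_factor matches the closed form and its properties", {
  expect_equal(bic_bayes_factor(10, 10), 1)
  expect_equal(bic_bayes_factor(2 * log(3), 0), 3)
  expect_error(bic_bayes_factor(NA, 1), "finite")
  # toy regression: BIC difference equals n*ln(RSS0/RSS1) + dp*ln(n)
  set.seed(3)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20)
  m0 <- lm(y ~ 1); m1 <- lm(y ~ x)
  # m1 spends one more parameter, so its penalty is one ln(n) larger
  hand <- 20 * log(sum(resid(m0)^2) / sum(resid(m1)^2)) - log(20)
  expect_equal(BIC(m0) - BIC(m1), hand, tolerance = 1e-10)
  expect_equal(bic_bayes_factor(BIC(m0), BIC(m1)), exp(hand / 2))
  # reciprocity
  for (i in 1:20) {
    a <- runif(1, -50, 50); b <- runif(1, -50, 50)
    expect_equal(bic_bayes_factor(a, b) * bic_bayes_factor(b, a), 1)
  }
})

test_that("sequential_bf is invariant to affine outcome rescaling", {
  d <- make_table(seed = 4)
  r1 <- sequential_bf(d, "beta_power")
  d2 <- d; d2$beta_power <- d2$beta_power * 13 - 5
  r2 <- sequential_bf(d2, "beta_power")
  expect_equal(r1$table$bf10, r2$table$bf10, tolerance = 1e-8)
  expect_equal(r1$table$estimate, r2$table$estimate, tolerance = 1e-8)
})

test_that("Poisson burst-rate models are exposure invariant", {
  d <- make_table(n = 80, seed = 5)
  r1 <- sequential_bf(d, "burst_rate")
  d2 <- d
  d2$n_events <- d2$n_events * 2L
  d2$analyzed_s <- d2$analyzed_s * 2
  d2$burst_rate <- d2$n_events / (d2$analyzed_s / 60)
  r2 <- sequential_bf(d2, "burst_rate")
  expect_equal(r1$table$estimate, r2$table$estimate, tolerance = 1e-6)
})

test_that("sequential_bf flags planted effects and stays calibrated", {
  # small smoke version; the full 200-seed calibration/power runs live
  # in the acceptance suite
  hits_null <- 0; hits_eff <- 0; nseed <- 25
  for (s in 1:nseed) {
    d0 <- generate_cohort(cohort_params(n_pd = 75, n_hc = 75,
                                        noise_sd = c(beta_power = 1),
                                        alpha_missing_prob = 0, seed = s))
    r0 <- sequential_bf(d0, "beta_power")
    hits_null <- hits_null + sum(r0$table$bf10 > 3)
    d1 <- generate_cohort(cohort_params(
      n_pd = 150, n_hc = 150,
      coefficients = list(beta_power = c(group = 0.5)),
      noise_sd = c(beta_power = 1), alpha_missing_prob = 0, seed = s))
    r1 <- sequential_bf(d1, "beta_power")
    hits_eff <- hits_eff + (r1$table$bf10[r1$table$predictor == "group"] > 3)
  }
  expect_lte(hits_null / (nseed * 11), 0.10)
  expect_gt(hits_eff / nseed, 0.8)
  # a pure-noise duplicated predictor is penalised (BF < 1 on average)
  set.seed(9)
  bfs <- sapply(1:25, function(i) {
    d <- make_table(seed = 100 + i)
    d$noise_copy <- rnorm(nrow(d))
    r <- sequential_bf(d, "beta_power",
                       order = c("group", "age", "noise_copy"))
    r$table$bf10[3]
  })
  expect_lt(mean(bfs), 1)
})

test_that("percent_effect converts coefficients to natural-scale changes", {
  d <- generate_cohort(cohort_params(
    n_pd = 75, n_hc = 75,
    coefficients = list(burst_rate = c(age = log(0.994), `group:age` = 0)),
    seed = 6))
  r <- sequential_bf(d, "burst_rate")
  # closed form: beta_age = ln(0.994)/yr is exactly -0.6 %/yr
  fake <- r
  fake$fit$coefficients["age"] <- log(0.994) * r$design$age_sd
  fake$fit$coefficients["group:age"] <- 0
  pe <- percent_effect(fake, "age", "pd")
  expect_equal(pe$percent, -0.6, tolerance = 1e-10)
  # beta = 0 -> 0%
  fake$fit$coefficients["age"] <- 0
  expect_equal(percent_effect(fake, "age", "pd")$percent, 0,
               tolerance = 1e-12)
  # estimated slope lands near the planted one
  pe2 <- percent_effect(r, "age", "pd")
  expect_lt(abs(pe2$percent - (-0.6)), 1)
  # Gaussian group contrast with a known planted difference
  dg <- generate_cohort(cohort_params(
    n_pd = 75, n_hc = 75, intercepts = c(beta_cf = 20),
    coefficients = list(beta_cf = c(group = -1)),
    noise_sd = c(beta_cf = 0.01), alpha_missing_prob = 0, seed = 7))
  rg <- sequential_bf(dg, "beta_cf")
  set.seed(1)
  peg <- percent_effect(rg, "group")
  expect_equal(peg$percent, 100 * (19 - 20) / 20, tolerance = 0.5)
  expect_lt(peg$ci_low, peg$percent)
  expect_gt(peg$ci_high, peg$percent)
})

test_that("clinical_regression recovers planted symptom effects", {
  d <- generate_cohort(cohort_params(
    n_pd = 78, n_hc = 2,
    clinical_coefficients = list(
      upper_bradykinesia_contra = c(burst_rate = -0.5)),
    alpha_missing_prob = 0, seed = 8))
  r <- clinical_regression(d, "upper_bradykinesia_contra")
  row <- r$table[r$table$predictor == "burst_rate", ]
  expect_lt(row$estimate, 0)
  expect_identical(nrow(r$table), 15L)
  # dropping a zero-effect predictor barely changes R2 in the
  # near-noiseless limit
  d2 <- generate_cohort(cohort_params(
    n_pd = 78, n_hc = 2,
    clinical_coefficients = list(rigidity = c(beta_power = 1)),
    clinical_noise_sd = 1e-4, alpha_missing_prob = 0, seed = 9))
  z <- function(v) as.numeric(scale(v))
  pd <- d2[d2$group == "pd", ]
  full <- summary(lm(z(rigidity) ~ z(beta_power) + z(alpha_power),
                     data = pd))$r.squared
  red <- summary(lm(z(rigidity) ~ z(beta_power), data = pd))$r.squared
  expect_lt(abs(full - red), 1e-2)
  # insufficient data errors
  expect_error(clinical_regression(d[1:15, ], "rigidity"), "insufficient")
})

test_that("welch_t_test and yates_chi_square match their formulas", {
  eq <- welch_t_test(5, 1, 10, 5, 2, 12)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  # pooled limit: equal n and sd -> df = n1 + n2 - 2
  pl <- welch_t_test(1, 2, 15, 0, 2, 15)
  expect_equal(pl$df, 28)
  # the study's age comparison from printed summaries
  tt <- welch_t_test(65.6, 9.5, 78, 63.93, 8.4, 60)
  expect_equal(tt$t, 1.09, tolerance = 0.005)
  expect_error(welch_t_test(1, 0, 5, 2, 1, 5), "> 0")
  # proportional table: continuity correction clamps to zero
  expect_equal(yates_chi_square(matrix(c(20, 40, 10, 20), 2))$chi2, 0)
  expect_error(yates_chi_square(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "marginal")
  # random tables vs the textbook formula
  set.seed(10)
  for (i in 1:50) {
    m <- matrix(rpois(4, 20) + 1, 2)
    E <- outer(rowSums(m), colSums(m)) / sum(m)
    want <- sum(pmax(abs(m - E) - 0.5, 0)^2 / E)
    expect_equal(yates_chi_square(m)$chi2, want, tolerance = 1e-10)
  }
})
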