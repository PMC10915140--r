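#' Prepare a regression design for one signal feature
#'
#' Builds the analysis data set for the feature-level models: group and
#' sex coded 0/1 (reference: healthy control, female), age and cortical
#' thickness centred and scaled to unit SD, age squared computed from
#' centred age. Gaussian outcomes are z-scored (the three positive
#' burst features are natural-log-transformed first); the burst count
#' outcome is left as a count with exposure equal to the analysed
#' minutes (Poisson family). Rows with a missing outcome are dropped.
#'
#' @param table a feature table (one row per subject).
#' @param outcome a feature column name; `"burst_rate"` selects the
#'   Poisson count model.
#' @return a `feature_design` list: `data` (columns `y`, `group`,
#'   `age`, `age2`, `sex`, `thickness`, and for counts `exposure_min`),
#'   `family`, `outcome`, and the centring/scaling constants needed to
#'   express effects on natural scales.
#' @export
prepare_design <- function(table, outcome) {
  if (!outcome %in% names(table)) stop_invalid("unknown outcome: ", outcome)
  keep <- !is.na(table[[outcome]])
  if (sum(keep) < 10) {
    stop_data("outcome `", outcome, "` present for fewer than 10 subjects")
  }
  d <- table[keep, , drop = FALSE]
  grp <- as.numeric(tolower(as.character(d$group)) %in% c("pd", "1"))
  sex <- as.numeric(tolower(as.character(d$sex)) %in% c("male", "m", "1"))
  for (v in c("age", "cortical_thickness")) {
    if (sd(d[[v]]) == 0) stop_invalid("degenerate design: `", v,
                                      "` has zero variance")
  }
  if (length(unique(grp)) < 2 && length(unique(d$group)) > 1) {
    stop_invalid("unrecognized group coding")
  }
  age_mean <- mean(d$age); age_sd <- sd(d$age)
  th_mean <- mean(d$cortical_thickness); th_sd <- sd(d$cortical_thickness)
  age_z <- (d$age - age_mean) / age_sd
  dd <- data.frame(group = grp, age = age_z, age2 = age_z^2, sex = sex,
                   thickness = (d$cortical_thickness - th_mean) / th_sd)
  fam <- "gaussian"
  y_mean <- NA_real_; y_sd <- NA_real_
  if (outcome == "burst_rate") {
    fam <- "poisson"
    if (!all(c("n_events", "analyzed_s") %in% names(d))) {
      stop_data("burst_rate model needs `n_events` and `analyzed_s` columns")
    }
    dd$y <- d$n_events
    dd$exposure_min <- d$analyzed_s / 60
  } else {
    y <- d[[outcome]]
    if (outcome %in% log_scale_features()) {
      if (any(y <= 0)) stop_invalid("`", outcome,
                                    "` must be strictly positive to log")
      y <- log(y)
    }
    y_mean <- mean(y); y_sd <- sd(y)
    if (y_sd == 0) stop_invalid("degenerate design: outcome has zero variance")
    dd$y <- (y - y_mean) / y_sd
  }
  structure(
    list(data = dd, family = fam, outcome = outcome, kept = which(keep),
         age_mean = age_mean, age_sd = age_sd,
         thickness_mean = th_mean, thickness_sd = th_sd,
         y_mean = y_mean, y_sd = y_sd, n = nrow(dd)),
    class = "feature_design"
  )
}

#' Bayes factor from two BIC values
#'
#' BIC approximation to the Bayes factor for model H1 over model H0:
#' `BF10 = exp((BIC_H0 - BIC_H1) / 2)`, interpretable as a Bayes factor
#' under a unit-information prior.
#'
#' @param bic_h0,bic_h1 BIC of the null and alternative model.
#' @return BF10 (> 0; 1 when the BICs are equal).
#' @export
bic_bayes_factor <- function(bic_h0, bic_h1) {
  if (!is.finite(bic_h0) || !is.finite(bic_h1)) {
    stop_invalid("BIC values must be finite")
  }
  exp((bic_h0 - bic_h1) / 2)
}

default_predictor_order <- function() {
  c("group", "age", "age2", "sex", "thickness",
    "group:age", "group:sex", "group:thickness",
    "age:sex", "age:thickness", "sex:thickness")
}

fit_feature_model <- function(design, terms) {
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  if (design$family == "poisson") {
    glm(stats::as.formula(paste("y ~", rhs, "+ offset(log(exposure_min))")),
        family = poisson(), data = design$data)
  } else {
    lm(stats::as.formula(paste("y ~", rhs)), data = design$data)
  }
}

#' Sequential Bayes-factor model comparison for one feature
#'
#' Fits the nested model sequence obtained by adding the predictors of
#' `order` one at a time (Gaussian least squares, or Poisson log-link
#' with a log-exposure offset for the burst count) and records, per
#' step, the Bayes factor for the model with the predictor (H1) against
#' the previous model without it (H0) via [bic_bayes_factor()]. Also
#' fits the full model and reports standardized coefficients with 95%
#' Wald intervals.
#'
#' @param table a feature table.
#' @param outcome feature column name.
#' @param order predictor sequence; the default adds the main effects
#'   group, age, age squared, sex, thickness and then the two-way
#'   interactions of the four predictors in lexical order.
#' @return a `model_comparison` list: `outcome`, `family`, `table`
#'   (`predictor`, `estimate`, `ci_low`, `ci_high`, `bf10`), `order`,
#'   plus the full `fit` and the `design` for downstream effect
#'   conversion.
#' @export
sequential_bf <- function(table, outcome, order = default_predictor_order()) {
  design <- prepare_design(table, outcome)
  # any extra (non-standard) predictors in `order` are pulled from the
  # table, z-scored, matching the treatment of the built-in continuous
  # predictors
  mains <- unique(unlist(strsplit(order, ":", fixed = TRUE)))
  extra <- setdiff(mains, names(design$data))
  for (v in extra) {
    if (!v %in% names(table)) stop_invalid("unknown predictor: ", v)
    col <- table[[v]][design$kept]
    design$data[[v]] <- (col - mean(col)) / sd(col)
  }
  fits <- vector("list", length(order) + 1L)
  fits[[1]] <- fit_feature_model(design, character(0))
  bics <- numeric(length(order) + 1L)
  bics[1] <- BIC(fits[[1]])
  bf <- numeric(length(order))
  for (k in seq_along(order)) {
    fits[[k + 1]] <- tryCatch(
      fit_feature_model(design, order[seq_len(k)]),
      error = function(e) stop_data("fit failure at step `", order[k],
                                    "`: ", conditionMessage(e))
    )
    bics[k + 1] <- BIC(fits[[k + 1]])
    bf[k] <- bic_bayes_factor(bics[k], bics[k + 1])
  }
  full <- fits[[length(fits)]]
  est <- coef(full)[order]
  se <- sqrt(diag(vcov(full)))[order]
  res <- data.frame(predictor = order, estimate = unname(est),
                    ci_low = unname(est - qnorm(0.975) * se),
                    ci_high = unname(est + qnorm(0.975) * se),
                    bf10 = bf)
  structure(
    list(outcome = outcome, family = design$family, table = res,
         order = order, fit = full, design = design),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %s (%s family), n = %d\n",
              x$outcome, x$family, x$design$n %||% nrow(x$fit$model)))
  tab <- x$table
  tab$flag <- ifelse(tab$bf10 > 3, "*", "")
  print(format(tab, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Express a model effect as a percent change on the natural scale
#'
#' For Poisson (burst count) models, returns `100 * (exp(beta) - 1)`
#' per unit of the predictor on its original scale: per year for age
#' (combining the age main effect with the group-by-age interaction for
#' the requested group), or the group contrast itself. For Gaussian
#' models, returns the fitted group difference as a percentage of the
#' fitted healthy-control mean at the covariate means, with the
#' interval obtained by parametric resampling of the coefficients.
#'
#' @param result a `model_comparison` from [sequential_bf()].
#' @param predictor `"age"` or `"group"`.
#' @param group group whose slope is requested (Poisson age effect):
#'   `"pd"` or `"hc"`.
#' @param n_draws resampling draws for the Gaussian interval.
#' @return list with `percent`, `ci_low`, `ci_high`.
#' @export
percent_effect <- function(result, predictor = c("age", "group"),
                           group = c("pd", "hc"), n_draws = 10000) {
  stopifnot(inherits(result, "model_comparison"))
  predictor <- match.arg(predictor)
  group <- match.arg(group)
  co <- coef(result$fit)
  V <- vcov(result$fit)
  if (result$family == "poisson") {
    if (predictor == "age") {
      g <- as.numeric(group == "pd")
      w <- setNames(numeric(length(co)), names(co))
      if (!"age" %in% names(co)) stop_invalid("model has no age term")
      w["age"] <- 1
      if ("group:age" %in% names(co)) w["group:age"] <- g
      beta_z <- sum(w * co)
      se_z <- sqrt(as.numeric(t(w) %*% V %*% w))
      b <- beta_z / result$design$age_sd       # per year
      s <- se_z / result$design$age_sd
    } else {
      b <- co[["group"]]
      s <- sqrt(V["group", "group"])
    }
    return(list(percent = 100 * (exp(b) - 1),
                ci_low = 100 * (exp(b - qnorm(0.975) * s) - 1),
                ci_high = 100 * (exp(b + qnorm(0.975) * s) - 1)))
  }
  # Gaussian: percent group difference at covariate means (all centred
  # covariates at zero), back-transformed to the outcome's raw scale.
  if (predictor != "group") {
    stop_invalid("Gaussian percent effects are defined for `group`")
  }
  pct_of <- function(cv) {
    mu_hc <- result$design$y_mean + result$design$y_sd * cv[["(Intercept)"]]
    mu_pd <- mu_hc + result$design$y_sd * cv[["group"]]
    if (result$outcome %in% log_scale_features()) {
      # log-scale outcome: a difference in log is itself a ratio
      return(100 * (exp(result$design$y_sd * cv[["group"]]) - 1))
    }
    if (mu_hc == 0) return(NA_real_)
    100 * (mu_pd - mu_hc) / mu_hc
  }
  est <- pct_of(co)
  if (!is.finite(est)) stop_invalid("undefined percent: fitted control mean is zero")
  draws <- MASS::mvrnorm(n_draws, co, V)
  pcts <- apply(draws, 1, function(r) pct_of(as.list(r)))
  list(percent = est,
       ci_low = unname(quantile(pcts, 0.025, na.rm = TRUE)),
       ci_high = unname(quantile(pcts, 0.975, na.rm = TRUE)))
}

#' Clinical symptom regression with leave-one-predictor-out Bayes factors
#'
#' Models one motor-symptom subscale in the PD group as a linear
#' function of the ten sensorimotor signal features plus age, sex,
#' disease duration, LEDD, and cortical thickness. The symptom score
#' and all continuous predictors except age are z-transformed. Evidence
#' per predictor is the Bayes factor of the full model (H1) against the
#' model without that predictor (H0), via the BIC approximation.
#' Subjects missing any used column (e.g. no alpha peak) are excluded
#' listwise.
#'
#' @param pd_table feature table restricted to (or filtered for) PD
#'   subjects.
#' @param symptom a subscale column name.
#' @param features signal feature predictors (default all ten).
#' @param covariates nuisance covariates.
#' @return a `model_comparison` with one row per predictor.
#' @export
clinical_regression <- function(pd_table, symptom,
                                features = feature_names(),
                                covariates = c("age", "sex",
                                               "disease_duration", "ledd",
                                               "cortical_thickness")) {
  d <- pd_table[tolower(as.character(pd_table$group)) %in% c("pd", "1"), ,
                drop = FALSE]
  if (!symptom %in% names(d)) stop_invalid("unknown symptom: ", symptom)
  used <- c(symptom, features, covariates)
  miss <- setdiff(used, names(d))
  if (length(miss)) stop_data("missing columns: ", paste(miss, collapse = ", "))
  d <- d[stats::complete.cases(d[, used, drop = FALSE]), , drop = FALSE]
  preds <- c(features, covariates)
  if (nrow(d) <= length(preds) + 2) {
    stop_data("insufficient data: n = ", nrow(d), " for ", length(preds),
              " predictors")
  }
  z <- function(v) (v - mean(v)) / sd(v)
  dd <- data.frame(y = z(d[[symptom]]))
  for (p in preds) {
    v <- d[[p]]
    if (p == "sex") {
      v <- as.numeric(tolower(as.character(v)) %in% c("male", "m", "1"))
    } else if (p != "age") {
      if (sd(v) == 0) stop_invalid("degenerate design: `", p,
                                   "` has zero variance")
      v <- z(v)
    }
    dd[[p]] <- v
  }
  full <- lm(stats::as.formula(paste("y ~", paste(preds, collapse = " + "))),
             data = dd)
  bic_full <- BIC(full)
  bf <- vapply(preds, function(p) {
    red <- lm(stats::as.formula(
      paste("y ~", paste(setdiff(preds, p), collapse = " + "))), data = dd)
    bic_bayes_factor(BIC(red), bic_full)
  }, numeric(1))
  est <- coef(full)[preds]
  se <- sqrt(diag(vcov(full)))[preds]
  res <- data.frame(predictor = preds, estimate = unname(est),
                    ci_low = unname(est - qnorm(0.975) * se),
                    ci_high = unname(est + qnorm(0.975) * se),
                    bf10 = unname(bf))
  structure(
    list(outcome = symptom, family = "gaussian", table = res,
         order = preds, fit = full,
         design = list(n = nrow(dd))),
    class = "model_comparison"
  )
}

#' Welch's unequal-variance t test from summary statistics
#'
#' @param mean1,sd1,n1 summary statistics of the first group.
#' @param mean2,sd2,n2 summary statistics of the second group.
#' @return list with `t`, `df` (Welch-Satterthwaite), and two-sided `p`.
#' @export
welch_t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop_invalid("group sizes must be >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop_invalid("standard deviations must be > 0")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Yates continuity-corrected chi-square test of independence (2x2)
#'
#' `chi2 = sum(max(|O - E| - 0.5, 0)^2 / E)` with 1 degree of freedom.
#'
#' @param table2x2 a 2x2 matrix of counts.
#' @return list with `chi2` and two-sided `p`.
#' @export
yates_chi_square <- function(table2x2) {
  m <- as.matrix(table2x2)
  if (!all(dim(m) == c(2, 2))) stop_invalid("need a 2x2 table")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop_invalid("invalid table: zero marginal")
  }
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  chi2 <- sum(pmax(abs(m - E) - 0.5, 0)^2 / E)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}
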