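# The crossover statistical stage: REML mixed models with Satterthwaite
# F-tests, effect sizes, Tukey post hocs and group-characteristic comparisons.

#' Fit the crossover mixed model
#'
#' REML linear mixed model with the full factorial of condition, timepoint and
#' group as fixed effects (plus optional covariates) and a random intercept
#' per participant; F-tests use Satterthwaite denominator degrees of freedom.
#' A singular random-intercept fit is downgraded, with a warning, to a
#' fixed-effects model (the design is balanced, so the factor tests remain
#' well defined).
#'
#' @param table A `trial_table` / long-format data.frame with columns
#'   `participant`, `group`, `condition`, `timepoint` and the outcome.
#' @param outcome Name of the outcome column (default `"outcome"`).
#' @param covariates Character vector of additional covariate columns.
#' @return List of class `crossover_fit`: `model` (the fitted object),
#'   `effects` (one row per fixed term: `term`, `F`, `df1`, `df2`, `p`,
#'   `omega_sq`, `partial_eta_sq`), `singular`.
#' @export
fit_crossover_model <- function(table, outcome = "outcome", covariates = NULL) {
  stopifnot(is.data.frame(table),
            all(c("participant", "group", "condition", "timepoint") %in% names(table)),
            outcome %in% names(table))
  if (!is.numeric(table[[outcome]])) stop("outcome must be numeric")
  dat <- as.data.frame(table)
  for (f in c("participant", "group", "condition", "timepoint"))
    dat[[f]] <- factor(dat[[f]])
  rhs <- "condition * timepoint * group"
  if (!is.null(covariates) && length(covariates))
    rhs <- paste(rhs, "+", paste(covariates, collapse = " + "))
  form <- stats::as.formula(paste(outcome, "~", rhs, "+ (1 | participant)"))
  fit <- lmerTest::lmer(form, data = dat, REML = TRUE)
  singular <- lme4::isSingular(fit, tol = 1e-4)
  if (singular) {
    warning("singular random-intercept fit; downgrading to a fixed-effects model")
    form_fe <- stats::as.formula(paste(outcome, "~", rhs))
    fe <- stats::lm(form_fe, data = dat)
    an <- stats::anova(fe)
    terms <- rownames(an)[rownames(an) != "Residuals"]
    eff <- data.frame(term = terms,
                      F = an$`F value`[seq_along(terms)],
                      df1 = an$Df[seq_along(terms)],
                      df2 = an$Df[nrow(an)],
                      p = an$`Pr(>F)`[seq_along(terms)])
  } else {
    an <- stats::anova(fit, type = 3)   # Satterthwaite ddf (lmerTest)
    eff <- data.frame(term = rownames(an),
                      F = an$`F value`,
                      df1 = an$NumDF,
                      df2 = an$DenDF,
                      p = an$`Pr(>F)`)
  }
  eff$omega_sq <- omega_squared(eff$F, eff$df1, eff$df2)
  eff$partial_eta_sq <- partial_eta_squared(eff$F, eff$df1, eff$df2)
  rownames(eff) <- NULL
  structure(list(model = if (singular) fe else fit, effects = eff,
                 singular = singular),
            class = "crossover_fit")
}

#' Omega-squared effect size from an F statistic
#'
#' `omega^2 = df1 (F - 1) / (df1 (F - 1) + df1 + df2 + 1)`. Negative values
#' (F < 1) are returned as computed; presentation rounding is the caller's
#' concern.
#'
#' @param F F statistic (>= 0), vectorised.
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Omega squared.
#' @export
omega_squared <- function(F, df1, df2) {
  stopifnot(all(F >= 0), all(df1 > 0), all(df2 > 0))
  df1 * (F - 1) / (df1 * (F - 1) + df1 + df2 + 1)
}

#' Partial eta-squared effect size from an F statistic
#'
#' `eta_p^2 = F df1 / (F df1 + df2)`, with the conventional benchmark label
#' (small < 0.05, medium < 0.25, large > 0.25) attached as an attribute.
#'
#' @inheritParams omega_squared
#' @return Partial eta squared with attribute `benchmark`.
#' @export
partial_eta_squared <- function(F, df1, df2) {
  stopifnot(all(F >= 0), all(df1 > 0), all(df2 > 0))
  v <- F * df1 / (F * df1 + df2)
  attr(v, "benchmark") <- ifelse(v < 0.05, "small",
                                 ifelse(v < 0.25, "medium", "large"))
  v
}

#' Tukey-adjusted post hoc contrasts for a model term
#'
#' All pairwise contrasts of the estimated marginal means of `term`, with
#' studentized-range (Tukey) adjustment within the family.
#'
#' @param fit A `crossover_fit` (or a model `emmeans` accepts).
#' @param term Factor term, e.g. `"condition"` or `"condition:timepoint"`.
#' @return data.frame with `contrast`, `estimate`, `lower_cl`, `upper_cl`,
#'   `p_tukey`, `p_raw`.
#' @export
tukey_posthoc <- function(fit, term) {
  model <- if (inherits(fit, "crossover_fit")) fit$model else fit
  spec <- stats::as.formula(paste("~", term))
  em <- try(emmeans::emmeans(model, spec), silent = TRUE)
  if (inherits(em, "try-error"))
    stop("term '", term, "' is not part of the fitted model")
  prs <- emmeans::contrast(em, method = "pairwise", adjust = "tukey")
  ci <- as.data.frame(stats::confint(prs))
  prs_df <- as.data.frame(prs)
  raw <- as.data.frame(emmeans::contrast(em, method = "pairwise", adjust = "none"))
  data.frame(contrast = prs_df$contrast,
             estimate = prs_df$estimate,
             lower_cl = ci$lower.CL,
             upper_cl = ci$upper.CL,
             p_tukey = prs_df$p.value,
             p_raw = raw$p.value)
}

#' Welch comparison of two groups
#'
#' Welch's unequal-variance t test with 95% confidence interval of the mean
#' difference; when either sample fails a Shapiro-Wilk normality check at
#' 0.05, a Mann-Whitney U test is computed alongside as the robustness check.
#'
#' @param x,y Numeric samples (n >= 2 each).
#' @param shapiro_alpha Normality-gate level (default 0.05).
#' @return List of class `welch_compare`: `estimate` (mean(x) - mean(y)),
#'   `conf_int`, `t`, `df`, `p`, `normal` (gate result), `mann_whitney_p`
#'   (`NA` unless the gate failed).
#' @export
welch_compare <- function(x, y, shapiro_alpha = 0.05) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    d <- mean(x) - mean(y)
    return(structure(list(estimate = d, conf_int = c(d, d),
                          t = if (d == 0) 0 else Inf, df = NA_real_,
                          p = if (d == 0) 1 else 0,
                          normal = NA, mann_whitney_p = NA_real_),
                     class = "welch_compare"))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  sw <- function(v) if (length(unique(v)) < 3) 0 else stats::shapiro.test(v)$p.value
  normal <- sw(x) >= shapiro_alpha && sw(y) >= shapiro_alpha
  mw <- if (!normal)
    suppressWarnings(stats::wilcox.test(x, y)$p.value) else NA_real_
  structure(list(estimate = unname(tt$estimate[1] - tt$estimate[2]),
                 conf_int = unname(tt$conf.int),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, normal = normal, mann_whitney_p = mw),
            class = "welch_compare")
}

#' Sample size for a generic F test (a-priori power utility)
#'
#' Smallest total sample size at which an F test with `df1` numerator degrees
#' of freedom and noncentrality `f_effect^2 * N` reaches the requested power.
#' Documented utility for planning; not a pipeline stage.
#'
#' @param f_effect Cohen's f effect size.
#' @param df1 Numerator degrees of freedom.
#' @param alpha Significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @param n_max Search bound.
#' @return Smallest `N` reaching the target power.
#' @export
power_f_test <- function(f_effect, df1, alpha = 0.05, power = 0.8,
                         n_max = 1000L) {
  stopifnot(f_effect > 0, df1 >= 1)
  for (N in seq(df1 + 2L, n_max)) {
    df2 <- N - df1 - 1L
    ncp <- f_effect^2 * N
    crit <- stats::qf(1 - alpha, df1, df2)
    if (1 - stats::pf(crit, df1, df2, ncp = ncp) >= power) return(N)
  }
  stop("target power not reached within n_max")
}

#' @export
print.crossover_fit <- function(x, ...) {
  cat("<crossover_fit>", if (x$singular) "(singular, fixed-effects fallback)" else
    "(REML random intercept)", "\n")
  eff <- x$effects
  eff$F <- round(eff$F, 2); eff$df2 <- round(eff$df2, 1)
  eff$p <- signif(eff$p, 3)
  eff$omega_sq <- round(eff$omega_sq, 2)
  eff$partial_eta_sq <- round(eff$partial_eta_sq, 3)
  print(eff)
  invisible(x)
}

#' @export
print.welch_compare <- function(x, ...) {
  cat(sprintf("<welch_compare> diff %.3f [%.3f, %.3f], t=%.2f df=%.1f p=%.4g%s\n",
              x$estimate, x$conf_int[1], x$conf_int[2], x$t, x$df, x$p,
              if (!is.na(x$mann_whitney_p))
                sprintf(" (Mann-Whitney p=%.4g)", x$mann_whitney_p) else ""))
  invisible(x)
}
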