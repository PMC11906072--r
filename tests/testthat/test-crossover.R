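# Mixed-model stage, effect sizes, post hocs, group comparisons.

test_that("omega squared is zero at F=1 and monotone in F", {
  expect_equal(omega_squared(1, 3, 40), 0)
  Fs <- seq(0.2, 8, by = 0.2)
  expect_true(all(diff(omega_squared(Fs, 3, 40)) > 0))
  expect_lt(omega_squared(0.4, 3, 40), 0)   # negative values pass through
})

test_that("partial eta squared matches its formula and benchmark labels", {
  expect_equal(unname(partial_eta_squared(0, 1, 10))[1], 0)
  v <- partial_eta_squared(4.48, 2, 43)
  expect_equal(as.numeric(v), 4.48 * 2 / (4.48 * 2 + 43), tolerance = 1e-12)
  expect_equal(round(as.numeric(v), 3), 0.172)
  labs <- attr(partial_eta_squared(c(0.3, 2, 30), 2, 40), "benchmark")
  expect_equal(labs, c("small", "medium", "large"))
})

test_that("the mixed-model F equals the classical repeated-measures F on balanced data", {
  tt <- generate_trial_table(trial_gen_spec(n_per_group = 6, seed = 21))
  fit <- suppressMessages(fit_crossover_model(tt))
  dat <- as.data.frame(tt)
  for (f in c("participant", "group", "condition", "timepoint"))
    dat[[f]] <- factor(dat[[f]])
  cl <- summary(stats::aov(outcome ~ condition * timepoint * group +
                             Error(participant), data = dat))
  within <- cl[["Error: Within"]][[1]]
  rownames(within) <- trimws(rownames(within))
  for (term in c("condition", "timepoint", "condition:timepoint",
                 "condition:timepoint:group")) {
    expect_equal(fit$effects$F[fit$effects$term == term],
                 within[term, "F value"], tolerance = 1e-6)
  }
  between <- cl[["Error: participant"]][[1]]
  rownames(between) <- trimws(rownames(between))
  expect_equal(fit$effects$F[fit$effects$term == "group"],
               between["group", "F value"], tolerance = 1e-6)
})

test_that("adding a constant to the outcome changes no F statistic", {
  tt <- generate_trial_table(trial_gen_spec(n_per_group = 4, seed = 22))
  f1 <- suppressMessages(fit_crossover_model(tt))
  tt$outcome <- tt$outcome + 1000
  f2 <- suppressMessages(fit_crossover_model(tt))
  expect_equal(f1$effects$F, f2$effects$F, tolerance = 1e-8)
})

test_that("an injected cell shift is flagged by the Tukey post hoc with high power", {
  # -8 units at one condition x timepoint x group cell, residual SD 5, n 12:
  # a contrast involving the shifted cell must reach Tukey significance
  em <- data.frame(condition = "BIKE", timepoint = "10", group = "middle",
                   shift = -8)
  hits <- vapply(1:25, function(i) {
    tt <- generate_trial_table(trial_gen_spec(n_per_group = 12,
                                              residual_sd = 5,
                                              effect_map = em,
                                              seed = 3000 + i))
    fit <- suppressMessages(fit_crossover_model(tt))
    ph <- suppressMessages(tukey_posthoc(fit, "condition:timepoint:group"))
    inv <- grepl("BIKE 10 middle", as.character(ph$contrast))
    any(ph$p_tukey[inv] < 0.05)
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})

test_that("Tukey post hocs cover the full contrast family and dominate raw p", {
  em <- data.frame(condition = rep("BIKE", 2), timepoint = c("10", "20"),
                   group = rep(c("young", "middle"), each = 1),
                   shift = c(-10, -10))
  tt <- generate_trial_table(trial_gen_spec(n_per_group = 8, effect_map = em,
                                            seed = 31))
  fit <- suppressMessages(fit_crossover_model(tt))
  ph <- suppressMessages(tukey_posthoc(fit, "condition"))
  expect_equal(nrow(ph), choose(4, 2))
  expect_true(all(ph$p_tukey >= ph$p_raw - 1e-12))
  expect_true(all(ph$lower_cl <= ph$estimate & ph$estimate <= ph$upper_cl))
  # the shifted condition owns the smallest adjusted p
  best <- ph$contrast[which.min(ph$p_tukey)]
  expect_match(as.character(best), "BIKE")
  expect_error(suppressMessages(tukey_posthoc(fit, "no_such_term")),
               "not part")
})

test_that("two literally identical cell means give an adjusted p of 1", {
  tt <- generate_trial_table(trial_gen_spec(n_per_group = 6, seed = 32))
  # force CON and BIKE to carry identical data per participant/timepoint
  key <- paste(tt$participant, tt$timepoint)
  con <- tt$condition == "CON"; bike <- tt$condition == "BIKE"
  tt$outcome[bike] <- tt$outcome[con][match(key[bike], key[con])]
  fit <- suppressMessages(fit_crossover_model(tt))
  ph <- suppressMessages(tukey_posthoc(fit, "condition"))
  row <- grepl("BIKE", ph$contrast) & grepl("CON", ph$contrast)
  expect_equal(ph$estimate[row], 0, tolerance = 1e-9)
  expect_equal(ph$p_tukey[row], 1, tolerance = 1e-6)
})

test_that("Welch comparison matches t.test and activates the rank fallback", {
  withr::with_seed(40, {
    x <- rnorm(12, 2.06, 0.8)
    y <- rnorm(12, 2.78, 0.85)
  })
  wc <- welch_compare(x, y)
  tt <- t.test(x, y)
  expect_equal(wc$estimate, unname(tt$estimate[1] - tt$estimate[2]))
  expect_equal(wc$p, tt$p.value)
  expect_true(is.na(wc$mann_whitney_p))   # normal samples: no fallback
  expect_equal(welch_compare(x, x)$estimate, 0)
  withr::with_seed(41, xs <- exp(rnorm(20, 0, 1.5)))  # heavily skewed
  ys <- xs * 3
  ws <- welch_compare(xs, ys)
  expect_false(ws$normal)
  expect_false(is.na(ws$mann_whitney_p))
  # zero-variance degenerate case
  expect_equal(welch_compare(rep(1, 5), rep(1, 5))$p, 1)
})

test_that("the singular fallback still reports the factorial F table", {
  tt <- generate_trial_table(trial_gen_spec(n_per_group = 4,
                                            between_subject_sd = 5,
                                            residual_sd = 5, seed = 50))
  # erase the participant structure so the intercept variance collapses
  tt$outcome <- withr::with_seed(51, rnorm(nrow(tt)))
  fit <- suppressMessages(suppressWarnings(fit_crossover_model(tt)))
  expect_equal(nrow(fit$effects), 7L)
  expect_true(all(is.finite(fit$effects$F)))
})

test_that("the generic F-test power utility brackets a hand-checked case", {
  # large effect needs few subjects, small effect needs more
  n_small <- power_f_test(0.4, df1 = 1)
  n_large <- power_f_test(0.15, df1 = 1)
  expect_lt(n_small, n_large)
  N <- power_f_test(0.25, df1 = 2)
  crit <- qf(0.95, 2, N - 3)
  expect_gte(1 - pf(crit, 2, N - 3, ncp = 0.25^2 * N), 0.8)
  expect_lt(1 - pf(qf(0.95, 2, N - 4), 2, N - 4, ncp = 0.25^2 * (N - 1)), 0.8)
})
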