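# Weir energy expenditure, steady-state search, intensities, VO2peak.

test_that("the Weir equation matches its closed form and is linear", {
  expect_equal(weir_ree(250, 200), 1.44 * (3.94 * 250 + 1.11 * 200))  # 1738.08
  expect_equal(weir_ree(250, 200), 1738.1, tolerance = 0.1)
  expect_equal(weir_ree(500, 400), 2 * weir_ree(250, 200))
  expect_equal(weir_ree(250, 200, per_minute = TRUE),
               weir_ree(250, 200) / 1440)
  expect_error(weir_ree(0, 100), "positive")
  expect_error(weir_ree(-5, 100), "positive")
  # strictly increasing in both flows
  expect_gt(weir_ree(260, 200), weir_ree(250, 200))
  expect_gt(weir_ree(250, 210), weir_ree(250, 200))
})

test_that("steady-state search returns the embedded compliant window only", {
  g <- generate_gas_trace(gas_gen_spec(cv_inside = 0.02, seed = 1))
  ss <- find_steady_state(g)
  emb <- attr(g, "steady_interval_min")
  expect_gte(ss$interval_min[1], emb[1])
  expect_lte(ss$interval_min[2], emb[2])
  expect_gt(ss$interval_min[1], 5)   # discarded first 5 minutes never used
})

test_that("traces with no compliant window raise the no-steady-state error", {
  withr::with_seed(2, {
    bad <- data.frame(t_min = 1:15,
                      vo2_ml_min = 250 * (1 + 0.3 * rnorm(15)),
                      vco2_ml_min = 210 * (1 + 0.3 * rnorm(15)))
  })
  bad$vo2_ml_min <- abs(bad$vo2_ml_min) + 50
  bad$vco2_ml_min <- abs(bad$vco2_ml_min) + 50
  cv <- function(x) sd(x) / mean(x)
  ok <- any(vapply(6:11, function(s) {
    sel <- bad$t_min >= s & bad$t_min <= s + 4
    cv(bad$vo2_ml_min[sel]) <= 0.1 && cv(bad$vco2_ml_min[sel]) <= 0.1
  }, logical(1)))
  expect_false(ok)  # construction check: every window is non-compliant
  expect_error(find_steady_state(bad), "no steady state")
})

test_that("among several compliant windows the lowest-REE one wins", {
  # two flat plateaus inside the search range; minutes 6-10 higher flows
  tr <- data.frame(t_min = 1:15,
                   vo2_ml_min = c(rep(400, 5), rep(260, 5), rep(250, 5)),
                   vco2_ml_min = c(rep(360, 5), rep(225, 5), rep(215, 5)))
  ss <- find_steady_state(tr)
  expect_equal(ss$interval_min, c(11, 15))
  expect_equal(ss$ree_kcal_day, weir_ree(250, 215))
})

test_that("session energy honours the AEE identity to machine precision", {
  g <- generate_gas_trace(gas_gen_spec(duration_min = 15, cv_inside = 0,
                                       seed = 3))
  ree <- find_steady_state(g)$ree_kcal_day
  cls <- generate_gas_trace(gas_gen_spec(duration_min = 45,
                                         activity_multiplier = 4,
                                         steady_start_min = 10,
                                         cv_inside = 0.05, seed = 4),
                            phase = "class")
  sess <- bind_gas_traces(g, cls)
  en <- session_energy(sess, ree, "class")
  expect_equal(en$aee_kcal + 0.1 * en$tee_kcal + en$ree_over_session_kcal,
               en$tee_kcal, tolerance = 1e-12)
  expect_equal(en$duration_min, 45L)
  expect_error(session_energy(sess, ree, "recovery"), "phase mark")
  # hand-check of the TEE arithmetic on a constant 45-min phase
  const <- data.frame(t_min = 1:45, vo2_ml_min = 1000, vco2_ml_min = 900,
                      phase = "class")
  en2 <- suppressWarnings(session_energy(const, ree, "class"))
  expect_equal(en2$tee_kcal, 45 * 1.44 * (3940 + 999) / 1440)  # 222.1 kcal
})

test_that("a purely resting session has near-zero activity energy", {
  g <- generate_gas_trace(gas_gen_spec(duration_min = 45, cv_inside = 0,
                                       steady_start_min = 20, seed = 5))
  g$phase <- "class"
  # AEE = TEE - REE_sess - 0.1 TEE vanishes when REE_sess = 0.9 TEE
  ree <- attr(g, "true_ree_kcal_day") * 0.9
  en <- suppressWarnings(session_energy(g, ree, "class"))  # tiny negative AEE ok
  expect_lt(abs(en$aee_kcal) / en$tee_kcal, 0.15)
})

test_that("intensity metrics are anchored at rest and peak", {
  tr <- data.frame(t_min = 1:3, vo2_ml_min = c(250, 1125, 2000),
                   hr_bpm = c(60, 120, 180))
  m <- intensity_metrics(tr, rest_vo2_ml_min = 250, vo2peak_ml_min = 2000,
                         rest_hr_bpm = 60, hrmax_bpm = 180)
  expect_equal(m$mets, c(1, 4.5, 8))
  expect_equal(m$pct_vo2_reserve, c(0, 50, 100))
  expect_equal(m$pct_hr_reserve, c(0, 50, 100))
  expect_false(any(m$out_of_range))
  expect_error(intensity_metrics(tr, 250, 200), "exceed")
})

test_that("VO2peak adjudication takes the last-minute maximum and counts criteria", {
  test_df <- data.frame(t_s = seq(10, 600, by = 10))
  test_df$vo2_ml_kg_min <- 10 + 0.05 * test_df$t_s
  test_df$hr_bpm <- 100 + 0.10 * test_df$t_s   # peaks at 160 < 0.9 * 195
  test_df$rer <- 0.8 + 0.0006 * test_df$t_s
  # peak RER 1.16 and RPE 19, HR below 90% predicted, no plateau info
  res <- adjudicate_vo2peak(test_df, age_years = 25, rpe_final = 19)
  expect_equal(res$vo2peak_ml_kg_min, max(test_df$vo2_ml_kg_min))
  expect_true(res$criteria_met[["rer_1.1"]])
  expect_true(res$criteria_met[["rpe_18"]])
  expect_false(res$criteria_met[["hr_near_max"]])
  expect_true(res$accepted)            # two criteria satisfied
  # only one criterion -> rejected
  res1 <- adjudicate_vo2peak(test_df, age_years = 25, rpe_final = 10)
  expect_false(res1$accepted)
  # plateau criterion: consecutive-stage increase of 1.4 < 2.0
  res2 <- adjudicate_vo2peak(test_df, age_years = 25, rpe_final = 10,
                             stage_delta_vo2 = c(3.1, 2.8, 1.4))
  expect_true(res2$criteria_met[["vo2_plateau"]])
  expect_true(res2$accepted)
  expect_error(adjudicate_vo2peak(test_df[1:3, ], 25), "60 s")
})
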