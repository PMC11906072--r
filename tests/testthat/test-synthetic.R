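# Generators: reproducibility, construction guarantees, ground truth.

test_that("every generator is seed-for-seed reproducible", {
  specs <- list(
    function(s) generate_rr(rr_gen_spec(duration_s = 60, hf_amp_ms = 20,
                                        noise_sd_ms = 5,
                                        ectopic_rate_per_min = 2, seed = s)),
    function(s) generate_baro_beats(baro_gen_spec(noise_sd_ms = 2, seed = s)),
    function(s) generate_wave_pair(wave_gen_spec(noise_sd = 1, seed = s,
                                                 fs_hz = 250)),
    function(s) generate_gas_trace(gas_gen_spec(seed = s)),
    function(s) generate_trial_table(trial_gen_spec(seed = s)))
  for (gen in specs) {
    a <- gen(42L); b <- gen(42L); c <- gen(43L)
    expect_identical(a, b)
    expect_false(identical(a, c))
  }
})

test_that("a silent spec yields a perfectly regular 150-beat tachogram", {
  b <- generate_rr(rr_gen_spec(duration_s = 120, mean_rr_ms = 800, seed = 1))
  expect_equal(nrow(b), 150L)
  expect_true(all(abs(b$rr_ms - 800) < 1e-12))
  expect_equal(b$time_s, cumsum(b$rr_ms) / 1000)
})

test_that("a pure HF tone spec places its periodogram peak at the tone frequency", {
  tw <- tone_window(0.25, seed = 2)
  ps <- welch_psd(tw$values_ms - mean(tw$values_ms), tw$fs_hz)
  expect_equal(ps$freq[which.max(ps$psd)], 0.25, tolerance = 0.02)
  # band power of a 30 ms tone ~ A^2/2 = 450 ms^2 by the periodogram oracle
  wp <- welch_band_power(tw$values_ms - mean(tw$values_ms), tw$fs_hz,
                         list(hf = c(0.15, 0.4)))
  expect_equal(unname(wp[["hf"]]), 450, tolerance = 0.10)
})

test_that("non-physiological RR specs are rejected", {
  expect_error(generate_rr(rr_gen_spec(duration_s = 60, mean_rr_ms = 220,
                                       hf_amp_ms = 100, seed = 1)),
               "200 ms")
})

test_that("exact linear SBP-RR coupling and sub-threshold construction behave as built", {
  b <- generate_baro_beats(baro_gen_spec(gain_ms_per_mmhg = 10,
                                         noise_sd_ms = 0, lag_beats = 0,
                                         n_beats = 60, seed = 1))
  d_rr <- diff(b$rr_ms); d_sbp <- diff(b$sbp_mmhg)
  expect_true(all(abs(d_rr - 10 * d_sbp) < 1e-9))
  # per-beat steps of 0.5 mmHg are invisible at the 1 mmHg threshold
  sub <- generate_baro_beats(baro_gen_spec(ramp_step_mmhg = 0.5,
                                           n_beats = 100, seed = 1))
  expect_equal(nrow(detect_ramps(sub$sbp_mmhg)), 0L)
})

test_that("the waveform pair encodes its transit delay and distance", {
  spec <- wave_gen_spec(fs_hz = 1000, delay_s = 0.100, distance_m = 0.875,
                        n_beats = 12, seed = 1)
  wp <- generate_wave_pair(spec)
  expect_equal(wp$meta$true_delay_s, 0.1)
  expect_equal(wp$distance_m * 0.8 / wp$meta$true_delay_s, 7.0)  # cf-corrected
  # noiseless feet recover the delay to within one sample
  fp <- detect_feet(wp$proximal, wp$fs_hz)
  fd <- detect_feet(wp$distal, wp$fs_hz)
  n <- min(length(fp), length(fd))
  expect_equal(mean(fd[1:n] - fp[1:n]), 0.1, tolerance = 1 / wp$fs_hz)
})

test_that("gas traces embed a steady state and record the true REE", {
  g <- generate_gas_trace(gas_gen_spec(cv_inside = 0.02, seed = 3))
  emb <- attr(g, "steady_interval_min")
  inside <- g$t_min >= emb[1] & g$t_min <= emb[2]
  cv <- function(x) sd(x) / mean(x)
  expect_lte(cv(g$vo2_ml_min[inside]), 0.02 + 1e-9)
  expect_gt(cv(g$vo2_ml_min[!inside]), 0.10)
  g0 <- generate_gas_trace(gas_gen_spec(cv_inside = 0, seed = 4))
  ss <- find_steady_state(g0)
  expect_equal(ss$ree_kcal_day, attr(g0, "true_ree_kcal_day"))
  expect_error(gas_gen_spec(steady_start_min = 14, steady_len_min = 5),
               "inside the trace")
})

test_that("trial tables have the balanced crossover layout and record truth", {
  em <- data.frame(condition = "BIKE", timepoint = "10", group = "middle",
                   shift = -8)
  tt <- generate_trial_table(trial_gen_spec(n_per_group = 6, effect_map = em,
                                            seed = 5))
  expect_equal(nrow(tt), 6 * 2 * 4 * 4)
  expect_equal(as.integer(table(tt$condition)), rep(48L, 4))
  expect_identical(attr(tt, "true_effects"), em)
  cell <- tt$condition == "BIKE" & tt$timepoint == "10" & tt$group == "middle"
  expect_lt(mean(tt$outcome[cell]), mean(tt$outcome[!cell]))
})
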