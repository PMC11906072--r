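# Foot detection, PWV, pressures and calibration.

test_that("foot detection is equivariant under time shift and amplitude scaling", {
  wp <- generate_wave_pair(wave_gen_spec(fs_hz = 500, n_beats = 8, seed = 1))
  feet <- detect_feet(wp$proximal, wp$fs_hz)
  # shift by an integer number of samples
  k <- 25L
  shifted <- c(wp$proximal[(k + 1):length(wp$proximal)],
               wp$proximal[1:k] + 0)  # wrap tail is a partial cycle; drop it
  shifted <- wp$proximal[-(1:k)]
  feet_s <- detect_feet(shifted, wp$fs_hz)
  n <- min(length(feet), length(feet_s))
  expect_equal(feet_s[1:n], feet[feet > k / wp$fs_hz][1:n] - k / wp$fs_hz,
               tolerance = 1e-3)
  # amplitude scaling leaves feet untouched
  feet_a <- detect_feet(50 + 3 * wp$proximal, wp$fs_hz)
  expect_equal(feet_a, feet, tolerance = 1e-6)
  expect_error(detect_feet(rep(100, 1000), 500), "flat")
})

test_that("PWV reproduces distance/delay closed forms with the cf correction", {
  wp <- generate_wave_pair(wave_gen_spec(fs_hz = 1000, delay_s = 0.100,
                                         distance_m = 0.875, n_beats = 12,
                                         seed = 1))
  res <- transit_and_pwv(wp, site = "cf")
  expect_equal(res$corrected_distance_m, 0.7)
  expect_equal(res$pwv_m_s, 7.0, tolerance = 1 / (1000 * 0.1))  # sub-sample
  expect_true(res$valid)

  wp2 <- generate_wave_pair(wave_gen_spec(fs_hz = 1000, delay_s = 0.050,
                                          distance_m = 0.5, n_beats = 12,
                                          seed = 2))
  res2 <- transit_and_pwv(wp2, site = "cr")
  expect_equal(res2$corrected_distance_m, 0.5)
  expect_equal(res2$pwv_m_s, 10.0, tolerance = 10 * (1 / 1000) / 0.05)
})

test_that("the 0.8 correction is applied exactly once, and only to cf", {
  wp <- generate_wave_pair(wave_gen_spec(fs_hz = 500, delay_s = 0.08,
                                         distance_m = 0.6, n_beats = 12,
                                         seed = 3))
  cf <- transit_and_pwv(wp, site = "cf")
  cr <- transit_and_pwv(wp, site = "cr")
  expect_equal(cf$pwv_m_s / cr$pwv_m_s, 0.8, tolerance = 1e-12)
  expect_equal(cf$transit_time_s, cr$transit_time_s)
  # doubling distance doubles PWV exactly
  wp2 <- wp; wp2$distance_m <- 1.2
  expect_equal(transit_and_pwv(wp2, site = "cf")$pwv_m_s, 2 * cf$pwv_m_s)
})

test_that("zero delay is rejected by the PWV stage, not the generator", {
  wp0 <- generate_wave_pair(wave_gen_spec(fs_hz = 500, delay_s = 0,
                                          n_beats = 12, seed = 4))
  expect_error(transit_and_pwv(wp0), "transit")
})

test_that("pulse pressure and the hypertension screen follow their rules", {
  expect_equal(pulse_pressure(120, 80), 40)
  expect_equal(pulse_pressure(141, 90), 51)
  expect_error(pulse_pressure(80, 80), "exceed")
  expect_true(screen_bp(140, 90))     # strict inequalities
  expect_false(screen_bp(141, 88))
  expect_false(screen_bp(120, 91))
  expect_true(screen_bp(118, 76))
})

test_that("carotid calibration solves the linear map and preserves shape", {
  # pulse train with min 0, mean exactly 1/3, max 1: the linear map taking
  # min -> 80 and mean -> 93.33 must send the max to 120
  fs <- 100
  tri <- rep(c(0, 0, 1), 600)                    # 18 s at 100 Hz
  cal <- calibrate_carotid(tri, fs, map_mmhg = 80 + 40 / 3, dbp_mmhg = 80)
  expect_equal(cal$csbp, 120, tolerance = 1e-9)
  expect_equal(cal$pp, 40, tolerance = 1e-9)
  expect_equal(cor(cal$calibrated, tri), 1)
  # already-calibrated input is a fixed point
  cal2 <- calibrate_carotid(cal$calibrated, fs, map_mmhg = cal$map,
                            dbp_mmhg = cal$dbp)
  expect_equal(cal2$calibrated, cal$calibrated, tolerance = 1e-9)
  expect_error(calibrate_carotid(tri, fs, map_mmhg = 70, dbp_mmhg = 80),
               "MAP")
  expect_error(calibrate_carotid(rep(1, 2000), fs, 93, 80), "flat")
  expect_error(calibrate_carotid(tri[1:100], fs, 93, 80), "15 s")
})
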