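# Synthetic physiological signal generators with known ground truth.
# Every generator consumes an explicit spec (validated constructor) carrying
# its own integer seed; no global RNG state leaks out.

#' Specification for a synthetic RR tachogram
#'
#' Describes an RR interval series with prescribed low- and high-frequency
#' oscillatory content, additive Gaussian beat-to-beat noise and a Poisson
#' stream of ectopic beats (premature beat at 0.6x the local RR followed by a
#' 1.4x compensatory pause, preserving the local mean).
#'
#' @param duration_s Recording length in seconds (> 0).
#' @param mean_rr_ms Mean RR interval in ms (> 0).
#' @param lf_amp_ms,lf_freq_hz Amplitude (ms) and frequency (Hz) of the
#'   low-frequency oscillation; frequency must lie in the 0.04-0.15 Hz band.
#' @param hf_amp_ms,hf_freq_hz High-frequency (respiratory) oscillation;
#'   frequency in the 0.15-0.4 Hz band.
#' @param noise_sd_ms Beat-to-beat Gaussian noise SD in ms (>= 0).
#' @param ectopic_rate_per_min Expected ectopic beats per minute (>= 0).
#' @param seed Integer RNG seed.
#' @return An object of class `rr_gen_spec`.
#' @export
rr_gen_spec <- function(duration_s = 300, mean_rr_ms = 800,
                        lf_amp_ms = 0, lf_freq_hz = 0.1,
                        hf_amp_ms = 0, hf_freq_hz = 0.25,
                        noise_sd_ms = 0, ectopic_rate_per_min = 0,
                        seed = 1L) {
  stopifnot(duration_s > 0, mean_rr_ms > 0,
            lf_amp_ms >= 0, hf_amp_ms >= 0,
            lf_freq_hz >= 0.04, lf_freq_hz <= 0.15,
            hf_freq_hz >= 0.15, hf_freq_hz <= 0.4,
            noise_sd_ms >= 0, ectopic_rate_per_min >= 0)
  structure(list(duration_s = duration_s, mean_rr_ms = mean_rr_ms,
                 lf_amp_ms = lf_amp_ms, lf_freq_hz = lf_freq_hz,
                 hf_amp_ms = hf_amp_ms, hf_freq_hz = hf_freq_hz,
                 noise_sd_ms = noise_sd_ms,
                 ectopic_rate_per_min = ectopic_rate_per_min,
                 seed = as.integer(seed)),
            class = "rr_gen_spec")
}

#' Generate an RR tachogram beat series
#'
#' Beat times are cumulative sums of the generated RR intervals;
#' `RR(t) = mean + lf_amp sin(2 pi lf_freq t) + hf_amp sin(2 pi hf_freq t) +
#' noise`, with ectopics injected afterwards as isolated premature/compensatory
#' pairs. Reproducible per seed.
#'
#' @param spec An [rr_gen_spec()].
#' @return A [beat_series()] whose `meta` records the spec and the indices of
#'   injected ectopic beats.
#' @export
generate_rr <- function(spec) {
  stopifnot(inherits(spec, "rr_gen_spec"))
  withr::with_seed(spec$seed, {
    rr <- numeric(0)
    t <- 0
    repeat {
      val <- spec$mean_rr_ms +
        spec$lf_amp_ms * sin(2 * pi * spec$lf_freq_hz * t) +
        spec$hf_amp_ms * sin(2 * pi * spec$hf_freq_hz * t) +
        if (spec$noise_sd_ms > 0) stats::rnorm(1, 0, spec$noise_sd_ms) else 0
      if (t + val / 1000 > spec$duration_s + 1e-9) break
      rr <- c(rr, val)
      t <- t + val / 1000
    }
    ect_idx <- integer(0)
    n_ect <- stats::rpois(1, spec$ectopic_rate_per_min * spec$duration_s / 60)
    if (n_ect > 0 && length(rr) > 6) {
      cand <- sample(3:(length(rr) - 2L))
      for (i in cand) {
        if (length(ect_idx) >= n_ect) break
        if (!any(abs(ect_idx - i) <= 2L)) ect_idx <- c(ect_idx, i)
      }
      ect_idx <- sort(ect_idx)
      rr[ect_idx] <- 0.6 * rr[ect_idx]
      rr[ect_idx + 1L] <- 1.4 * rr[ect_idx + 1L]
    }
    if (any(rr <= 200))
      stop("generated RR interval <= 200 ms is non-physiological; ",
           "reduce amplitudes/noise or raise mean_rr_ms")
    beat_series(time_s = cumsum(rr) / 1000, rr_ms = rr,
                meta = list(spec = spec, ectopic_idx = ect_idx))
  })
}

#' Specification for coupled SBP-RR beat pairs with known baroreflex gain
#'
#' @param n_beats Number of beats.
#' @param gain_ms_per_mmhg True reflex gain (> 0), ms of RR change per mmHg.
#' @param ramp_len_beats Beats per pressure ramp (>= 3).
#' @param ramp_step_mmhg Per-beat SBP step within a ramp (> 0).
#' @param lag_beats RR response lag in beats (>= 0).
#' @param noise_sd_ms RR noise SD in ms.
#' @param seed Integer RNG seed.
#' @return An object of class `baro_gen_spec`.
#' @export
baro_gen_spec <- function(n_beats = 300L, gain_ms_per_mmhg = 10,
                          ramp_len_beats = 4L, ramp_step_mmhg = 1.5,
                          lag_beats = 0L, noise_sd_ms = 0, seed = 1L) {
  stopifnot(n_beats >= 10, gain_ms_per_mmhg > 0, ramp_len_beats >= 3,
            ramp_step_mmhg > 0, lag_beats >= 0, noise_sd_ms >= 0)
  structure(list(n_beats = as.integer(n_beats),
                 gain_ms_per_mmhg = gain_ms_per_mmhg,
                 ramp_len_beats = as.integer(ramp_len_beats),
                 ramp_step_mmhg = ramp_step_mmhg,
                 lag_beats = as.integer(lag_beats),
                 noise_sd_ms = noise_sd_ms, seed = as.integer(seed)),
            class = "baro_gen_spec")
}

#' Generate coupled SBP/RR beats for baroreflex analysis
#'
#' SBP alternates up and down ramps of `ramp_len_beats` with a constant
#' per-beat step; the RR response is `gain * (SBP - SBP_ref)` applied at
#' `lag_beats`, plus independent Gaussian noise. The true gain is recorded in
#' the series metadata.
#'
#' @param spec A [baro_gen_spec()].
#' @return A [beat_series()] with `sbp_mmhg` column; `meta$true_gain` holds
#'   the generating gain.
#' @export
generate_baro_beats <- function(spec) {
  stopifnot(inherits(spec, "baro_gen_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_beats
    sbp0 <- 120
    dirs <- rep(rep(c(1, -1), length.out = ceiling(n / spec$ramp_len_beats)),
                each = spec$ramp_len_beats)[seq_len(n)]
    steps <- dirs * spec$ramp_step_mmhg
    steps[1] <- 0
    sbp <- sbp0 + cumsum(steps)
    lagged <- c(rep(sbp[1], spec$lag_beats), sbp)[seq_len(n)]
    base_rr <- 900
    rr <- base_rr + spec$gain_ms_per_mmhg * (lagged - sbp0) +
      if (spec$noise_sd_ms > 0) stats::rnorm(n, 0, spec$noise_sd_ms) else 0
    beat_series(time_s = cumsum(rr) / 1000, rr_ms = rr, sbp_mmhg = sbp,
                meta = list(spec = spec, true_gain = spec$gain_ms_per_mmhg))
  })
}

#' Specification for a synchronized pressure waveform pair
#'
#' @param fs_hz Sampling rate (>= 100 Hz).
#' @param n_beats Number of cardiac cycles.
#' @param period_s Cycle length in seconds.
#' @param delay_s Pulse transit delay of the distal site (>= 0, < period).
#' @param distance_m Direct inter-site path distance in metres (> 0).
#' @param dbp_mmhg,sbp_mmhg Diastolic/systolic pressure of the template.
#' @param noise_sd Additive sample noise SD in mmHg.
#' @param seed Integer RNG seed.
#' @return An object of class `wave_gen_spec`.
#' @export
wave_gen_spec <- function(fs_hz = 1000, n_beats = 12L, period_s = 0.9,
                          delay_s = 0.06, distance_m = 0.6,
                          dbp_mmhg = 80, sbp_mmhg = 120,
                          noise_sd = 0, seed = 1L) {
  stopifnot(fs_hz >= 100, n_beats >= 2, period_s > 0.2,
            delay_s >= 0, delay_s < period_s, distance_m > 0,
            sbp_mmhg > dbp_mmhg, noise_sd >= 0)
  structure(list(fs_hz = fs_hz, n_beats = as.integer(n_beats),
                 period_s = period_s, delay_s = delay_s,
                 distance_m = distance_m, dbp_mmhg = dbp_mmhg,
                 sbp_mmhg = sbp_mmhg, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "wave_gen_spec")
}

# analytic beat template: two log-normal bumps on a diastolic baseline,
# evaluated at cycle phase u in [0, 1); zero at u = 0 by construction
.beat_template <- function(u) {
  u <- pmax(u, 1e-12)
  exp(-(log(u / 0.16))^2 / (2 * 0.28^2)) +
    0.4 * exp(-(log(u / 0.45))^2 / (2 * 0.22^2))
}

#' Generate a proximal/distal pressure waveform pair
#'
#' The proximal waveform is a periodic analytic beat template scaled to
#' `[dbp, sbp]`; the distal waveform is the same template delayed by
#' `delay_s`. Physiological realism is not the goal; a detectable systolic
#' foot is. Ground-truth foot times (intersecting-tangent feet of the
#' noiseless template, computed on a 32x oversampled grid) are stored in the
#' metadata.
#'
#' @param spec A [wave_gen_spec()].
#' @return An object of class `waveform_pair`: list with `fs_hz`, `t_s`,
#'   `proximal`, `distal`, `distance_m`, `site_pair`, `meta`.
#' @export
generate_wave_pair <- function(spec) {
  stopifnot(inherits(spec, "wave_gen_spec"))
  withr::with_seed(spec$seed, {
    n <- round(spec$n_beats * spec$period_s * spec$fs_hz)
    t <- (0:(n - 1)) / spec$fs_hz
    peak <- max(.beat_template(seq(0.001, 0.999, by = 0.001)))
    shape <- function(tt) {
      u <- (tt %% spec$period_s) / spec$period_s
      spec$dbp_mmhg + (spec$sbp_mmhg - spec$dbp_mmhg) * .beat_template(u) / peak
    }
    prox <- shape(t)
    dist <- shape(t - spec$delay_s)
    if (spec$noise_sd > 0) {
      prox <- prox + stats::rnorm(n, 0, spec$noise_sd)
      dist <- dist + stats::rnorm(n, 0, spec$noise_sd)
    }
    # dense-template ground-truth foot offset within a cycle
    fs_d <- 32 * spec$fs_hz
    td <- seq(0, spec$period_s, by = 1 / fs_d)
    wd <- shape(td)
    dw <- diff(wd) * fs_d
    i <- which.max(dw)
    foot_off <- td[i] - (wd[i] - min(wd)) / dw[i]
    feet <- foot_off + spec$period_s * (0:(spec$n_beats - 1))
    structure(list(fs_hz = spec$fs_hz, t_s = t, proximal = prox, distal = dist,
                   distance_m = spec$distance_m, site_pair = "cf",
                   meta = list(spec = spec, true_delay_s = spec$delay_s,
                               true_foot_times_s = feet)),
              class = "waveform_pair")
  })
}

#' Specification for a gas-exchange trace with an embedded steady state
#'
#' @param duration_min Trace length in minutes.
#' @param rest_vo2_ml_min,rest_vco2_ml_min Resting flows (mL/min); their ratio
#'   (resting RER) must lie in the admissible 0.7-1.0 window.
#' @param activity_multiplier Scalar multiplying both flows over the whole
#'   trace (1 = resting).
#' @param steady_start_min,steady_len_min Embedded compliant segment.
#' @param cv_inside Realized coefficient of variation inside the segment
#'   (<= 0.10).
#' @param cv_outside Lower bound on the CV outside the segment (> 0.10);
#'   outside bins deviate by at least `max(cv_outside, 0.25)` with
#'   alternating sign so that no window touching them can masquerade as a
#'   steady state.
#' @param seed Integer RNG seed.
#' @return An object of class `gas_gen_spec`.
#' @export
gas_gen_spec <- function(duration_min = 15L, rest_vo2_ml_min = 250,
                         rest_vco2_ml_min = 210, activity_multiplier = 1,
                         steady_start_min = 8L, steady_len_min = 5L,
                         cv_inside = 0.03, cv_outside = 0.25, seed = 1L) {
  rer <- rest_vco2_ml_min / rest_vo2_ml_min
  stopifnot(duration_min >= 2, rest_vo2_ml_min > 0, rest_vco2_ml_min >= 0,
            rer >= 0.7, rer <= 1.0, activity_multiplier > 0,
            cv_inside >= 0, cv_inside <= 0.10, cv_outside > 0.10,
            cv_outside < 0.5)
  if (steady_start_min < 1 || steady_start_min + steady_len_min - 1 > duration_min)
    stop("steady-state window must lie inside the trace")
  structure(list(duration_min = as.integer(duration_min),
                 rest_vo2_ml_min = rest_vo2_ml_min,
                 rest_vco2_ml_min = rest_vco2_ml_min,
                 activity_multiplier = activity_multiplier,
                 steady_start_min = as.integer(steady_start_min),
                 steady_len_min = as.integer(steady_len_min),
                 cv_inside = cv_inside, cv_outside = cv_outside,
                 seed = as.integer(seed)),
            class = "gas_gen_spec")
}

# deviations with exact sample CV around a base level
.cv_noise <- function(base, k, cv) {
  if (cv == 0 || k < 2) return(rep(base, k))
  z <- stats::rnorm(k)
  z <- (z - mean(z)) / stats::sd(z)
  base * (1 + cv * z)
}

# non-compliant segment: alternating-sign deviations large enough that any
# 5-bin window containing even one such bin exceeds a 10% CV (a single bin
# deviating by fraction m drives the window CV to ~0.447 m)
.cv_noise_outside <- function(base, k, cv) {
  if (k == 0L) return(numeric(0))
  m <- max(cv, 0.25)
  signs <- rep(c(1, -1), length.out = k) * sample(c(1, -1), 1)
  base * (1 + signs * m * stats::runif(k, 1, 1.15))
}

#' Generate a 1-minute-binned gas-exchange trace
#'
#' Flows are the resting values times `activity_multiplier` with
#' multiplicative noise whose realized coefficient of variation equals
#' `cv_inside` inside the embedded steady segment and `cv_outside` outside it.
#' The true resting energy expenditure (Weir equation on the noiseless resting
#' flows) is recorded in the metadata.
#'
#' @param spec A [gas_gen_spec()].
#' @param phase Phase label stored on every row (default `"rest"`).
#' @return An object of class `gas_trace` (data.frame with `t_min`,
#'   `vo2_ml_min`, `vco2_ml_min`, `hr_bpm`, `phase`).
#' @export
generate_gas_trace <- function(spec, phase = "rest") {
  stopifnot(inherits(spec, "gas_gen_spec"))
  withr::with_seed(spec$seed, {
    mins <- seq_len(spec$duration_min)
    inside <- mins >= spec$steady_start_min &
      mins < spec$steady_start_min + spec$steady_len_min
    vo2 <- vco2 <- numeric(spec$duration_min)
    b_vo2 <- spec$rest_vo2_ml_min * spec$activity_multiplier
    b_vco2 <- spec$rest_vco2_ml_min * spec$activity_multiplier
    vo2[inside] <- .cv_noise(b_vo2, sum(inside), spec$cv_inside)
    vco2[inside] <- .cv_noise(b_vco2, sum(inside), spec$cv_inside)
    vo2[!inside] <- .cv_noise_outside(b_vo2, sum(!inside), spec$cv_outside)
    vco2[!inside] <- .cv_noise_outside(b_vco2, sum(!inside), spec$cv_outside)
    hr <- round(60 + 40 * (spec$activity_multiplier - 1) + stats::rnorm(length(mins), 0, 2))
    out <- data.frame(t_min = mins, vo2_ml_min = vo2, vco2_ml_min = vco2,
                      hr_bpm = hr, phase = phase)
    structure(out,
              class = c("gas_trace", "data.frame"),
              true_ree_kcal_day = weir_ree(spec$rest_vo2_ml_min,
                                           spec$rest_vco2_ml_min),
              steady_interval_min = c(spec$steady_start_min,
                                      spec$steady_start_min + spec$steady_len_min - 1L),
              gen_spec = spec)
  })
}

#' Specification for a synthetic crossover trial outcome table
#'
#' Emulates a two-group (young/middle-aged), four-condition, four-timepoint
#' crossover with a participant random intercept.
#'
#' @param n_per_group Participants per age group.
#' @param conditions,timepoints Factor level vocabularies (4 each).
#' @param between_subject_sd Participant intercept SD (outcome units).
#' @param residual_sd Residual SD.
#' @param effect_map `NULL` (null model) or a data.frame with columns
#'   `condition`, `timepoint`, `group`, `shift` giving cell mean shifts.
#' @param grand_mean Overall outcome mean.
#' @param seed Integer RNG seed.
#' @return An object of class `trial_gen_spec`.
#' @export
trial_gen_spec <- function(n_per_group = 12L,
                           conditions = c("CON", "BIKE", "PP", "GT"),
                           timepoints = c("rest", "10", "20", "30"),
                           between_subject_sd = 5, residual_sd = 5,
                           effect_map = NULL, grand_mean = 100, seed = 1L) {
  stopifnot(n_per_group >= 2, length(conditions) == 4, length(timepoints) == 4,
            between_subject_sd > 0, residual_sd > 0)
  if (!is.null(effect_map))
    stopifnot(is.data.frame(effect_map),
              all(c("condition", "timepoint", "group", "shift") %in% names(effect_map)))
  structure(list(n_per_group = as.integer(n_per_group), conditions = conditions,
                 timepoints = timepoints, between_subject_sd = between_subject_sd,
                 residual_sd = residual_sd, effect_map = effect_map,
                 grand_mean = grand_mean, seed = as.integer(seed)),
            class = "trial_gen_spec")
}

#' Generate a long-format crossover trial table
#'
#' One row per participant x condition x timepoint; outcome = grand mean +
#' participant intercept + effect-map shift + residual. True effects are
#' recorded in the `true_effects` attribute.
#'
#' @param spec A [trial_gen_spec()].
#' @return A data.frame (class `trial_table`) with columns `participant`,
#'   `group`, `condition`, `timepoint`, `outcome`.
#' @export
generate_trial_table <- function(spec) {
  stopifnot(inherits(spec, "trial_gen_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_per_group
    ids <- sprintf("P%02d", seq_len(2L * n))
    groups <- rep(c("young", "middle"), each = n)
    tab <- expand.grid(participant = ids, condition = spec$conditions,
                       timepoint = spec$timepoints, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
    tab$group <- groups[match(tab$participant, ids)]
    b <- stats::rnorm(length(ids), 0, spec$between_subject_sd)
    shift <- numeric(nrow(tab))
    if (!is.null(spec$effect_map)) {
      key <- paste(tab$condition, tab$timepoint, tab$group)
      mkey <- paste(spec$effect_map$condition, spec$effect_map$timepoint,
                    spec$effect_map$group)
      m <- match(key, mkey)
      shift <- ifelse(is.na(m), 0, spec$effect_map$shift[m])
    }
    tab$outcome <- spec$grand_mean + b[match(tab$participant, ids)] + shift +
      stats::rnorm(nrow(tab), 0, spec$residual_sd)
    tab <- tab[c("participant", "group", "condition", "timepoint", "outcome")]
    structure(tab, class = c("trial_table", "data.frame"),
              true_effects = spec$effect_map, gen_spec = spec)
  })
}
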