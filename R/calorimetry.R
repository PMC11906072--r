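# Indirect-calorimetry energy expenditure and VO2peak adjudication.

#' Resting energy expenditure by the Weir equation
#'
#' `kcal/day = 1.44 * (3.94 * VO2 + 1.11 * VCO2)` with flows in mL/min
#' (abbreviated Weir form without the urinary-nitrogen term).
#'
#' @param vo2_ml_min Oxygen uptake (mL/min, > 0).
#' @param vco2_ml_min Carbon-dioxide output (mL/min, >= 0).
#' @param per_minute If TRUE return kcal/min instead of kcal/day.
#' @return Energy expenditure (kcal/day, or kcal/min).
#' @export
weir_ree <- function(vo2_ml_min, vco2_ml_min, per_minute = FALSE) {
  if (any(vo2_ml_min <= 0)) stop("VO2 must be positive")
  if (any(vco2_ml_min < 0)) stop("VCO2 must be non-negative")
  kcal_day <- 1.44 * (3.94 * vo2_ml_min + 1.11 * vco2_ml_min)
  if (per_minute) kcal_day / 1440 else kcal_day
}

#' Locate the resting steady state in a gas trace
#'
#' Scores every sliding window of `win_min` one-minute bins inside the search
#' interval; a window is valid when the coefficient of variation of both VO2
#' and VCO2 is at most `cv_max` and the mean respiratory exchange ratio lies
#' in `[rer_lo, rer_hi]`. Among valid windows the one with the lowest Weir
#' REE is returned. The search interval defaults to minutes 5-15, so the
#' discarded first five minutes are never used.
#'
#' @param trace A `gas_trace` data.frame (`t_min`, `vo2_ml_min`,
#'   `vco2_ml_min`).
#' @param win_min Window length in minutes (default 5).
#' @param cv_max CV threshold (default 0.10).
#' @param rer_lo,rer_hi Admissible mean-RER window (default 0.7-1.0).
#' @param search `c(first, last)` minutes searched (default `c(5, 15)`,
#'   window starts at minute > `search[1]`).
#' @return Object of class `steady_state`: `interval_min` (first/last minute),
#'   `ree_kcal_day`, `mean_vo2`, `mean_vco2`, `mean_rer`, `cv_vo2`, `cv_vco2`.
#' @export
find_steady_state <- function(trace, win_min = 5L, cv_max = 0.10,
                              rer_lo = 0.7, rer_hi = 1.0,
                              search = c(5, 15)) {
  stopifnot(is.data.frame(trace),
            all(c("t_min", "vo2_ml_min", "vco2_ml_min") %in% names(trace)))
  if (max(trace$t_min) < search[2])
    stop("trace does not cover the search interval")
  cv <- function(x) stats::sd(x) / mean(x)
  starts <- trace$t_min[trace$t_min > search[1] &
                          trace$t_min + win_min - 1 <= search[2]]
  best <- NULL
  for (s in starts) {
    sel <- trace$t_min >= s & trace$t_min <= s + win_min - 1
    if (sum(sel) < win_min) next
    vo2 <- trace$vo2_ml_min[sel]
    vco2 <- trace$vco2_ml_min[sel]
    rer <- mean(vco2 / vo2)
    if (cv(vo2) > cv_max || cv(vco2) > cv_max) next
    if (rer < rer_lo || rer > rer_hi) next
    ree <- weir_ree(mean(vo2), mean(vco2))
    if (is.null(best) || ree < best$ree_kcal_day) {
      best <- list(interval_min = c(s, s + win_min - 1),
                   ree_kcal_day = ree, mean_vo2 = mean(vo2),
                   mean_vco2 = mean(vco2), mean_rer = rer,
                   cv_vo2 = cv(vo2), cv_vco2 = cv(vco2))
    }
  }
  if (is.null(best))
    stop("no steady state: no ", win_min,
         "-min window met the CV/RER criteria; measurement unusable")
  structure(best, class = "steady_state")
}

#' Session energy expenditure and the activity component
#'
#' Total energy expenditure (TEE) is the per-minute Weir energy summed over
#' the phase; activity energy expenditure is
#' `AEE = TEE - (REE_over_session + 0.1 * TEE)`, the 10% term approximating
#' the thermic effect of food.
#'
#' @param trace A `gas_trace` with a `phase` column.
#' @param ree_kcal_day Resting energy expenditure (kcal/day) from
#'   [find_steady_state()].
#' @param phase Phase label to analyse (e.g. `"class"`).
#' @return Object of class `energy_result`: `tee_kcal`, `ree_over_session_kcal`,
#'   `aee_kcal`, `duration_min`, `aee_negative` flag, `rer_series`.
#' @export
session_energy <- function(trace, ree_kcal_day, phase) {
  stopifnot(is.data.frame(trace), "phase" %in% names(trace))
  sel <- trace$phase == phase
  if (!any(sel))
    stop("no phase mark '", phase, "' present in the trace")
  vo2 <- trace$vo2_ml_min[sel]
  vco2 <- trace$vco2_ml_min[sel]
  dur <- sum(sel)                      # 1-minute bins
  tee <- sum(weir_ree(vo2, vco2, per_minute = TRUE))
  ree_sess <- ree_kcal_day * dur / 1440
  aee <- tee - (ree_sess + 0.1 * tee)
  if (aee < 0)
    warning("negative AEE (", round(aee, 1), " kcal): session below resting cost")
  structure(list(tee_kcal = tee, ree_over_session_kcal = ree_sess,
                 aee_kcal = aee, duration_min = dur,
                 aee_negative = aee < 0, rer_series = vco2 / vo2),
            class = "energy_result")
}

#' Per-minute exercise intensity metrics
#'
#' METs use the participant's measured resting VO2 (`MET = VO2 / rest_vo2`),
#' not the 3.5 mL/kg/min convention (available via `rest_vo2` itself);
#' reserves are `100 * (x - rest) / (max - rest)`. Values outside `[0, 100]`
#' are reported as computed and flagged, never clipped.
#'
#' @param trace A `gas_trace` (needs `vo2_ml_min`, optionally `hr_bpm`).
#' @param rest_vo2_ml_min Resting VO2 (mL/min, > 0).
#' @param vo2peak_ml_min Peak VO2 (mL/min, > rest).
#' @param rest_hr_bpm,hrmax_bpm Resting and maximal heart rate (bpm);
#'   optional, enable the %HRR column.
#' @return data.frame with `t_min`, `mets`, `pct_vo2_reserve`, optionally
#'   `pct_hr_reserve`, plus an `out_of_range` flag column.
#' @export
intensity_metrics <- function(trace, rest_vo2_ml_min, vo2peak_ml_min,
                              rest_hr_bpm = NULL, hrmax_bpm = NULL) {
  stopifnot(rest_vo2_ml_min > 0)
  if (vo2peak_ml_min <= rest_vo2_ml_min)
    stop("vo2peak must exceed resting VO2")
  out <- data.frame(
    t_min = trace$t_min,
    mets = trace$vo2_ml_min / rest_vo2_ml_min,
    pct_vo2_reserve = 100 * (trace$vo2_ml_min - rest_vo2_ml_min) /
      (vo2peak_ml_min - rest_vo2_ml_min))
  if (!is.null(rest_hr_bpm) && !is.null(hrmax_bpm)) {
    if (hrmax_bpm <= rest_hr_bpm) stop("HRmax must exceed resting HR")
    out$pct_hr_reserve <- 100 * (trace$hr_bpm - rest_hr_bpm) /
      (hrmax_bpm - rest_hr_bpm)
  }
  resv <- out[grep("^pct_", names(out))]
  out$out_of_range <- Reduce(`|`, lapply(resv, function(x) x < 0 | x > 100))
  out
}

#' Adjudicate a VO2peak test
#'
#' VO2peak is the highest 10-second average within the final minute of
#' effort; the test is accepted when at least two criteria hold: (1) maximal
#' HR at or above 90% of the age-predicted maximum (220 - age); (2) a VO2
#' plateau, i.e. a consecutive-stage increase below 2.0 mL/kg/min despite a
#' workload increase; (3) rating of perceived exertion >= 18; (4) peak
#' respiratory exchange ratio >= 1.1; (5) observer judgment of exhaustion.
#'
#' @param test data.frame of 10-second averages with columns `t_s`,
#'   `vo2_ml_kg_min`, and optionally `hr_bpm`, `rer`.
#' @param age_years Participant age (years).
#' @param body_mass_kg Optional body mass to also report VO2peak in L/min.
#' @param rpe_final Final rating of perceived exertion (Borg 6-20), or `NA`.
#' @param stage_delta_vo2 Consecutive-stage VO2 increments (mL/kg/min) under
#'   increasing workload, or `NULL` when stage data are unavailable.
#' @param observer_exhaustion Logical observer-judgment flag.
#' @return Object of class `vo2peak_result`: `vo2peak_ml_kg_min`,
#'   `vo2peak_l_min`, `hrmax_bpm`, `criteria_met` (named logical),
#'   `accepted`.
#' @export
adjudicate_vo2peak <- function(test, age_years, body_mass_kg = NULL,
                               rpe_final = NA, stage_delta_vo2 = NULL,
                               observer_exhaustion = FALSE) {
  stopifnot(is.data.frame(test), all(c("t_s", "vo2_ml_kg_min") %in% names(test)))
  t_end <- max(test$t_s)
  if (t_end - min(test$t_s) < 60)
    stop("need at least 60 s of 10-second-averaged data")
  final <- test$t_s > t_end - 60
  vo2peak <- max(test$vo2_ml_kg_min[final])
  hrmax <- if ("hr_bpm" %in% names(test)) max(test$hr_bpm, na.rm = TRUE) else NA_real_
  rer_max <- if ("rer" %in% names(test)) max(test$rer, na.rm = TRUE) else NA_real_
  pred_hrmax <- 220 - age_years
  crit <- c(
    hr_near_max = !is.na(hrmax) && hrmax >= 0.90 * pred_hrmax,
    vo2_plateau = !is.null(stage_delta_vo2) && any(stage_delta_vo2 < 2.0),
    rpe_18 = !is.na(rpe_final) && rpe_final >= 18,
    rer_1.1 = !is.na(rer_max) && rer_max >= 1.1,
    observer = isTRUE(observer_exhaustion))
  structure(list(
    vo2peak_ml_kg_min = vo2peak,
    vo2peak_l_min = if (is.null(body_mass_kg)) NA_real_ else
      vo2peak * body_mass_kg / 1000,
    hrmax_bpm = hrmax,
    criteria_met = crit,
    accepted = sum(crit) >= 2L
  ), class = "vo2peak_result")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("<steady_state> minutes %d-%d, REE %.0f kcal/day (RER %.2f, CV VO2 %.1f%%)\n",
              x$interval_min[1], x$interval_min[2], x$ree_kcal_day,
              x$mean_rer, 100 * x$cv_vo2))
  invisible(x)
}

#' @export
print.energy_result <- function(x, ...) {
  cat(sprintf("<energy_result> TEE %.1f kcal over %d min; AEE %.1f kcal (REE share %.1f)\n",
              x$tee_kcal, x$duration_min, x$aee_kcal, x$ree_over_session_kcal))
  invisible(x)
}
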