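# Foot-to-foot pulse wave velocity, pulse pressure and carotid calibration.

# rising mid-amplitude crossings used to segment cardiac cycles
.cycle_crossings <- function(w, fs_hz) {
  rng <- range(w)
  if (diff(rng) < 1e-6) return(integer(0))
  level <- rng[1] + 0.5 * diff(rng)
  above <- w > level
  which(!above[-length(above)] & above[-1]) + 1L
}

#' Detect waveform feet (intersecting-tangent method)
#'
#' Cycles are segmented by mid-amplitude rising crossings; for each cycle the
#' foot is the intersection of the horizontal line through the diastolic
#' minimum with the tangent at the point of maximal upstroke slope. The
#' derivative peak is refined to sub-sample precision by a local quadratic
#' fit.
#'
#' @param wave Sampled pressure waveform (mmHg or arbitrary units).
#' @param fs_hz Sampling rate (Hz).
#' @return Numeric vector of foot times in seconds.
#' @export
detect_feet <- function(wave, fs_hz) {
  stopifnot(is.numeric(wave), length(wave) > 10, fs_hz > 0)
  cross <- .cycle_crossings(wave, fs_hz)
  if (length(cross) < 2L)
    stop("quality error: signal is flat or non-periodic; no feet detectable")
  period_n <- stats::median(diff(cross))
  dw <- c(NA, (wave[-1] - wave[-length(wave)])) * fs_hz  # backward difference
  feet <- numeric(0)
  for (cx in cross) {
    lo <- max(2L, cx - as.integer(round(0.45 * period_n)))
    hi <- min(length(wave), cx + as.integer(round(0.15 * period_n)))
    seg <- lo:hi
    imin <- seg[which.min(wave[seg])]
    useg <- imin:hi
    if (length(useg) < 4L) next
    ipk <- useg[which.max(dw[useg])]
    if (ipk <= 2L || ipk >= length(wave)) next
    # sub-sample quadratic refinement of the derivative peak
    y1 <- dw[ipk - 1L]; y2 <- dw[ipk]; y3 <- dw[ipk + 1L]
    denom <- (y1 - 2 * y2 + y3)
    delta <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
    delta <- max(min(delta, 0.5), -0.5)
    t_star <- (ipk - 1 + delta) / fs_hz
    slope <- y2 - 0.25 * (y1 - y3) * delta   # quadratic value at the vertex
    if (slope <= 0) next
    w_star <- wave[ipk] + (wave[min(ipk + 1L, length(wave))] - wave[ipk]) * delta
    w_min <- wave[imin]
    feet <- c(feet, t_star - (w_star - w_min) / slope)
  }
  if (length(feet) < 2L)
    stop("quality error: fewer than two feet located")
  sort(feet)
}

#' Transit time and pulse wave velocity from a waveform pair
#'
#' Per-beat transit is the distal minus the proximal foot time, beats matched
#' by rank order; PWV is the path distance (corrected by 0.8 for the
#' carotid-femoral site, reflecting arterial path-length differences) divided
#' by the mean transit time.
#'
#' @param pair A `waveform_pair` (see [generate_wave_pair()] or
#'   [read_waveform_pair()]).
#' @param site Site pair: `"cf"` (carotid-femoral, 0.8 distance correction),
#'   `"cr"` or `"cd"` (no correction).
#' @param correction Optional explicit distance correction factor, overriding
#'   the site rule.
#' @param min_beats Beats required for a fully valid estimate (default 10);
#'   fewer beats yields a result flagged `valid = FALSE`, not an error.
#' @return Object of class `pwv_result`: `transit_time_s`,
#'   `per_beat_transit_s`, `corrected_distance_m`, `pwv_m_s`, `n_beats_used`,
#'   `valid`.
#' @export
transit_and_pwv <- function(pair, site = pair$site_pair, correction = NULL,
                            min_beats = 10L) {
  stopifnot(inherits(pair, "waveform_pair"))
  if (is.null(correction))
    correction <- if (identical(site, "cf")) 0.8 else 1.0
  fp <- detect_feet(pair$proximal, pair$fs_hz)
  fd <- detect_feet(pair$distal, pair$fs_hz)
  # rank-order matching within the common span: drop leading distal feet that
  # precede the first proximal foot
  fd <- fd[fd > fp[1] - 1e-9]
  n <- min(length(fp), length(fd))
  transit <- fd[seq_len(n)] - fp[seq_len(n)]
  tt <- mean(transit)
  if (tt <= 0)
    stop("non-positive mean transit time: proximal/distal sites reversed or zero delay")
  structure(list(
    transit_time_s = tt,
    per_beat_transit_s = transit,
    corrected_distance_m = pair$distance_m * correction,
    pwv_m_s = pair$distance_m * correction / tt,
    n_beats_used = n,
    valid = n >= min_beats
  ), class = "pwv_result")
}

#' Pulse pressure
#'
#' @param sbp,dbp Systolic and diastolic pressure (mmHg); `sbp > dbp`.
#' @return `sbp - dbp` (mmHg).
#' @export
pulse_pressure <- function(sbp, dbp) {
  if (any(sbp <= dbp)) stop("SBP must exceed DBP")
  sbp - dbp
}

#' Calibrate a carotid waveform to MAP and DBP
#'
#' Linear rescale `a*x + b` mapping the waveform minimum to diastolic
#' pressure and the time average to mean arterial pressure; central systolic
#' pressure is the mean of the per-beat maxima of the calibrated trace over
#' the acquisition window.
#'
#' @param wave Uncalibrated carotid samples (arbitrary units).
#' @param fs_hz Sampling rate (Hz).
#' @param map_mmhg Mean arterial pressure measured immediately before the
#'   acquisition (mmHg).
#' @param dbp_mmhg Diastolic pressure (mmHg); `map_mmhg > dbp_mmhg`.
#' @param min_window_s Minimum signal length (default 15 s).
#' @return Object of class `pressure_summary`: `csbp`, `dbp`, `map`, `pp`
#'   (central pulse pressure `csbp - dbp`) and the calibrated samples.
#' @export
calibrate_carotid <- function(wave, fs_hz, map_mmhg, dbp_mmhg,
                              min_window_s = 15) {
  stopifnot(is.numeric(wave), fs_hz > 0)
  if (map_mmhg <= dbp_mmhg) stop("MAP must exceed DBP for calibration")
  if (length(wave) / fs_hz < min_window_s)
    stop("need at least ", min_window_s, " s of carotid signal")
  wmin <- min(wave)
  wmean <- mean(wave)
  if (wmean - wmin < 1e-9)
    stop("flat waveform: mean equals minimum, calibration impossible")
  a <- (map_mmhg - dbp_mmhg) / (wmean - wmin)
  cal <- dbp_mmhg + a * (wave - wmin)
  cross <- .cycle_crossings(cal, fs_hz)
  csbp <- if (length(cross) >= 2L) {
    maxima <- vapply(seq_len(length(cross) - 1L), function(k)
      max(cal[cross[k]:(cross[k + 1L] - 1L)]), numeric(1))
    mean(maxima)
  } else max(cal)
  structure(list(csbp = csbp, dbp = dbp_mmhg, map = map_mmhg,
                 pp = csbp - dbp_mmhg, calibrated = cal),
            class = "pressure_summary")
}

#' Resting-hypertension eligibility screen
#'
#' Flags a participant ineligible when resting SBP exceeds 140 mmHg or DBP
#' exceeds 90 mmHg (strict inequalities: 140/90 exactly remains eligible).
#'
#' @param sbp,dbp Resting brachial pressures (mmHg).
#' @return Logical: `TRUE` when eligible.
#' @export
screen_bp <- function(sbp, dbp) {
  stopifnot(is.numeric(sbp), is.numeric(dbp))
  !(sbp > 140 | dbp > 90)
}

#' @export
print.pwv_result <- function(x, ...) {
  cat(sprintf("<pwv_result> %.2f m/s (transit %.1f ms over %.3f m, %d beats%s)\n",
              x$pwv_m_s, 1000 * x$transit_time_s, x$corrected_distance_m,
              x$n_beats_used, if (x$valid) "" else ", LOW BEAT COUNT"))
  invisible(x)
}
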