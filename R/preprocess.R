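# Artifact editing and uniform resampling of beat streams into 2-minute
# tachogram windows.

#' Flag ectopic/artifactual beats
#'
#' A beat is flagged when its RR interval deviates from the median of its
#' 11-beat neighbourhood (5 beats each side, the beat itself excluded) by more
#' than `dev_frac` of that median. The series is returned unmodified except
#' for the `flag` column.
#'
#' @param beats A [beat_series()].
#' @param dev_frac Fractional deviation threshold (default 0.2).
#' @return The beat series with updated flags; the number of flagged beats is
#'   stored in `series_meta(x)$n_flagged`.
#' @export
flag_ectopics <- function(beats, dev_frac = 0.2) {
  stopifnot(inherits(beats, "beat_series"), dev_frac > 0)
  n <- nrow(beats)
  if (n < 11L) {
    warning("series shorter than the 11-beat local window; nothing flagged")
    return(beats)
  }
  rr <- beats$rr_ms
  flags <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - 5L)
    hi <- min(n, i + 5L)
    nb <- rr[setdiff(lo:hi, i)]
    med <- stats::median(nb)
    flags[i] <- abs(rr[i] - med) > dev_frac * med
  }
  meta <- series_meta(beats)
  meta$n_flagged <- sum(flags)
  out <- beats
  out$flag <- flags
  attr(out, "meta") <- meta
  out
}

#' Remove flagged beats and bridge the gaps
#'
#' Deletes flagged beats; the RR interval of each beat that immediately
#' follows a gap (and therefore spans removed beats) is re-estimated by
#' natural-cubic interpolation of the surrounding trustworthy RR-versus-time
#' curve, and beat times are recomputed as cumulative RR sums so the
#' RR/beat-time invariant holds again.
#'
#' @param beats A flagged [beat_series()] (see [flag_ectopics()]).
#' @param max_edit_frac Abort threshold: more than this fraction of flagged
#'   beats renders the window unusable (default 0.2).
#' @return An edited [beat_series()]; `series_meta(x)$n_edited` counts removed
#'   beats.
#' @export
remove_and_bridge <- function(beats, max_edit_frac = 0.2) {
  stopifnot(inherits(beats, "beat_series"))
  n <- nrow(beats)
  n_flag <- sum(beats$flag)
  if (n_flag / n > max_edit_frac)
    stop(sprintf("quality error: %.0f%% of beats flagged (> %.0f%%); window unusable",
                 100 * n_flag / n, 100 * max_edit_frac))
  meta <- series_meta(beats)
  meta$n_edited <- n_flag
  if (n_flag == 0L) {
    attr(beats, "meta") <- meta
    return(beats)
  }
  keep <- !beats$flag
  kept <- beats[keep, , drop = FALSE]
  # a kept beat whose predecessor (in the original stream) was removed has an
  # RR spanning the gap: re-estimate it
  prev_removed <- c(FALSE, beats$flag[-n])[keep]
  trust <- !prev_removed
  trust[1] <- trust[1] && !beats$flag[1]
  if (sum(trust) < 4L) stop("too few trustworthy beats to bridge gaps")
  f <- stats::splinefun(kept$time_s[trust], kept$rr_ms[trust], method = "natural")
  rr_new <- kept$rr_ms
  rr_new[!trust] <- f(kept$time_s[!trust])
  if (any(rr_new <= 0)) stop("gap bridging produced non-positive RR")
  t0 <- kept$time_s[1] - rr_new[1] / 1000
  beat_series(time_s = t0 + cumsum(rr_new) / 1000, rr_ms = rr_new,
              sbp_mmhg = kept$sbp_mmhg, dbp_mmhg = kept$dbp_mmhg,
              map_mmhg = kept$map_mmhg, meta = meta)
}

#' Resample a beat series into a uniform tachogram window
#'
#' Cubic-spline interpolation of the RR-versus-beat-time curve evaluated on a
#' uniform grid, producing the 2-minute series the spectral stage consumes.
#'
#' @param beats A [beat_series()] covering the window.
#' @param start_s Window start (s); the window is
#'   `[start_s, start_s + window_len_s]`.
#' @param fs_hz Resampling rate (default 4 Hz); `fs_hz * window_len_s` must be
#'   an integer.
#' @param window_len_s Window length in seconds (default 120).
#' @param max_gap_s Maximum tolerated inter-beat gap inside the window
#'   (default 3 s); larger gaps abort.
#' @return An object of class `tachogram_window`: list with `fs_hz`,
#'   `values_ms`, `start_s`, `window_len_s`, `n_edited`, `meta`.
#' @export
resample_window <- function(beats, start_s, fs_hz = 4, window_len_s = 120,
                            max_gap_s = 3) {
  stopifnot(inherits(beats, "beat_series"), fs_hz > 0, window_len_s > 0)
  n_samp <- fs_hz * window_len_s
  if (abs(n_samp - round(n_samp)) > 1e-9)
    stop("fs_hz * window_len_s must be an integer number of samples")
  n_samp <- as.integer(round(n_samp))
  end_s <- start_s + window_len_s
  if (min(beats$time_s) > start_s + 1e-9 || max(beats$time_s) < end_s - 1e-9)
    stop("beats do not cover the requested window [",
         sprintf("%.1f, %.1f] s", start_s, end_s))
  inwin <- beats$time_s >= start_s - 5 & beats$time_s <= end_s + 5
  tt <- beats$time_s[inwin]
  gaps <- diff(tt[tt >= start_s & tt <= end_s])
  if (length(gaps) && max(gaps) > max_gap_s)
    stop(sprintf("coverage gap of %.1f s inside window; cannot certify", max(gaps)))
  f <- stats::splinefun(beats$time_s, beats$rr_ms, method = "natural")
  grid <- start_s + (0:(n_samp - 1L)) / fs_hz
  meta <- series_meta(beats)
  structure(list(fs_hz = fs_hz, values_ms = f(grid), start_s = start_s,
                 window_len_s = window_len_s,
                 n_edited = if (is.null(meta$n_edited)) 0L else meta$n_edited,
                 meta = meta),
            class = "tachogram_window")
}

#' @export
print.tachogram_window <- function(x, ...) {
  cat(sprintf("<tachogram_window> %g s at %g Hz (%d samples), mean RR %.1f ms\n",
              x$window_len_s, x$fs_hz, length(x$values_ms), mean(x$values_ms)))
  invisible(x)
}
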