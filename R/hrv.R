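# Time-domain and wavelet time-frequency HRV indices.

#' Time-domain HRV indices
#'
#' Computed on the edited NN intervals themselves (never on the resampled
#' signal): SDNN is the n-1 standard deviation, RMSSD the root mean square of
#' successive differences, pNN50 the percentage of successive differences
#' exceeding 50 ms. Natural-log transforms of the positive indices are
#' attached for the statistical stage.
#'
#' @param beats A [beat_series()].
#' @param window Optional `c(start_s, end_s)` restriction.
#' @param min_beats Minimum number of unflagged beats (default 30, the
#'   usability guard for 2-minute supine windows).
#' @return Object of class `hrv_time_domain`: `mean_ibi_ms`, `sdnn_ms`,
#'   `rmssd_ms`, `pnn50_pct`, `n_beats`, and `ln_*` transforms.
#' @export
hrv_time_domain <- function(beats, window = NULL, min_beats = 30L) {
  stopifnot(inherits(beats, "beat_series"))
  sel <- !beats$flag
  if (!is.null(window))
    sel <- sel & beats$time_s >= window[1] & beats$time_s <= window[2]
  nn <- beats$rr_ms[sel]
  if (length(nn) < min_beats)
    stop("quality error: only ", length(nn), " unflagged beats (need >= ",
         min_beats, ")")
  d <- diff(nn)
  res <- list(
    mean_ibi_ms = mean(nn),
    sdnn_ms = stats::sd(nn),
    rmssd_ms = sqrt(mean(d^2)),
    pnn50_pct = 100 * sum(abs(d) > 50) / length(d),
    n_beats = length(nn)
  )
  res$ln_ibi <- log(res$mean_ibi_ms)
  res$ln_sdnn <- if (res$sdnn_ms > 0) log(res$sdnn_ms) else NA_real_
  res$ln_rmssd <- if (res$rmssd_ms > 0) log(res$rmssd_ms) else NA_real_
  structure(res, class = "hrv_time_domain")
}

.hrv_bands <- function(lf = c(0.04, 0.15), hf = c(0.15, 0.4)) {
  list(lf = lf, hf = hf)
}

.spectral_result <- function(lf, hf) {
  structure(list(
    lf_ms2 = lf, hf_ms2 = hf,
    lf_nu_pct = 100 * lf / (lf + hf),
    hf_nu_pct = 100 * hf / (lf + hf),
    ln_lf = if (lf > 0) log(lf) else NA_real_,
    ln_hf = if (hf > 0) log(hf) else NA_real_,
    ln_lf_hf_ratio = if (lf > 0 && hf > 0) log(lf) - log(hf) else NA_real_
  ), class = "hrv_spectral")
}

#' Wavelet LF/HF band powers of a tachogram window
#'
#' Shift-invariant (maximal overlap) Daubechies wavelet decomposition of the
#' mean-detrended window; coefficient variances are attributed to the
#' low-frequency (0.04-0.15 Hz) and high-frequency (0.15-0.4 Hz) bands via
#' the adaptive packet mapping described in [modwt_band_power()]. Normalized
#' units are `100 * LF / (LF + HF)` and its complement.
#'
#' @param window A [resample_window()] result.
#' @param bands Named list with `lf` and `hf` edges in Hz.
#' @param wavelet Daubechies filter label, `"db<p>"` with `p` vanishing
#'   moments (default `"db12"`).
#' @param max_level Maximum packet depth (see [modwt_band_power()]).
#' @return Object of class `hrv_spectral`: `lf_ms2`, `hf_ms2`, `lf_nu_pct`,
#'   `hf_nu_pct`, `ln_lf`, `ln_hf`, `ln_lf_hf_ratio`.
#' @export
wavelet_band_power <- function(window, bands = .hrv_bands(),
                               wavelet = "db12", max_level = 6L) {
  stopifnot(inherits(window, "tachogram_window"))
  p <- .parse_wavelet(wavelet)
  bp <- modwt_band_power(window$values_ms - mean(window$values_ms),
                         window$fs_hz, bands, p = p, max_level = max_level)
  .spectral_result(bp[["lf"]], bp[["hf"]])
}

.parse_wavelet <- function(wavelet) {
  if (!grepl("^db[0-9]+$", wavelet))
    stop("wavelet must be of the form 'db<p>' (Daubechies, p vanishing moments)")
  as.integer(sub("^db", "", wavelet))
}

#' Welch periodogram LF/HF band powers (cross-check oracle)
#'
#' Fourier counterpart of [wavelet_band_power()]; same band edges and result
#' shape, used to cross-check the wavelet estimates.
#'
#' @inheritParams wavelet_band_power
#' @param nseg Welch segment length (default 256 samples).
#' @return Object of class `hrv_spectral`.
#' @export
fft_band_power <- function(window, bands = .hrv_bands(), nseg = 256L) {
  stopifnot(inherits(window, "tachogram_window"))
  bp <- welch_band_power(window$values_ms - mean(window$values_ms),
                         window$fs_hz, bands, nseg = nseg)
  .spectral_result(bp[["lf"]], bp[["hf"]])
}

#' @export
print.hrv_time_domain <- function(x, ...) {
  cat(sprintf("<hrv_time_domain> mean IBI %.1f ms, SDNN %.2f ms, RMSSD %.2f ms, pNN50 %.1f%% (n=%d)\n",
              x$mean_ibi_ms, x$sdnn_ms, x$rmssd_ms, x$pnn50_pct, x$n_beats))
  invisible(x)
}

#' @export
print.hrv_spectral <- function(x, ...) {
  cat(sprintf("<hrv_spectral> LF %.1f ms2 (%.1f nu), HF %.1f ms2 (%.1f nu), ln LF/HF %.2f\n",
              x$lf_ms2, x$lf_nu_pct, x$hf_ms2, x$hf_nu_pct, x$ln_lf_hf_ratio))
  invisible(x)
}
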