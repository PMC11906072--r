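# The common currency of the HRV/BRS stages: a validated per-beat record.

#' Construct a beat series
#'
#' A per-beat record stream: strictly increasing beat times, RR intervals in
#' ms, and optional beat-to-beat pressures. For unedited beats the RR interval
#' must agree with the successive beat-time difference within 1 ms.
#'
#' @param time_s Beat occurrence times in seconds (strictly increasing).
#' @param rr_ms RR intervals in ms (> 0), same length.
#' @param sbp_mmhg,dbp_mmhg,map_mmhg Optional per-beat pressures.
#' @param flags Optional logical vector of quality flags (TRUE = suspect).
#' @param meta List of provenance metadata (participant, condition, ...).
#' @param check_rr_time If TRUE (default) enforce the RR/beat-time
#'   consistency invariant.
#' @return A data.frame of class `beat_series` with attribute `meta`.
#' @export
beat_series <- function(time_s, rr_ms, sbp_mmhg = NULL, dbp_mmhg = NULL,
                        map_mmhg = NULL, flags = NULL, meta = list(),
                        check_rr_time = TRUE) {
  stopifnot(is.numeric(time_s), is.numeric(rr_ms),
            length(time_s) == length(rr_ms), length(time_s) >= 1)
  if (any(diff(time_s) <= 0)) {
    bad <- which(diff(time_s) <= 0)[1] + 1L
    stop("beat times must be strictly increasing (violated at beat ", bad, ")")
  }
  if (any(rr_ms <= 0)) stop("RR intervals must be positive")
  if (check_rr_time && length(time_s) > 1) {
    dev <- abs(rr_ms[-1] - 1000 * diff(time_s))
    if (any(dev > 1 + 1e-9))
      stop("RR interval and beat-time difference disagree by > 1 ms at beat ",
           which(dev > 1 + 1e-9)[1] + 1L)
  }
  df <- data.frame(time_s = time_s, rr_ms = rr_ms)
  if (!is.null(sbp_mmhg)) df$sbp_mmhg <- sbp_mmhg
  if (!is.null(dbp_mmhg)) df$dbp_mmhg <- dbp_mmhg
  if (!is.null(map_mmhg)) df$map_mmhg <- map_mmhg
  df$flag <- if (is.null(flags)) FALSE else as.logical(flags)
  structure(df, class = c("beat_series", "data.frame"), meta = meta)
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats over %.1f s, %d flagged\n",
              nrow(x), max(x$time_s) - min(x$time_s), sum(x$flag)))
  if (!is.null(x$sbp_mmhg))
    cat(sprintf("  SBP %.0f-%.0f mmHg\n", min(x$sbp_mmhg), max(x$sbp_mmhg)))
  invisible(x)
}

#' Metadata of a beat series or tachogram window
#' @param x Object carrying a `meta` attribute.
#' @return The metadata list.
#' @export
series_meta <- function(x) attr(x, "meta", exact = TRUE)
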