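# Spontaneous sequence-method baroreflex sensitivity.

#' Detect spontaneous SBP ramps
#'
#' Maximal runs of at least `min_len` consecutive beats whose per-beat SBP
#' changes are all in the same direction and each exceed `thr_mmhg` in
#' magnitude. Up and down ramps are both returned.
#'
#' @param sbp Per-beat systolic pressure (mmHg).
#' @param min_len Minimum ramp length in beats (default 3, the classical
#'   sequence-method convention).
#' @param thr_mmhg Per-beat change threshold (default 1 mmHg, strict).
#' @return data.frame with `start_beat`, `end_beat`, `direction`
#'   (`"up"`/`"down"`), `n_beats`; zero rows when no ramps exist.
#' @export
detect_ramps <- function(sbp, min_len = 3L, thr_mmhg = 1) {
  stopifnot(is.numeric(sbp), min_len >= 3)
  out <- data.frame(start_beat = integer(0), end_beat = integer(0),
                    direction = character(0), n_beats = integer(0))
  if (length(sbp) < min_len) return(out)
  d <- diff(sbp)
  s <- ifelse(d > thr_mmhg, 1L, ifelse(d < -thr_mmhg, -1L, 0L))
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] == 0L) next
    n_beats <- r$lengths[k] + 1L          # run of deltas spans one more beat
    if (n_beats < min_len) next
    out <- rbind(out, data.frame(
      start_beat = starts[k], end_beat = ends[k] + 1L,
      direction = if (r$values[k] > 0) "up" else "down",
      n_beats = n_beats))
  }
  out
}

#' Pair SBP ramps with lagged RR responses
#'
#' For each ramp the RR segment at `lag` beats offset is tested for
#' same-direction per-beat changes exceeding `thr_ms`; the sequence slope is
#' the least-squares regression of RR on SBP and is kept only when
#' `r^2 >= r2_min`.
#'
#' @param ramps Output of [detect_ramps()].
#' @param sbp,rr Aligned per-beat SBP (mmHg) and RR (ms) vectors.
#' @param lag RR response lag in beats (default 1).
#' @param thr_ms Per-beat RR change threshold (default 4 ms, strict).
#' @param r2_min Minimum squared correlation for a valid sequence
#'   (default 0.85).
#' @return data.frame of sequences (`start_beat`, `end_beat`, `direction`,
#'   `slope_ms_per_mmhg`, `r`, `n_beats`); attributes `n_ramps` and
#'   `n_skipped_out_of_range` carry the bookkeeping.
#' @export
pair_sequences <- function(ramps, sbp, rr, lag = 1L, thr_ms = 4,
                           r2_min = 0.85) {
  stopifnot(is.data.frame(ramps), length(sbp) == length(rr), lag >= 0)
  res <- list()
  skipped <- 0L
  for (k in seq_len(nrow(ramps))) {
    i0 <- ramps$start_beat[k]; i1 <- ramps$end_beat[k]
    j0 <- i0 + lag; j1 <- i1 + lag
    if (j1 > length(rr)) { skipped <- skipped + 1L; next }
    rseg <- rr[j0:j1]
    sseg <- sbp[i0:i1]
    drr <- diff(rseg)
    dir_ok <- if (ramps$direction[k] == "up") all(drr > thr_ms) else all(drr < -thr_ms)
    if (!dir_ok) next
    fit <- stats::lm.fit(cbind(1, sseg), rseg)
    slope <- fit$coefficients[2]
    r <- stats::cor(sseg, rseg)
    if (r^2 < r2_min) next
    res[[length(res) + 1L]] <- data.frame(
      start_beat = i0, end_beat = i1, direction = ramps$direction[k],
      lag_beats = lag, slope_ms_per_mmhg = unname(slope), r = r,
      n_beats = ramps$n_beats[k])
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(start_beat = integer(0), end_beat = integer(0),
               direction = character(0), lag_beats = integer(0),
               slope_ms_per_mmhg = numeric(0), r = numeric(0),
               n_beats = integer(0))
  attr(out, "n_ramps") <- nrow(ramps)
  attr(out, "n_skipped_out_of_range") <- skipped
  out
}

#' Estimate baroreflex sensitivity from valid sequences
#'
#' BRS is the mean of the valid sequence slopes; the baroreflex effectiveness
#' index (BEI) is the fraction of SBP ramps that produced a valid sequence.
#'
#' @param sequences Output of [pair_sequences()].
#' @param min_sequences Minimum number of sequences required (default 3).
#' @return Object of class `brs_estimate`: `brs_ms_per_mmhg`, `n_sequences`,
#'   `n_up`, `n_down`, `bei`.
#' @export
estimate_brs <- function(sequences, min_sequences = 3L) {
  n_ramps <- attr(sequences, "n_ramps", exact = TRUE)
  if (is.null(n_ramps)) n_ramps <- NA_integer_
  if (nrow(sequences) < min_sequences) {
    if (!is.na(n_ramps) && n_ramps == 0L)
      stop("quality error: no SBP ramps detected")
    stop("quality error: only ", nrow(sequences),
         " valid sequences (ramps without an adequate RR response; need >= ",
         min_sequences, ")")
  }
  structure(list(
    brs_ms_per_mmhg = mean(sequences$slope_ms_per_mmhg),
    n_sequences = nrow(sequences),
    n_up = sum(sequences$direction == "up"),
    n_down = sum(sequences$direction == "down"),
    bei = if (!is.na(n_ramps) && n_ramps > 0) nrow(sequences) / n_ramps else NA_real_
  ), class = "brs_estimate")
}

#' Sequence-method BRS straight from a beat series
#'
#' Convenience wrapper chaining [detect_ramps()], [pair_sequences()] and
#' [estimate_brs()] on a beat series carrying SBP.
#'
#' @param beats A [beat_series()] with an `sbp_mmhg` column.
#' @param window Optional `c(start_s, end_s)` restriction.
#' @param min_len,thr_mmhg Ramp detection parameters (see [detect_ramps()]).
#' @param lag,thr_ms,r2_min Sequence parameters (see [pair_sequences()]).
#' @param min_sequences Estimate guard (see [estimate_brs()]).
#' @return A `brs_estimate`.
#' @export
brs_from_beats <- function(beats, window = NULL, min_len = 3L, thr_mmhg = 1,
                           lag = 1L, thr_ms = 4, r2_min = 0.85,
                           min_sequences = 3L) {
  stopifnot(inherits(beats, "beat_series"))
  if (is.null(beats$sbp_mmhg)) stop("beat series carries no SBP column")
  sel <- if (is.null(window)) rep(TRUE, nrow(beats)) else
    beats$time_s >= window[1] & beats$time_s <= window[2]
  sbp <- beats$sbp_mmhg[sel]
  rr <- beats$rr_ms[sel]
  ramps <- detect_ramps(sbp, min_len = min_len, thr_mmhg = thr_mmhg)
  seqs <- pair_sequences(ramps, sbp, rr, lag = lag, thr_ms = thr_ms,
                         r2_min = r2_min)
  estimate_brs(seqs, min_sequences = min_sequences)
}

#' @export
print.brs_estimate <- function(x, ...) {
  cat(sprintf("<brs_estimate> %.2f ms/mmHg from %d sequences (%d up / %d down), BEI %.2f\n",
              x$brs_ms_per_mmhg, x$n_sequences, x$n_up, x$n_down, x$bei))
  invisible(x)
}
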