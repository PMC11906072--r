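# Delimited-text readers and writers. One dialect everywhere: comma
# separator, '.' decimal, mandatory header, UTF-8.

#' Read a beat table
#'
#' CSV with columns `time_s`, `rr_ms` and optional `sbp_mmhg`, `dbp_mmhg`,
#' `map_mmhg`. Duplicate-measurement column pairs named `<col>_1`/`<col>_2`
#' (e.g. two brachial readings) are averaged into `<col>`.
#'
#' @param path CSV file path.
#' @return A [beat_series()].
#' @export
read_beat_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  # average duplicate-measurement columns
  for (base in unique(sub("_[12]$", "", grep("_[12]$", names(df), value = TRUE)))) {
    c1 <- paste0(base, "_1"); c2 <- paste0(base, "_2")
    if (all(c(c1, c2) %in% names(df))) {
      df[[base]] <- (df[[c1]] + df[[c2]]) / 2
      df[[c1]] <- df[[c2]] <- NULL
    }
  }
  req <- c("time_s", "rr_ms")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  for (cc in intersect(c("time_s", "rr_ms", "sbp_mmhg", "dbp_mmhg", "map_mmhg"),
                       names(df))) {
    if (!is.numeric(df[[cc]]))
      stop("non-numeric value in column '", cc, "' (row ",
           which(is.na(suppressWarnings(as.numeric(df[[cc]]))))[1], ")")
  }
  if (any(diff(df$time_s) <= 0))
    stop("non-monotone time at row ", which(diff(df$time_s) <= 0)[1] + 1L)
  beat_series(df$time_s, df$rr_ms, sbp_mmhg = df$sbp_mmhg,
              dbp_mmhg = df$dbp_mmhg, map_mmhg = df$map_mmhg,
              check_rr_time = FALSE)
}

#' Write a beat table
#' @param beats A [beat_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_beat_table <- function(beats, path) {
  stopifnot(inherits(beats, "beat_series"))
  df <- as.data.frame(beats)
  df$flag <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a waveform pair
#'
#' CSV with columns `t_s`, `proximal_au`, `distal_au`; the sampling rate is
#' recovered from the time column.
#'
#' @param path CSV path.
#' @param distance_m Direct inter-site distance (m).
#' @param site_pair Site pair label (`"cf"`, `"cr"`, `"cd"`).
#' @return A `waveform_pair`.
#' @export
read_waveform_pair <- function(path, distance_m, site_pair = "cf") {
  df <- utils::read.csv(path)
  req <- c("t_s", "proximal_au", "distal_au")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  dt <- diff(df$t_s)
  if (any(dt <= 0)) stop("non-monotone time at row ", which(dt <= 0)[1] + 1L)
  structure(list(fs_hz = 1 / stats::median(dt), t_s = df$t_s,
                 proximal = df$proximal_au, distal = df$distal_au,
                 distance_m = distance_m, site_pair = site_pair,
                 meta = list(path = path)),
            class = "waveform_pair")
}

#' Write a waveform pair
#' @param pair A `waveform_pair`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_waveform_pair <- function(pair, path) {
  stopifnot(inherits(pair, "waveform_pair"))
  utils::write.csv(data.frame(t_s = pair$t_s, proximal_au = pair$proximal,
                              distal_au = pair$distal),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gas-exchange trace
#'
#' CSV with columns `t_min`, `vo2_ml_min`, `vco2_ml_min`, optional `hr_bpm`
#' and `phase`.
#'
#' @param path CSV path.
#' @return A `gas_trace` data.frame.
#' @export
read_gas_trace <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("t_min", "vo2_ml_min", "vco2_ml_min")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$vo2_ml_min < 0) || any(df$vco2_ml_min < 0))
    stop("negative gas flow encountered")
  if (!"phase" %in% names(df)) df$phase <- "rest"
  structure(df, class = c("gas_trace", "data.frame"))
}

#' Write a gas-exchange trace
#' @param trace A `gas_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gas_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Concatenate gas traces into a multi-phase session trace
#'
#' @param ... `gas_trace` objects in session order; their `phase` labels are
#'   kept, and `t_min` is re-numbered consecutively.
#' @return A `gas_trace`.
#' @export
bind_gas_traces <- function(...) {
  parts <- list(...)
  df <- do.call(rbind, lapply(parts, as.data.frame))
  df$t_min <- seq_len(nrow(df))
  structure(df, class = c("gas_trace", "data.frame"))
}

#' Read a long-format trial table
#' @param path CSV with columns `participant`, `group`, `condition`,
#'   `timepoint` and at least one outcome column.
#' @return A `trial_table` data.frame.
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("participant", "group", "condition", "timepoint")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  structure(df, class = c("trial_table", "data.frame"))
}

#' Write a long-format results or trial table
#' @param table data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
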