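## Plain-text serialization: wide CSV for EMG, event CSV, JSON for synergy
## sets, impairment reports and stimulation strategies, CSV command logs.

#' Read a wide EMG CSV
#'
#' Expects a header row of muscle names with a leading `time_s` column;
#' one row per sample.
#'
#' @param path CSV file path.
#' @param sample_rate sampling rate in Hz; inferred from the time column
#'   when `NULL`.
#' @param side recording side.
#' @return An [emg_recording()].
#' @export
read_emg_csv <- function(path, sample_rate = NULL, side = "dominant") {
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "time_s")
    sg_stop("invalid_input", "first column must be time_s")
  if (is.null(sample_rate)) {
    dt <- diff(df$time_s)
    sample_rate <- 1 / median(dt)
  }
  emg_recording(t(as.matrix(df[, -1L, drop = FALSE])),
                muscle_names = names(df)[-1L],
                sample_rate = sample_rate, side = side)
}

#' Write a wide EMG CSV
#'
#' @param rec an [emg_recording()].
#' @param path output path.
#' @export
write_emg_csv <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  df <- data.frame(time_s = (seq_len(ncol(rec$data)) - 1L) / rec$sample_rate)
  df <- cbind(df, as.data.frame(t(rec$data)))
  names(df) <- c("time_s", rec$muscle_names)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a gait-event CSV (`time_s`, `event`, `side` columns)
#'
#' @param path CSV path.
#' @return A [gait_event_stream()].
#' @export
read_events_csv <- function(path) {
  df <- read.csv(path)
  need <- c("time_s", "event", "side")
  if (!all(need %in% names(df)))
    sg_stop("invalid_input", "event CSV needs columns: %s", paste(need, collapse = ", "))
  gait_event_stream(df$time_s, df$event, df$side)
}

#' Write a gait-event CSV
#'
#' @param stream a [gait_event_stream()].
#' @param path output path.
#' @export
write_events_csv <- function(stream, path) {
  write.csv(data.frame(time_s = stream$time_s, event = stream$type,
                       side = stream$side), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a synergy set to JSON
#'
#' @param syn a [synergy_set()].
#' @param path output path.
#' @export
write_synergy_json <- function(syn, path) {
  stopifnot(inherits(syn, "synergy_set"))
  obj <- list(muscle_names = syn$muscle_names, labels = syn$labels,
              W = unname(syn$W), H = unname(syn$H),
              vaf_total = syn$vaf_total,
              vaf_per_muscle = unname(syn$vaf_per_muscle))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a synergy set from JSON
#'
#' @param path JSON path written by [write_synergy_json()].
#' @return A [synergy_set()].
#' @export
read_synergy_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  syn <- synergy_set(as.matrix(obj$W), as.matrix(obj$H),
                     muscle_names = obj$muscle_names, labels = obj$labels,
                     vaf_total = obj$vaf_total %||% NA_real_)
  syn
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize an impairment report to JSON
#'
#' @param report an [impairment_report()].
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "impairment_report"))
  obj <- list(metrics = as.data.frame(report$metrics),
              synergies = rownames(report$metrics),
              thresholds = as.list(report$thresholds),
              impaired = as.list(report$impaired),
              vaf = as.list(report$vaf))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an impairment report from JSON
#'
#' @param path JSON path written by [write_report_json()].
#' @return An [impairment_report()].
#' @export
read_report_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  metrics <- as.matrix(obj$metrics)
  rownames(metrics) <- obj$synergies
  impairment_report(metrics, unlist(obj$thresholds),
                    if (length(obj$impaired)) unlist(obj$impaired) else NULL,
                    vaf = unlist(obj$vaf))
}

#' Write an impairment report as a metric table CSV
#'
#' One row per metric, one column per synergy plus the threshold column.
#'
#' @param report an [impairment_report()].
#' @param path output path.
#' @export
write_report_csv <- function(report, path) {
  tab <- t(report$metrics)
  tab <- cbind(tab, threshold = report$thresholds[rownames(tab)])
  write.csv(round(tab, 4), path)
  invisible(path)
}

#' Serialize a stimulation strategy to JSON
#'
#' @param strategy a [build_strategy()] result.
#' @param path output path.
#' @export
write_strategy_json <- function(strategy, path) {
  stopifnot(inherits(strategy, "stimulation_strategy"))
  obj <- list(
    impaired = strategy$impaired,
    pw_max_us = strategy$pw_max_us,
    frequency_hz = strategy$frequency_hz,
    template_phase_bounds = strategy$template_phase_bounds,
    no_stimulation = strategy$no_stimulation,
    channels = lapply(strategy$channels, function(ch)
      list(muscles = ch$muscles, amplitude_mA = ch$amplitude_mA,
           profile = unname(ch$profile))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stimulation strategy from JSON
#'
#' @param path JSON path written by [write_strategy_json()].
#' @return A `stimulation_strategy`.
#' @export
read_strategy_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  channels <- lapply(seq_len(length(obj$channels$muscles %||% obj$channels)),
                     function(i) NULL)
  ## jsonlite simplification varies with channel count; rebuild robustly
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  channels <- lapply(raw$channels, function(ch)
    list(muscles = unlist(ch$muscles),
         amplitude_mA = if (is.null(ch$amplitude_mA)) NA_real_ else ch$amplitude_mA,
         profile = unlist(ch$profile)))
  structure(list(channels = channels,
                 impaired = unlist(raw$impaired),
                 pw_max_us = raw$pw_max_us, frequency_hz = raw$frequency_hz,
                 template_phase_bounds = unlist(raw$template_phase_bounds),
                 no_stimulation = isTRUE(raw$no_stimulation)),
            class = "stimulation_strategy")
}

#' Write a stimulator command log CSV
#'
#' @param log data frame from [simulate_session()].
#' @param path output path.
#' @export
write_command_log <- function(log, path) {
  write.csv(log, path, row.names = FALSE)
  invisible(path)
}
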