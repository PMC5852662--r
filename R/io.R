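#' Events tables
#'
#' Sequences are exchanged as tab-separated events tables with columns
#' `onset` (s, written with 6 decimals), `duration` (s), `event_type`
#' (`"tone"` or `"press"`), `value` (tone frequency in Hz or percept
#' label), `condition`, and `delta_f`.
#'
#' @param timeline A [build_stimulus_timeline()].
#' @param reports The sequence's `report_stream`.
#' @return Events data.frame sorted by onset.
#' @export
events_from_sequence <- function(timeline, reports) {
  tones <- data.frame(
    onset = as.vector(t(timeline$tone_onsets)),
    duration = timeline$tone_duration,
    event_type = "tone",
    value = as.character(as.vector(t(timeline$tone_freqs))),
    condition = reports$condition,
    delta_f = timeline$delta_f,
    stringsAsFactors = FALSE
  )
  presses <- data.frame(
    onset = reports$presses$time,
    duration = 0,
    event_type = "press",
    value = reports$presses$percept,
    condition = reports$condition,
    delta_f = timeline$delta_f,
    stringsAsFactors = FALSE
  )
  ev <- rbind(tones, presses)
  ev[order(ev$onset), , drop = FALSE]
}

#' @rdname events_from_sequence
#' @param events Events data.frame.
#' @param path File path.
#' @export
write_events <- function(events, path) {
  required <- c("onset", "duration", "event_type", "value",
                "condition", "delta_f")
  missing <- setdiff(required, names(events))
  if (length(missing) > 0) {
    stop("events table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ev <- events[required]
  ev$onset <- sprintf("%.6f", ev$onset)
  utils::write.table(ev, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname events_from_sequence
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("onset", "duration", "event_type", "value",
                "condition", "delta_f")
  missing <- setdiff(required, names(ev))
  if (length(missing) > 0) {
    stop("events table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("onset", "duration", "delta_f")) {
    num <- suppressWarnings(as.numeric(ev[[col]]))
    bad <- which(is.na(num) & !is.na(ev[[col]]))
    if (length(bad) > 0) {
      stop("malformed ", col, " at line ", bad[1] + 1L, call. = FALSE)
    }
    ev[[col]] <- num
  }
  ev
}

#' Extract a report stream from an events table
#'
#' @param events Events data.frame for one sequence.
#' @param sequence_duration Duration in seconds (defaults to the last tone
#'   offset plus the 200 ms inter-triplet gap).
#' @return A `report_stream`.
#' @export
reports_from_events <- function(events, sequence_duration = NULL) {
  pr <- events[events$event_type == "press", , drop = FALSE]
  if (is.null(sequence_duration)) {
    tones <- events[events$event_type == "tone", , drop = FALSE]
    sequence_duration <- max(tones$onset) + 0.100 + 0.200
  }
  structure(list(
    presses = data.frame(time = pr$onset, percept = pr$value,
                         stringsAsFactors = FALSE),
    condition = events$condition[1],
    delta_f = events$delta_f[1],
    sequence_duration = sequence_duration
  ), class = "report_stream")
}

#' Binary recording files
#'
#' Recordings are stored as little-endian float32 with a JSON sidecar
#' (`sampling_rate_hz`, `n_samples`, `channels`, `units`, `seed`).
#'
#' @param rec A [recording()].
#' @param path_prefix Path without extension; writes `.f32` and `.json`.
#' @param seed Seed recorded in the sidecar.
#' @export
write_recording <- function(rec, path_prefix, seed = NA) {
  bin <- paste0(path_prefix, ".f32")
  con <- file(bin, "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4L, endian = "little")
  sidecar <- list(sampling_rate_hz = rec$sample_rate,
                  n_samples = length(rec$data),
                  channels = rec$channel, units = rec$units, seed = seed)
  jsonlite::write_json(sidecar, paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path_prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(path_prefix) {
  sidecar <- jsonlite::read_json(paste0(path_prefix, ".json"),
                                 simplifyVector = TRUE)
  con <- file(paste0(path_prefix, ".f32"), "rb")
  on.exit(close(con))
  data <- readBin(con, numeric(), n = sidecar$n_samples, size = 4L,
                  endian = "little")
  recording(data, sidecar$sampling_rate_hz, sidecar$units, sidecar$channels)
}

#' Serialize / restore a pipeline configuration
#'
#' Configurations round-trip losslessly through JSON.
#'
#' @param config A [cohort_config()].
#' @param path File path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$percept$mu_log <- lapply(raw$percept$mu_log, unlist)
  raw$percept$intention_multipliers <-
    lapply(raw$percept$intention_multipliers, unlist)
  raw$percept <- do.call(percept_params, raw$percept)
  raw$neural <- do.call(neural_params, lapply(raw$neural, unlist))
  structure(raw, class = "pipeline_config")
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_deep)
  } else if (is.atomic(x) && !is.null(names(x))) {
    as.list(x)                      # keep names through JSON round trips
  } else {
    x
  }
}
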