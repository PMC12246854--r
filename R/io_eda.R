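#' Electrodermal activity series
#'
#' An `eda_series` is a tibble with one row per sample and columns
#' `time_s` (seconds from recording start), `conductance_us` (skin
#' conductance in microsiemens) and `artifact` (logical; `TRUE` marks a
#' sample flagged invalid). Recording metadata travel as attributes:
#' `participant_id`, `start_time` (POSIXct, UTC), `sample_rate` (Hz) and
#' `events` (tibble of `time_s`, `label` marks pressed on the device).
#'
#' @param values numeric conductance samples in microsiemens.
#' @param sample_rate sampling rate in Hz (wrist devices: 4).
#' @param start_time recording start, POSIXct (UTC) or epoch seconds.
#' @param participant_id opaque participant identifier.
#' @param events optional tibble `time_s`, `label` of event marks.
#' @param artifact optional logical artifact mask (defaults to all-FALSE).
#' @return an `eda_series` tibble.
#' @export
eda_series <- function(values, sample_rate, start_time = 0,
                       participant_id = "unknown", events = NULL,
                       artifact = NULL) {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) {
    abort("EDA values must be finite and non-missing",
          class = "stressphys_validation_error")
  }
  if (length(values) < 2) {
    abort("an EDA series needs at least 2 samples",
          class = "stressphys_validation_error")
  }
  if (!is.finite(sample_rate) || sample_rate <= 0) {
    abort("sample_rate must be > 0", class = "stressphys_validation_error")
  }
  if (is.null(artifact)) artifact <- rep(FALSE, length(values))
  if (length(artifact) != length(values)) {
    abort("artifact mask must match values length",
          class = "stressphys_validation_error")
  }
  if (is.numeric(start_time)) {
    start_time <- as.POSIXct(start_time, origin = "1970-01-01", tz = "UTC")
  }
  duration <- length(values) / sample_rate
  if (is.null(events)) {
    events <- tibble(time_s = numeric(), label = character())
  } else {
    events <- as_tibble(events)
    bad <- events$time_s < 0 | events$time_s > duration
    if (any(bad)) {
      abort(sprintf("event mark(s) outside recording span [0, %g s]: %s",
                    duration, paste(events$time_s[bad], collapse = ", ")),
            class = "stressphys_validation_error")
    }
  }
  out <- tibble(
    time_s = (seq_along(values) - 1) / sample_rate,
    conductance_us = values,
    artifact = as.logical(artifact)
  )
  structure(out,
            participant_id = participant_id,
            start_time = start_time,
            sample_rate = sample_rate,
            events = events,
            class = c("eda_series", class(out)))
}

eda_attrs <- function(series) {
  list(participant_id = attr(series, "participant_id"),
       start_time = attr(series, "start_time"),
       sample_rate = attr(series, "sample_rate"),
       events = attr(series, "events"))
}

# rebuild an eda_series with new values/mask, keeping metadata
eda_update <- function(series, values = series$conductance_us,
                       artifact = series$artifact) {
  a <- eda_attrs(series)
  eda_series(values, a$sample_rate, a$start_time, a$participant_id,
             events = a$events, artifact = artifact)
}

#' Read and write wrist-device EDA CSV exports
#'
#' The device dialect is: row 1 — UTC start time as an epoch timestamp;
#' row 2 — sampling rate in Hz; every following row — one conductance
#' sample in microsiemens. An optional companion tags file holds one UTC
#' epoch timestamp per line, one per event-mark button press.
#'
#' @param path CSV file in the device dialect.
#' @param tags_path optional tags file (one epoch timestamp per line).
#' @param participant_id identifier to attach; defaults to the file stem.
#' @return `read_eda_csv()`: an [eda_series]. `write_eda_csv()`: `path`,
#'   invisibly (writes the companion tags file when events are present).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' s <- eda_series(c(2, 2.1, 2.2, 2.1), sample_rate = 4, start_time = 1e9)
#' write_eda_csv(s, f)
#' identical(read_eda_csv(f)$conductance_us, s$conductance_us)
#' @export
read_eda_csv <- function(path, tags_path = NULL, participant_id = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("EDA file not found: %s", path), class = "stressphys_io_error")
  }
  lines <- readLines(path)
  if (length(lines) < 2) {
    abort(sprintf("%s: malformed header — expected epoch (row 1) and sample rate (row 2)", path),
          class = "stressphys_format_error")
  }
  start_epoch <- suppressWarnings(as.numeric(lines[1]))
  rate <- suppressWarnings(as.numeric(lines[2]))
  if (is.na(start_epoch)) {
    abort(sprintf("%s: row 1 is not a numeric epoch timestamp ('%s')", path, lines[1]),
          class = "stressphys_format_error")
  }
  if (is.na(rate) || rate <= 0) {
    abort(sprintf("%s: row 2 is not a positive sample rate ('%s')", path, lines[2]),
          class = "stressphys_format_error")
  }
  values <- suppressWarnings(as.numeric(lines[-(1:2)]))
  if (anyNA(values)) {
    bad <- which(is.na(values))[1] + 2
    abort(sprintf("%s: non-numeric sample at row %d", path, bad),
          class = "stressphys_format_error")
  }
  events <- NULL
  if (!is.null(tags_path)) {
    if (!file.exists(tags_path)) {
      abort(sprintf("tags file not found: %s", tags_path),
            class = "stressphys_io_error")
    }
    tl <- readLines(tags_path)
    tl <- tl[nzchar(trimws(tl))]
    if (length(tl)) {
      tags <- as.numeric(tl)
      events <- tibble(time_s = tags - start_epoch,
                       label = sprintf("tag%d", seq_along(tags)))
    }
  }
  if (is.null(participant_id)) {
    participant_id <- sub("\\.[^.]*$", "", basename(path))
  }
  eda_series(values, rate, start_epoch, participant_id, events = events)
}

#' @rdname read_eda_csv
#' @param series an [eda_series].
#' @export
write_eda_csv <- function(series, path, tags_path = NULL) {
  a <- eda_attrs(series)
  start_epoch <- as.numeric(a$start_time)
  writeLines(c(sprintf("%.2f", start_epoch),
               sprintf("%.2f", a$sample_rate),
               format(series$conductance_us, trim = TRUE, scientific = FALSE,
                      digits = 15)),
             path)
  if (!is.null(tags_path) && nrow(a$events)) {
    writeLines(sprintf("%.2f", start_epoch + a$events$time_s), tags_path)
  }
  invisible(path)
}
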