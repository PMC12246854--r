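#' Raw fNIRS optical-density recording
#'
#' `fnirs_raw()` bundles a participant's optical-density (OD) traces with
#' the montage and the participant age needed for pathlength adjustment.
#' Each montage channel carries exactly two traces, one per device
#' wavelength; OD changes are dimensionless.
#'
#' @param od named list, one element per channel id, each an `n x 2` numeric
#'   matrix with column names the wavelengths in nm (e.g. `"760"`, `"850"`).
#' @param sample_rate sampling rate in Hz (device default 50).
#' @param montage an [fnirs_montage][read_montage] describing the channels.
#' @param age_years participant age (used for the DPF).
#' @param participant_id opaque identifier.
#' @param start_time recording start (POSIXct or epoch seconds, UTC).
#' @return an object of class `"fnirs_raw"`.
#' @export
fnirs_raw <- function(od, sample_rate, montage, age_years,
                      participant_id = "unknown", start_time = 0) {
  if (!inherits(montage, "fnirs_montage")) {
    abort("montage must be an fnirs_montage", class = "stressphys_config_error")
  }
  unknown <- setdiff(names(od), montage$channels$channel_id)
  if (length(unknown)) {
    abort(sprintf("OD traces reference channels missing from the montage: %s",
                  paste(unknown, collapse = ", ")),
          class = "stressphys_validation_error")
  }
  lens <- integer(0)
  for (ch in names(od)) {
    m <- od[[ch]]
    if (!is.matrix(m) || ncol(m) != 2) {
      abort(sprintf("channel %s must carry exactly 2 wavelength traces", ch),
            class = "stressphys_format_error")
    }
    lens <- c(lens, nrow(m))
  }
  if (length(unique(lens)) > 1) {
    abort("all OD traces must have equal length",
          class = "stressphys_validation_error")
  }
  if (!is.finite(sample_rate) || sample_rate <= 0) {
    abort("sample_rate must be > 0", class = "stressphys_validation_error")
  }
  if (is.numeric(start_time)) {
    start_time <- as.POSIXct(start_time, origin = "1970-01-01", tz = "UTC")
  }
  structure(
    list(participant_id = participant_id, sample_rate = sample_rate,
         montage = montage, age_years = age_years, od = od,
         start_time = start_time),
    class = "fnirs_raw"
  )
}

#' @export
print.fnirs_raw <- function(x, ...) {
  n <- if (length(x$od)) nrow(x$od[[1]]) else 0
  cat(sprintf("<fnirs_raw> %s: %d channels x 2 wavelengths, %d samples @ %g Hz (%.1f s)\n",
              x$participant_id, length(x$od), n, x$sample_rate,
              n / x$sample_rate))
  invisible(x)
}

fnirs_label <- function(channel_id, wavelength_nm) {
  sprintf("%s %g", channel_id, wavelength_nm)
}

#' Read and write fNIRS recordings in EDF
#'
#' EDF signal labels follow the convention `"<channel id> <wavelength nm>"`
#' (e.g. `"Tx1-Rx2 760"`); the convention is configurable by supplying a
#' `label_map` that translates nonconforming labels before matching. Every
#' montage channel must resolve to exactly two wavelength traces.
#'
#' @param path EDF file.
#' @param montage an [fnirs_montage][read_montage].
#' @param age_years participant age in years.
#' @param participant_id identifier; defaults to the file stem.
#' @param label_map optional named character vector translating raw EDF
#'   labels to `"<channel> <wavelength>"` form.
#' @return `read_fnirs_edf()`: an [fnirs_raw]. `write_fnirs_edf()`: the
#'   path, invisibly.
#' @export
read_fnirs_edf <- function(path, montage, age_years, participant_id = NULL,
                           label_map = NULL) {
  edf <- read_edf(path)
  labels <- edf$labels
  if (!is.null(label_map)) {
    hit <- labels %in% names(label_map)
    labels[hit] <- unname(label_map[labels[hit]])
  }
  parts <- strsplit(labels, " +")
  chan <- vapply(parts, `[`, "", 1)
  wl <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  known <- chan %in% montage$channels$channel_id & !is.na(wl)
  if (any(!known)) {
    abort(sprintf("EDF labels not matching any montage channel: %s",
                  paste(edf$labels[!known], collapse = ", ")),
          class = "stressphys_format_error")
  }
  od <- list()
  for (ch in unique(chan)) {
    idx <- which(chan == ch)
    if (length(idx) != 2) {
      abort(sprintf("channel %s has %d wavelength trace(s), expected 2",
                    ch, length(idx)),
            class = "stressphys_format_error")
    }
    idx <- idx[order(wl[idx])]
    m <- cbind(edf$signals[[idx[1]]], edf$signals[[idx[2]]])
    colnames(m) <- as.character(wl[idx])
    od[[ch]] <- m
  }
  rate <- unique(edf$sample_rates)
  if (length(rate) != 1) {
    abort("fNIRS EDF must have a single sampling rate across signals",
          class = "stressphys_format_error")
  }
  if (is.null(participant_id)) {
    participant_id <- sub("\\.[^.]*$", "", basename(path))
  }
  fnirs_raw(od, rate, montage, age_years, participant_id,
            start_time = edf$start_time)
}

#' @rdname read_fnirs_edf
#' @param raw an [fnirs_raw].
#' @export
write_fnirs_edf <- function(raw, path) {
  signals <- list()
  for (ch in names(raw$od)) {
    m <- raw$od[[ch]]
    for (w in colnames(m)) {
      signals[[fnirs_label(ch, as.numeric(w))]] <- m[, w]
    }
  }
  write_edf(signals, raw$sample_rate, path, start_time = raw$start_time,
            patient_id = raw$participant_id)
}
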