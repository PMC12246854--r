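#' Minimal European Data Format (EDF) reader and writer
#'
#' EDF stores multichannel physiological recordings as an ASCII header
#' (256 bytes global + 256 bytes per signal) followed by data records of
#' 16-bit little-endian integers, linearly mapped between each signal's
#' digital and physical ranges. This implementation covers continuous
#' recordings with a fixed record duration of one second and an integer
#' number of samples per record per signal — the layout produced by fNIRS
#' acquisition software exports — and is the transport used by the
#' synthetic-cohort generator.
#'
#' Values round-trip within quantisation precision: 16-bit scaling over the
#' stored physical range bounds the absolute error by
#' `(phys_max - phys_min) / (2^16 - 1)` per sample.
#'
#' @param path file path.
#' @return `read_edf()`: a list with `start_time` (POSIXct UTC), `labels`
#'   (character), `sample_rates` (per signal, Hz), and `signals` (named list
#'   of numeric vectors in physical units).
#' @keywords internal
read_edf <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("EDF file not found: %s", path), class = "stressphys_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 256))
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  startdate <- fld(hdr, 169, 8)
  starttime <- fld(hdr, 177, 8)
  n_records <- as.integer(fld(hdr, 237, 8))
  rec_dur <- as.numeric(fld(hdr, 245, 8))
  ns <- as.integer(fld(hdr, 253, 4))
  if (is.na(ns) || ns < 1) {
    abort(sprintf("%s: malformed EDF header (signal count)", path),
          class = "stressphys_format_error")
  }
  sig_hdr <- rawToChar(readBin(con, "raw", 256 * ns))
  take <- function(width, offset) {
    vapply(seq_len(ns), function(i) {
      trimws(substr(sig_hdr, offset + (i - 1) * width + 1, offset + i * width))
    }, character(1))
  }
  labels <- take(16, 0)
  phys_min <- as.numeric(take(8, ns * (16 + 80 + 8)))
  phys_max <- as.numeric(take(8, ns * (16 + 80 + 8 + 8)))
  dig_min <- as.numeric(take(8, ns * (16 + 80 + 8 + 8 + 8)))
  dig_max <- as.numeric(take(8, ns * (16 + 80 + 8 + 8 + 8 + 8)))
  spr <- as.integer(take(8, ns * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80)))
  data <- readBin(con, "integer", n = n_records * sum(spr), size = 2,
                  signed = TRUE, endian = "little")
  signals <- vector("list", ns)
  for (i in seq_len(ns)) signals[[i]] <- numeric(n_records * spr[i])
  offs <- c(0, cumsum(spr))
  rec_len <- sum(spr)
  for (r in seq_len(n_records)) {
    base <- (r - 1) * rec_len
    for (i in seq_len(ns)) {
      idx <- base + (offs[i] + 1):offs[i + 1]
      signals[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <- data[idx]
    }
  }
  for (i in seq_len(ns)) {
    gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    signals[[i]] <- (signals[[i]] - dig_min[i]) * gain + phys_min[i]
  }
  names(signals) <- labels
  start_time <- as.POSIXct(paste(startdate, starttime),
                           format = "%d.%m.%y %H.%M.%S", tz = "UTC")
  list(start_time = start_time, labels = labels,
       sample_rates = spr / rec_dur, signals = signals)
}

fmt_edf_num <- function(x, width = 8) {
  for (digits in 7:1) {
    s <- sprintf("%.*g", digits, x)
    if (nchar(s) <= width) return(s)
  }
  abort(sprintf("cannot format %g into %d EDF header characters", x, width),
        class = "stressphys_format_error")
}

pad <- function(s, width) {
  s <- substr(s, 1, width)
  sprintf("%-*s", width, s)
}

#' @rdname read_edf
#' @param signals named list of equal-rate numeric vectors (names become EDF
#'   labels, max 16 characters).
#' @param sample_rate samples per second (integer) shared by all signals.
#' @param start_time recording start, POSIXct or epoch seconds (UTC).
#' @param patient_id,recording_id free-text EDF identity fields.
#' @keywords internal
write_edf <- function(signals, sample_rate, path, start_time = 0,
                      patient_id = "X", recording_id = "Startdate X") {
  if (sample_rate != round(sample_rate)) {
    abort("write_edf requires an integer sample rate",
          class = "stressphys_parameter_error")
  }
  ns <- length(signals)
  n <- unique(lengths(signals))
  if (length(n) != 1) {
    abort("all EDF signals must have equal length",
          class = "stressphys_format_error")
  }
  n_records <- n %/% sample_rate
  if (n_records * sample_rate != n) {
    abort("signal length must be a whole number of 1-s records",
          class = "stressphys_format_error")
  }
  if (is.numeric(start_time)) {
    start_time <- as.POSIXct(start_time, origin = "1970-01-01", tz = "UTC")
  }
  phys_min <- phys_max <- numeric(ns)
  digital <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- signals[[i]]
    r <- max(abs(x), 1e-12)
    # store the rounded header values and quantise against them, so the file
    # is self-consistent; format the negative bound first (the minus sign
    # costs a character) and mirror it, keeping the range exactly symmetric
    pm <- -as.numeric(fmt_edf_num(-r * 1.001))
    phys_min[i] <- -pm
    phys_max[i] <- pm
    d <- round((x + pm) / (2 * pm) * 65535 - 32768)
    digital[[i]] <- as.integer(pmin(pmax(d, -32768), 32767))
  }
  hdr <- paste0(
    pad("0", 8), pad(patient_id, 80), pad(recording_id, 80),
    pad(format(start_time, "%d.%m.%y", tz = "UTC"), 8),
    pad(format(start_time, "%H.%M.%S", tz = "UTC"), 8),
    pad(as.character(256 * (1 + ns)), 8), pad("", 44),
    pad(as.character(n_records), 8), pad("1", 8), pad(as.character(ns), 4)
  )
  sig_hdr <- paste0(
    paste(vapply(names(signals), pad, "", width = 16), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad("", 8), ns), collapse = ""),
    paste(vapply(phys_min, function(v) pad(fmt_edf_num(v), 8), ""), collapse = ""),
    paste(vapply(phys_max, function(v) pad(fmt_edf_num(v), 8), ""), collapse = ""),
    paste(rep(pad("-32768", 8), ns), collapse = ""),
    paste(rep(pad("32767", 8), ns), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad(as.character(sample_rate), 8), ns), collapse = ""),
    paste(rep(pad("", 32), ns), collapse = "")
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(hdr, sig_hdr)), con)
  # interleave per record
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1) * sample_rate + 1):(r * sample_rate)
      writeBin(digital[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
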