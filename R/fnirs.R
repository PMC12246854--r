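#' Age- and wavelength-dependent differential pathlength factor
#'
#' Continuous-wave NIRS measures attenuation along a photon path much longer
#' than the source-detector separation; the differential pathlength factor
#' (DPF) corrects the geometric distance to the effective pathlength. The
#' general age- and wavelength-dependent formulation is
#'
#' \deqn{DPF(\lambda, A) = 223.3 + 0.05624\,A^{0.8493}
#'   - 5.723\times 10^{-7}\lambda^3 + 0.001245\,\lambda^2
#'   - 0.9025\,\lambda}
#'
#' with age `A` in years and wavelength `lambda` in nm. Typical adult values
#' at 760/850 nm are around 6.
#'
#' @param age_years age in years, in (0, 100].
#' @param wavelength_nm wavelength in nm, within the NIR window
#'   (690–880 nm).
#' @return dimensionless DPF (vectorised over either argument).
#' @examples
#' compute_dpf(23, 760)
#' compute_dpf(23, 850)
#' @export
compute_dpf <- function(age_years, wavelength_nm) {
  if (any(age_years <= 0 | age_years > 100)) {
    abort("age_years must be in (0, 100]", class = "stressphys_parameter_error")
  }
  if (any(wavelength_nm < 690 | wavelength_nm > 880)) {
    abort("wavelength_nm must be within the 690-880 nm NIR window",
          class = "stressphys_parameter_error")
  }
  223.3 + 0.05624 * age_years^0.8493 -
    5.723e-7 * wavelength_nm^3 + 0.001245 * wavelength_nm^2 -
    0.9025 * wavelength_nm
}

#' Molar extinction coefficients of haemoglobin
#'
#' Returns the 2x2 extinction matrix used by the modified Beer-Lambert law:
#' rows are wavelengths, columns the chromophores (`ohb`, `hhb`), in
#' cm^-1 per micromol/L. Values are taken from the standard compiled
#' haemoglobin absorption spectra at the device wavelengths; additional
#' wavelengths can be supplied through a user table.
#'
#' @param wavelengths_nm numeric vector of wavelengths.
#' @param table optional data frame `wavelength_nm`, `ohb`, `hhb`
#'   overriding the packaged coefficients.
#' @return matrix with `length(wavelengths_nm)` rows and columns
#'   `ohb`, `hhb`.
#' @export
extinction_coefficients <- function(wavelengths_nm = c(760, 850),
                                    table = NULL) {
  if (is.null(table)) {
    table <- tibble(
      wavelength_nm = c(760, 850),
      ohb = c(0.1486, 0.2526),
      hhb = c(0.3843, 0.1798)
    )
  }
  i <- match(wavelengths_nm, table$wavelength_nm)
  if (anyNA(i)) {
    abort(sprintf("no extinction coefficients for wavelength(s): %s",
                  paste(wavelengths_nm[is.na(i)], collapse = ", ")),
          class = "stressphys_config_error")
  }
  m <- as.matrix(table[i, c("ohb", "hhb")])
  rownames(m) <- as.character(wavelengths_nm)
  m
}

#' Haemoglobin concentration-change series
#'
#' Holds per-channel oxygenated (`ohb`) and deoxygenated (`hhb`)
#' concentration changes in micromol/L after Beer-Lambert conversion.
#'
#' @param channels named list of `n x 2` matrices with columns
#'   `ohb`, `hhb`.
#' @param sample_rate Hz.
#' @param participant_id identifier.
#' @param retained_channels channel ids that passed quality control
#'   (defaults to all).
#' @return object of class `"hemo_series"`.
#' @export
hemo_series <- function(channels, sample_rate, participant_id = "unknown",
                        retained_channels = names(channels)) {
  structure(
    list(participant_id = participant_id, sample_rate = sample_rate,
         channels = channels,
         retained_channels = intersect(retained_channels, names(channels))),
    class = "hemo_series"
  )
}

#' @export
print.hemo_series <- function(x, ...) {
  n <- if (length(x$channels)) nrow(x$channels[[1]]) else 0
  cat(sprintf("<hemo_series> %s: %d/%d channels retained, %d samples @ %g Hz\n",
              x$participant_id, length(x$retained_channels),
              length(x$channels), n, x$sample_rate))
  invisible(x)
}

#' Convert optical densities to haemoglobin concentration changes
#'
#' Applies the modified Beer-Lambert law per channel and sample: the
#' optical-density change at each wavelength is modelled as
#' \deqn{\Delta OD(\lambda) = [\varepsilon_{OHb}(\lambda)\Delta C_{OHb} +
#'   \varepsilon_{HHb}(\lambda)\Delta C_{HHb}]\; d \; DPF(\lambda)}
#' with `d` the source-detector distance (cm) and DPF the age-adjusted
#' differential pathlength factor. The 2x2 linear system over the two
#' wavelengths is solved for `(dOHb, dHHb)` in micromol/L.
#'
#' @param raw an [fnirs_raw].
#' @param extinction optional extinction matrix (see
#'   [extinction_coefficients()]); defaults to the packaged table at the
#'   montage wavelengths.
#' @return a [hemo_series] with all channels retained.
#' @export
beer_lambert <- function(raw, extinction = NULL) {
  wl <- raw$montage$wavelengths_nm
  if (is.null(extinction)) extinction <- extinction_coefficients(wl)
  if (abs(det(extinction)) < 1e-12) {
    abort("extinction matrix is singular", class = "stressphys_numeric_error")
  }
  dpf <- compute_dpf(raw$age_years, wl)
  dist <- setNames(raw$montage$channels$distance_cm,
                   raw$montage$channels$channel_id)
  channels <- list()
  for (ch in names(raw$od)) {
    d <- dist[[ch]]
    if (is.na(d)) {
      abort(sprintf("no source-detector distance for channel %s", ch),
            class = "stressphys_config_error")
    }
    od <- raw$od[[ch]]
    wl_cols <- as.numeric(colnames(od))
    i <- match(wl, wl_cols)
    # effective pathlength per wavelength
    a <- extinction * (d * dpf)   # rows scaled by d*DPF(lambda)
    inv <- solve(a)
    conc <- od[, i, drop = FALSE] %*% t(inv)
    colnames(conc) <- c("ohb", "hhb")
    channels[[ch]] <- conc
  }
  hemo_series(channels, raw$sample_rate, raw$participant_id)
}

#' Forward Beer-Lambert model (concentrations to optical densities)
#'
#' The exact inverse of [beer_lambert()]: given true `(dOHb, dHHb)` traces
#' it produces the optical-density changes a two-wavelength device would
#' record. The synthetic generator builds its EDF files through this
#' forward model with the same extinction table and DPF as the analysis
#' path, so the round-trip identity is exact up to numeric precision.
#'
#' @param conc `n x 2` matrix, columns `ohb`, `hhb` (micromol/L).
#' @param distance_cm source-detector distance.
#' @param age_years participant age.
#' @param wavelengths_nm device wavelengths.
#' @param extinction optional extinction matrix.
#' @return `n x 2` matrix of OD changes, columns named by wavelength.
#' @export
hemo_to_od <- function(conc, distance_cm, age_years,
                       wavelengths_nm = c(760, 850), extinction = NULL) {
  if (is.null(extinction)) extinction <- extinction_coefficients(wavelengths_nm)
  dpf <- compute_dpf(age_years, wavelengths_nm)
  a <- extinction * (distance_cm * dpf)
  od <- conc %*% t(a)
  colnames(od) <- as.character(wavelengths_nm)
  od
}

#' Scalp coupling index of one channel
#'
#' The SCI measures optode-scalp contact through the cardiac pulsation
#' shared by a channel's two wavelength traces: both traces are band-pass
#' filtered to the cardiac band (default 0.7-1.5 Hz), scaled to unit
#' variance, and their zero-lag normalised cross-correlation is returned.
#' Well-coupled channels show a strong common cardiac component (SCI near
#' 1); decoupled channels record independent noise (SCI near 0). A trace
#' with zero variance after filtering yields SCI 0 by convention.
#'
#' @param raw an [fnirs_raw].
#' @param channel_id channel to score.
#' @param band cardiac band in Hz (default `c(0.7, 1.5)`).
#' @param order Butterworth order per band edge (default 4).
#' @return SCI in `[-1, 1]`.
#' @export
compute_sci <- function(raw, channel_id, band = c(0.7, 1.5), order = 4) {
  od <- raw$od[[channel_id]]
  if (is.null(od)) {
    abort(sprintf("unknown channel '%s'", channel_id),
          class = "stressphys_config_error")
  }
  f1 <- butter_bandpass_zp(od[, 1], raw$sample_rate, band, order)
  f2 <- butter_bandpass_zp(od[, 2], raw$sample_rate, band, order)
  if (sd(f1) == 0 || sd(f2) == 0) return(0)
  # after unit-variance scaling the zero-lag cross-correlation is the
  # Pearson correlation of the two cardiac-band traces
  stats::cor(f1, f2)
}

#' Channel quality report and rejection
#'
#' Scores every montage channel with the scalp coupling index and keeps
#' channels with `sci >= threshold` (default 0.75; the boundary value is
#' kept).
#'
#' @param raw an [fnirs_raw].
#' @param threshold minimum SCI to retain a channel.
#' @inheritParams compute_sci
#' @return tibble of class `"sci_report"`: `channel_id`, `sci`, `keep`,
#'   with the threshold as attribute.
#' @export
sci_report <- function(raw, threshold = 0.75, band = c(0.7, 1.5), order = 4) {
  out <- purrr::map_dfr(names(raw$od), function(ch) {
    tibble(channel_id = ch,
           sci = compute_sci(raw, ch, band = band, order = order))
  })
  out$keep <- out$sci >= threshold
  structure(out, threshold = threshold,
            class = c("sci_report", class(out)))
}

#' Band-pass filter haemodynamic traces
#'
#' Applies a zero-phase Butterworth band-pass (default 0.02-0.18 Hz,
#' realised as a high-pass/low-pass cascade of the given order per edge) to
#' both chromophore traces of every retained channel, removing cardiac and
#' respiratory components and slow drift.
#'
#' @param hemo a [hemo_series].
#' @param band pass band in Hz (default `c(0.02, 0.18)`).
#' @param order Butterworth order per edge (default 4).
#' @return filtered [hemo_series].
#' @export
bandpass_hemo <- function(hemo, band = c(0.02, 0.18), order = 4) {
  channels <- hemo$channels
  for (ch in hemo$retained_channels) {
    m <- channels[[ch]]
    channels[[ch]] <- cbind(
      ohb = butter_bandpass_zp(m[, "ohb"], hemo$sample_rate, band, order),
      hhb = butter_bandpass_zp(m[, "hhb"], hemo$sample_rate, band, order)
    )
  }
  hemo_series(channels, hemo$sample_rate, hemo$participant_id,
              hemo$retained_channels)
}

#' Rolling-window stage averages of haemodynamic traces
#'
#' For every retained channel and stage, computes the mean dOHb and dHHb
#' as the average of fully-overlapping rolling-window means (default
#' window 120 s), exactly as for the EDA tonic level. Rejected channels do
#' not appear in the output.
#'
#' @param hemo a [hemo_series].
#' @param schedule a [stage_schedule].
#' @param window_s rolling window in seconds (default 120).
#' @return tibble: `participant`, `channel_id`, `stage`, `mean_ohb`,
#'   `mean_hhb` (micromol/L).
#' @export
hemo_stage_summary <- function(hemo, schedule, window_s = 120) {
  fs <- hemo$sample_rate
  if (!length(hemo$retained_channels)) {
    return(tibble(participant = character(), channel_id = character(),
                  stage = character(), mean_ohb = numeric(),
                  mean_hhb = numeric()))
  }
  n <- nrow(hemo$channels[[hemo$retained_channels[1]]])
  duration <- n / fs
  t_s <- (seq_len(n) - 1) / fs
  w <- round(window_s * fs)
  purrr::map_dfr(hemo$retained_channels, function(ch) {
    m <- hemo$channels[[ch]]
    purrr::pmap_dfr(schedule, function(stage, start_s, end_s) {
      if (start_s < 0 || end_s > duration + 1e-9) {
        abort(sprintf("stage '%s' [%g, %g) lies outside the recording (%.1f s)",
                      stage, start_s, end_s, duration),
              class = "stressphys_validation_error")
      }
      sel <- t_s >= start_s & t_s < end_s
      tibble(participant = hemo$participant_id, channel_id = ch,
             stage = stage,
             mean_ohb = rolling_stage_mean(m[sel, "ohb"], w),
             mean_hhb = rolling_stage_mean(m[sel, "hhb"], w))
    })
  })
}
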