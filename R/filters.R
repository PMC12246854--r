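#' Zero-phase Butterworth filtering
#'
#' Shared filtering primitives used by both the EDA and fNIRS preprocessing
#' steps. All filters are applied forward and backward (`signal::filtfilt`),
#' so they introduce no phase distortion: a symmetric pulse stays symmetric
#' and stage boundaries are not shifted in time.
#'
#' Band-pass filtering is realised as a cascade of a Butterworth high-pass at
#' the lower band edge and a Butterworth low-pass at the upper edge, each of
#' the requested order. At the very low normalised corner frequencies used in
#' haemodynamic work (0.02 Hz at a 50 Hz sampling rate is 8e-4 of Nyquist) a
#' direct high-order band-pass design is numerically unstable in double
#' precision (pole radii exceed 1), while the cascade keeps each section
#' well-conditioned and has the same nominal roll-off per edge.
#'
#' @param x numeric vector, uniformly sampled.
#' @param sample_rate sampling rate in Hz.
#' @param cutoff_hz low-pass cutoff frequency in Hz.
#' @param band_hz numeric length-2, band edges in Hz (low, high).
#' @param order Butterworth order per section (default 4).
#' @return filtered numeric vector, same length as `x`.
#' @keywords internal
#' @name zero_phase_filters
NULL

check_band <- function(f_hz, sample_rate, what = "cutoff") {
  nyq <- sample_rate / 2
  if (any(!is.finite(f_hz)) || any(f_hz <= 0) || any(f_hz >= nyq)) {
    abort(
      sprintf("%s frequency must lie strictly inside (0, Nyquist = %g Hz); got %s",
              what, nyq, paste(f_hz, collapse = ", ")),
      class = "stressphys_parameter_error"
    )
  }
  invisible(f_hz)
}

# forward-backward filtering with odd-reflection padding: extending the
# signal by its point-mirrored image at each end suppresses the start-up
# transient of the recursive filter, which would otherwise bleed filter
# settling (from zero initial state) into the data. The pad length covers
# several settling time constants of the slowest corner frequency.
filtfilt_padded <- function(flt, x, sample_rate, f_low) {
  n <- length(x)
  p <- min(n - 1, ceiling(10 * sample_rate / f_low))
  if (p < 1) return(as.numeric(signal::filtfilt(flt, x)))
  left <- 2 * x[1] - x[(p + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - p)]
  y <- signal::filtfilt(flt, c(left, x, right))
  as.numeric(y[(p + 1):(p + n)])
}

#' @rdname zero_phase_filters
#' @export
butter_lowpass_zp <- function(x, sample_rate, cutoff_hz, order = 4) {
  check_band(cutoff_hz, sample_rate)
  flt <- signal::butter(order, cutoff_hz / (sample_rate / 2), type = "low")
  filtfilt_padded(flt, x, sample_rate, cutoff_hz)
}

#' @rdname zero_phase_filters
#' @export
butter_bandpass_zp <- function(x, sample_rate, band_hz, order = 4) {
  if (length(band_hz) != 2 || band_hz[1] >= band_hz[2]) {
    abort("band_hz must be c(low, high) with low < high",
          class = "stressphys_parameter_error")
  }
  check_band(band_hz, sample_rate, what = "band edge")
  nyq <- sample_rate / 2
  hp <- signal::butter(order, band_hz[1] / nyq, type = "high")
  lp <- signal::butter(order, band_hz[2] / nyq, type = "low")
  n <- length(x)
  p <- min(n - 1, ceiling(10 * sample_rate / band_hz[1]))
  if (p < 1) {
    return(as.numeric(signal::filtfilt(lp, signal::filtfilt(hp, x))))
  }
  left <- 2 * x[1] - x[(p + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - p)]
  y <- signal::filtfilt(lp, signal::filtfilt(hp, c(left, x, right)))
  as.numeric(y[(p + 1):(p + n)])
}

#' Mean of fully-overlapping rolling-window means
#'
#' Stage-level summaries average a rolling window (default 2 min) over the
#' samples of a stage, then average the windowed means. With a step of one
#' sample this equals a centre-weighted mean of the stage samples; it
#' suppresses transient fluctuations at the stage edges relative to a plain
#' mean.
#'
#' @param x numeric vector of samples within one stage.
#' @param width window width in samples (>= 1, <= length(x)).
#' @return scalar mean of rolling means.
#' @keywords internal
rolling_stage_mean <- function(x, width) {
  if (width < 1) abort("window width must be >= 1 sample",
                       class = "stressphys_parameter_error")
  if (width > length(x)) {
    abort(sprintf("window (%d samples) longer than stage (%d samples)", width,
                  length(x)),
          class = "stressphys_parameter_error")
  }
  mean(zoo::rollmean(x, k = width, align = "center"))
}
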