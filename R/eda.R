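#' Detect detachment artifacts in an EDA series
#'
#' Wrist-worn dry-electrode recordings occasionally lose skin contact for up
#' to a few seconds, producing abrupt excursions that ordinary filtering
#' cannot correct. A sample is flagged as artifactual when two conditions
#' hold simultaneously: (1) its absolute difference from the previous
#' *valid* sample exceeds `jump_threshold` (default 0.01 microsiemens), and
#' (2) it falls outside the local acceptable range, a rolling
#' median +/- `band_k` x IQR band (default 3 x IQR over a 30 s window).
#' The second condition protects genuine fast skin-conductance responses
#' from being flagged. Because comparisons are always made against the last
#' valid sample, a whole detachment episode is flagged as one contiguous
#' segment. Values are left untouched; only the `artifact` mask is filled.
#'
#' @param series an [eda_series].
#' @param jump_threshold minimum abrupt change in microsiemens (default 0.01).
#' @param band_window_s window for the rolling acceptable-range band (s).
#' @param band_k half-width of the acceptable band in rolling IQR units.
#' @return the series with its `artifact` column filled.
#' @export
eda_detect_artifacts <- function(series, jump_threshold = 0.01,
                                 band_window_s = 30, band_k = 3) {
  if (jump_threshold <= 0) {
    abort("jump_threshold must be > 0", class = "stressphys_parameter_error")
  }
  x <- series$conductance_us
  n <- length(x)
  fs <- attr(series, "sample_rate")
  w <- max(3, round(band_window_s * fs))
  if (w %% 2 == 0) w <- w + 1
  if (w > n) w <- if (n %% 2 == 1) n else n - 1

  flag_against_band <- function(lo, hi) {
    mask <- logical(n)
    last_valid <- x[1]
    for (i in 2:n) {
      if (abs(x[i] - last_valid) > jump_threshold &&
          (x[i] < lo[i] || x[i] > hi[i])) {
        mask[i] <- TRUE
      } else {
        last_valid <- x[i]
      }
    }
    # the first sample has no predecessor; flag it only if it sits far
    # outside the band itself
    if (x[1] < 2 * lo[1] - hi[1] || x[1] > 2 * hi[1] - lo[1]) {
      mask[1] <- TRUE
    }
    mask
  }

  # two passes: the band is first estimated from the raw trace, then
  # re-estimated with first-pass flags replaced by interpolation. A single
  # pass underestimates the band's centre when several detachments fall in
  # one window (the collapsed samples drag the quantiles down and the band
  # swallows the artifact).
  mask <- logical(n)
  for (pass in 1:2) {
    xb <- x
    if (any(mask) && !all(mask)) {
      idx <- seq_len(n)
      xb[mask] <- approx(idx[!mask], x[!mask], xout = idx[mask],
                         rule = 2)$y
    }
    # running median at full resolution; the quartiles vary slowly, so they
    # are evaluated on a 1 s grid and interpolated
    med <- stats::runmed(xb, w)
    half <- w %/% 2
    pos <- unique(c(seq(1, n, by = max(1, round(fs))), n))
    q <- vapply(pos, function(i) {
      win <- xb[max(1, i - half):min(n, i + half)]
      quantile(win, c(0.25, 0.75), names = FALSE)
    }, numeric(2))
    iqr <- approx(pos, q[2, ] - q[1, ], xout = seq_len(n), rule = 2)$y
    mask <- flag_against_band(med - band_k * iqr, med + band_k * iqr)
    if (all(mask)) {
      abort("no valid anchor samples: every sample flagged as artifact",
            class = "stressphys_validation_error")
    }
  }
  eda_update(series, artifact = mask)
}

#' Repair flagged artifact segments by linear interpolation
#'
#' Each contiguous flagged segment is replaced by a straight line between
#' the nearest valid neighbours; segments touching the start or end of the
#' recording are filled by extending the nearest valid value. The artifact
#' mask is retained for provenance, so downstream summaries can report the
#' repaired fraction. Repair is idempotent and never alters unflagged
#' samples.
#'
#' @param series an [eda_series] with its mask populated (see
#'   [eda_detect_artifacts()]).
#' @return the series with flagged values replaced.
#' @export
eda_repair_artifacts <- function(series) {
  mask <- series$artifact
  if (all(mask)) {
    abort("cannot repair a series with no valid samples",
          class = "stressphys_validation_error")
  }
  if (!any(mask)) return(series)
  x <- series$conductance_us
  idx <- seq_along(x)
  fixed <- approx(idx[!mask], x[!mask], xout = idx, method = "linear",
                  rule = 2)$y
  x[mask] <- fixed[mask]
  eda_update(series, values = x)
}

#' Low-pass filter an EDA series
#'
#' Removes high-frequency noise with a zero-phase Butterworth low-pass
#' (default order 4, 0.5 Hz cutoff), leaving the slow tonic skin
#' conductance level and skin conductance responses intact.
#'
#' @param series an [eda_series] (repair first: filtering spreads artifacts).
#' @param cutoff_hz cutoff frequency, must be below Nyquist (default 0.5).
#' @param order filter order (default 4).
#' @return filtered series, same length.
#' @export
eda_lowpass <- function(series, cutoff_hz = 0.5, order = 4) {
  fs <- attr(series, "sample_rate")
  y <- butter_lowpass_zp(series$conductance_us, fs, cutoff_hz, order)
  eda_update(series, values = y)
}

#' Min-max normalise an EDA series to [0, 1]
#'
#' Scales the whole recording of one participant to the unit interval:
#' `(x - min) / (max - min)`. Normalisation is per participant over the
#' full session, so stage differences survive; a constant series maps to
#' all zeros by convention.
#'
#' @param series an [eda_series].
#' @return normalised series (dimensionless, in `[0, 1]`).
#' @export
eda_normalize <- function(series) {
  x <- series$conductance_us
  rng <- range(x)
  y <- if (diff(rng) == 0) rep(0, length(x)) else (x - rng[1]) / diff(rng)
  eda_update(series, values = y)
}

#' Tonic-level stage summaries of an EDA series
#'
#' Segments the (repaired, filtered, normalised) series by the stage
#' schedule and computes, per stage, the tonic skin conductance level as the
#' mean of fully-overlapping rolling-window means (default window 120 s,
#' step one sample).
#'
#' @param series an [eda_series], typically after
#'   [eda_repair_artifacts()], [eda_lowpass()] and [eda_normalize()].
#' @param schedule a [stage_schedule].
#' @param window_s rolling window in seconds (must not exceed the shortest
#'   stage; default 120).
#' @return tibble: `participant`, `stage`, `tonic_mean`, `n_valid_samples`,
#'   `fraction_repaired`.
#' @export
eda_stage_summary <- function(series, schedule, window_s = 120) {
  fs <- attr(series, "sample_rate")
  n <- nrow(series)
  duration <- n / fs
  purrr::pmap_dfr(schedule, function(stage, start_s, end_s) {
    if (start_s < 0 || end_s > duration + 1e-9) {
      abort(sprintf("stage '%s' [%g, %g) lies outside the recording (%.1f s)",
                    stage, start_s, end_s, duration),
            class = "stressphys_validation_error")
    }
    sel <- series$time_s >= start_s & series$time_s < end_s
    x <- series$conductance_us[sel]
    w <- round(window_s * fs)
    tibble(
      participant = attr(series, "participant_id"),
      stage = stage,
      tonic_mean = rolling_stage_mean(x, w),
      n_valid_samples = sum(!series$artifact[sel]),
      fraction_repaired = mean(series$artifact[sel])
    )
  })
}

#' Fuse stage summaries from redundant EDA devices
#'
#' When a participant wears a wristband on each arm, stage summaries are
#' computed per device and averaged, using only devices whose overall valid
#' (unrepaired) fraction reaches `min_valid_fraction`. If no device
#' qualifies, the best available device is used alone with a warning.
#'
#' @param summaries tibble of per-device stage summaries
#'   (rows from [eda_stage_summary()], with a `device` column).
#' @param min_valid_fraction minimum overall valid fraction for a device to
#'   enter the average (default 0.7).
#' @return tibble with one row per (participant, stage).
#' @export
fuse_eda_summaries <- function(summaries, min_valid_fraction = 0.7) {
  # valid fraction per device across the session: stage totals recovered
  # from n_valid and fraction_repaired
  quality <- summaries %>%
    mutate(n_total = ifelse(.data$fraction_repaired < 1,
                            .data$n_valid_samples / (1 - .data$fraction_repaired),
                            .data$n_valid_samples)) %>%
    group_by(.data$participant, .data$device) %>%
    summarise(valid = sum(.data$n_valid_samples) / sum(.data$n_total),
              .groups = "drop")
  keep <- quality[quality$valid >= min_valid_fraction, ]
  out <- purrr::map_dfr(unique(summaries$participant), function(p) {
    devs <- keep$device[keep$participant == p]
    if (!length(devs)) {
      best <- quality[quality$participant == p, ]
      devs <- best$device[which.max(best$valid)]
      warn(sprintf("participant %s: no EDA device reaches %.0f%% valid; using best device '%s'",
                   p, 100 * min_valid_fraction, devs))
    }
    summaries %>%
      filter(.data$participant == p, .data$device %in% devs) %>%
      group_by(.data$participant, .data$stage) %>%
      summarise(tonic_mean = mean(.data$tonic_mean),
                n_valid_samples = sum(.data$n_valid_samples),
                fraction_repaired = mean(.data$fraction_repaired),
                n_devices = dplyr::n_distinct(.data$device),
                .groups = "drop")
  })
  out
}
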