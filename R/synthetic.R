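#' Synthetic-cohort configuration
#'
#' Defines the generative model for a complete synthetic cohort: group
#' sizes, stage schedule, cortisol kinetics, EDA signal model and fNIRS
#' signal model, all with known ground truth. Defaults emulate the study
#' conditions: 12/11/12 participants (soothing / robotic / silence), the
#' standard stage schedule, a clear stress response in every modality, a
#' right-lateralised prefrontal dOHb increase under stress, a
#' sound-stage group contrast confined to a fixed channel set, and
#' soothing-group cortisol recovery twice as fast as the controls.
#'
#' Magnitudes are free parameters of the generator — chosen once, by a
#' design-time power analysis at the study's sample sizes — not estimates
#' from any real cohort.
#'
#' @param ... named overrides, e.g. `synth_config(cortisol = list(rise_mean
#'   = 0))` — lists are merged element-wise into the defaults.
#' @return nested list of class `"synth_config"`.
#' @export
synth_config <- function(...) {
  base <- list(
    n_per_group = c(soothing = 12, robotic = 11, silence = 12),
    sound_s = 600,
    schedule = NULL,   # optional stage_schedule overriding the default
    age = list(mean = 23, sd = 5, min = 18, max = 35),
    cortisol = list(
      baseline_log_mean = log(10),  # median 10 nmol/L
      baseline_log_sd = 0.3,
      rise_mean = 8,                # nmol/L added at the stress sample
      rise_sd = 1.5,
      recovery_rate = c(soothing = 0.11, robotic = 0.055, silence = 0.055),
      noise_log_sd = 0.05,          # ~5% assay noise, multiplicative
      sample_minutes = c(baseline = -15, stress = 0, sound = 15,
                         rest1 = 25, rest2 = 35)
    ),
    eda = list(
      sample_rate = 4,
      tonic_mean_us = 3, tonic_sd_us = 0.8,
      stage_increment_us = c(baseline = 0, anticipation = 0.3, stress = 1.0,
                             intermediate_rest = 0.4, sound = 0.2,
                             rest1 = 0.15, rest2 = 0.1),
      ramp_s = 20,                  # smooth transition between stage levels
      scr_rate_hz = 1 / 20,         # ~3 events/min
      # wrist-worn dry-electrode SCRs are strongly attenuated relative to
      # palmar sites; amplitudes are typically well below 0.1 uS
      scr_amp_us = 0.05,            # mean event amplitude (exponential)
      drift_amp_us = 0.1, drift_period_s = 900,
      noise_sd_us = 0.02,
      artifact_rate_per_min = 0.2,
      artifact_duration_s = c(1, 4),
      artifact_drop_frac = 0.95,    # detachment: reading drops to 5%
      summary_noise_sd = 0.1        # per-stage noise in the fast path (uS)
    ),
    fnirs = list(
      sample_rate = 50,
      baseline_ohb = 0.2, baseline_hhb = 0.05,   # umol/L stage levels
      stress_ohb_right = 0.5, stress_ohb_left = 0.15,
      stress_hhb_right = -0.1, stress_hhb_left = -0.03,
      sound_channels = c("Tx3-Rx2", "Tx3-Rx3", "Tx8-Rx7", "Tx6-Rx6"),
      sound_contrast_ohb = 0.3,     # added for control groups at sound_channels
      slow_osc_amp = 0.05, slow_osc_freq_hz = 0.04,
      cardiac_freq_hz = 1.1, cardiac_amp_od = 0.02,
      mayer_amp_od = 0.004, mayer_freq_hz = 0.1,
      resp_amp_od = 0.004, resp_freq_hz = 0.25,
      od_noise_sd = 0.003,
      decoupled_channels = character(0),
      decoupled_noise_sd = 0.006,
      # between-participant variation of per-channel stage levels (umol/L);
      # the participant-specific levels are what the ground truth records
      participant_sd = 0.15,
      summary_noise_sd = 0.15       # per-stage mean noise in the fast path
    )
  )
  over <- list(...)
  merge_cfg <- function(b, o) {
    for (nm in names(o)) {
      if (is.list(b[[nm]]) && is.list(o[[nm]])) {
        b[[nm]] <- merge_cfg(b[[nm]], o[[nm]])
      } else {
        b[[nm]] <- o[[nm]]
      }
    }
    b
  }
  cfg <- merge_cfg(base, over)
  if (any(cfg$n_per_group < 2)) {
    abort("n_per_group must all be >= 2", class = "stressphys_config_error")
  }
  structure(cfg, class = "synth_config")
}

#' @rdname synth_config
#' @param config a `synth_config` to null out.
#' @return `null_config()`: the same configuration with every stage and
#'   group effect set to zero (for type-I-error calibration).
#' @export
null_config <- function(config = synth_config()) {
  config$cortisol$rise_mean <- 0
  config$cortisol$rise_sd <- 0
  config$cortisol$recovery_rate[] <- 0
  config$eda$stage_increment_us[] <- 0
  config$fnirs$stress_ohb_right <- 0
  config$fnirs$stress_ohb_left <- 0
  config$fnirs$stress_hhb_right <- 0
  config$fnirs$stress_hhb_left <- 0
  config$fnirs$sound_contrast_ohb <- 0
  config
}

#' Cohort roster: participant ids, groups, ages
#' @keywords internal
synth_roster <- function(config) {
  groups <- rep(names(config$n_per_group), config$n_per_group)
  n <- length(groups)
  age <- round(stats::rnorm(n, config$age$mean, config$age$sd))
  age <- pmin(pmax(age, config$age$min), config$age$max)
  tibble(participant = sprintf("p%02d", seq_len(n)), group = groups,
         age = age)
}

#' Simulate a cortisol panel
#'
#' Per participant: a lognormal baseline level, an additive stress rise
#' sampled at the stress time point, first-order exponential recovery at
#' the participant's group rate constant, and multiplicative lognormal
#' assay noise on every sample.
#'
#' @param config a [synth_config].
#' @param roster optional roster tibble (defaults to a fresh one).
#' @return list: `panel` (a [cortisol_panel][read_cortisol_csv]),
#'   `truth` (per-participant baseline, rise and rate constant).
#' @export
simulate_cortisol_panel <- function(config = synth_config(), roster = NULL) {
  cc <- config$cortisol
  if (is.null(roster)) roster <- synth_roster(config)
  n <- nrow(roster)
  B <- exp(stats::rnorm(n, cc$baseline_log_mean, cc$baseline_log_sd))
  A <- pmax(stats::rnorm(n, cc$rise_mean, cc$rise_sd), 0)
  k <- unname(cc$recovery_rate[roster$group])
  mins <- cc$sample_minutes
  rows <- purrr::map_dfr(seq_len(n), function(i) {
    conc <- vapply(names(mins), function(stg) {
      m <- mins[[stg]]
      mu <- if (m < 0) B[i] else B[i] + A[i] * exp(-k[i] * m)
      mu * exp(stats::rnorm(1, 0, cc$noise_log_sd))
    }, numeric(1))
    tibble(participant = roster$participant[i], group = roster$group[i],
           stage = names(mins), nmol_per_l = unname(conc))
  })
  list(panel = cortisol_panel(rows),
       truth = tibble(participant = roster$participant, baseline = B,
                      rise = A, rate = k))
}

# true haemodynamic stage mean for one channel/stage/group
true_hemo_mean <- function(fc, chrom, channel_id, hemisphere, stage, group) {
  base <- if (chrom == "ohb") fc$baseline_ohb else fc$baseline_hhb
  eff <- 0
  if (stage == "stress") {
    eff <- eff + if (chrom == "ohb") {
      if (hemisphere == "right") fc$stress_ohb_right else fc$stress_ohb_left
    } else {
      if (hemisphere == "right") fc$stress_hhb_right else fc$stress_hhb_left
    }
  }
  if (stage == "sound" && chrom == "ohb" && group != "soothing" &&
      channel_id %in% fc$sound_channels) {
    eff <- eff + fc$sound_contrast_ohb
  }
  base + eff
}

#' Simulate cohort stage summaries directly (fast path)
#'
#' Draws per-participant stage summaries straight from the ground-truth
#' effect model, bypassing signal synthesis: cortisol panel from the
#' kinetic model, EDA tonic stage means from the stage-increment model,
#' and haemodynamic stage means from the channel/stage/group effect map,
#' each with participant-level noise. This is the path used for
#' calibration and power studies over many replicate cohorts, where
#' synthesising 50 Hz signals would add nothing but runtime; signal-level
#' fidelity is exercised separately by the full generator.
#'
#' @param config a [synth_config].
#' @param montage an [fnirs_montage][read_montage].
#' @return list: `roster`, `cortisol` (panel), `eda` (tonic stage
#'   summaries), `hemo` (channel stage summaries), `truth`.
#' @export
simulate_cohort_summaries <- function(config = synth_config(),
                                      montage = default_montage()) {
  roster <- synth_roster(config)
  cort <- simulate_cortisol_panel(config, roster)
  ec <- config$eda
  stages <- cortisol_stages()
  tonic0 <- stats::rnorm(nrow(roster), ec$tonic_mean_us, ec$tonic_sd_us)
  eda <- tidyr::expand_grid(i = seq_len(nrow(roster)), stage = stages) %>%
    mutate(participant = roster$participant[.data$i],
           tonic_mean = tonic0[.data$i] +
             unname(ec$stage_increment_us[.data$stage]) +
             stats::rnorm(dplyr::n(), 0, ec$summary_noise_sd),
           n_valid_samples = NA_integer_,
           fraction_repaired = 0) %>%
    select("participant", "stage", "tonic_mean", "n_valid_samples",
           "fraction_repaired")
  fc <- config$fnirs
  ch <- montage$channels
  hemo <- tidyr::expand_grid(i = seq_len(nrow(roster)),
                             ci = seq_len(nrow(ch)),
                             stage = c("baseline", "stress", "sound")) %>%
    mutate(
      participant = roster$participant[.data$i],
      group = roster$group[.data$i],
      channel_id = ch$channel_id[.data$ci],
      hemisphere = ch$hemisphere[.data$ci]
    )
  is_stress <- hemo$stage == "stress"
  is_right <- hemo$hemisphere == "right"
  sound_hit <- hemo$stage == "sound" & hemo$group != "soothing" &
    hemo$channel_id %in% fc$sound_channels
  hemo$true_ohb <- fc$baseline_ohb +
    is_stress * ifelse(is_right, fc$stress_ohb_right, fc$stress_ohb_left) +
    sound_hit * fc$sound_contrast_ohb
  hemo$true_hhb <- fc$baseline_hhb +
    is_stress * ifelse(is_right, fc$stress_hhb_right, fc$stress_hhb_left)
  hemo <- hemo %>%
    mutate(mean_ohb = .data$true_ohb +
             stats::rnorm(dplyr::n(), 0, fc$summary_noise_sd),
           mean_hhb = .data$true_hhb +
             stats::rnorm(dplyr::n(), 0, fc$summary_noise_sd)) %>%
    select("participant", "channel_id", "stage", "mean_ohb", "mean_hhb")
  list(roster = roster, cortisol = cort$panel, eda = eda, hemo = hemo,
       truth = list(cortisol = cort$truth,
                    eda_tonic = tibble(participant = roster$participant,
                                       tonic = tonic0)))
}

# smooth stage-level step function sampled at t_s (linear ramps at edges)
stage_level_trace <- function(t_s, schedule, levels, ramp_s) {
  knots_t <- numeric(0); knots_v <- numeric(0)
  for (i in seq_len(nrow(schedule))) {
    s <- schedule$start_s[i]; e <- schedule$end_s[i]
    v <- levels[[schedule$stage[i]]]
    half <- min(ramp_s / 2, (e - s) / 2)
    knots_t <- c(knots_t, s + half, e - half)
    knots_v <- c(knots_v, v, v)
  }
  approx(knots_t, knots_v, xout = t_s, rule = 2)$y
}

# bi-exponential SCR kernel (1 s rise, 4 s decay), unit peak
scr_kernel <- function(fs, dur_s = 20) {
  t <- seq(0, dur_s, by = 1 / fs)
  k <- exp(-t / 4) - exp(-t / 1)
  k / max(k)
}

#' Simulate one participant's EDA recording
#'
#' Builds a clean skin-conductance trace — tonic level with smooth
#' stage-dependent increments, slow drift, phasic skin conductance
#' responses with exponentially distributed inter-event intervals and
#' bi-exponential shapes, and white measurement noise — then injects
#' detachment artifacts (the reading collapses toward zero for one to a
#' few seconds). Artifact segments avoid stage-boundary samples so stage
#' summaries always have valid anchors. The clean trace and the injected
#' segment indices are returned as ground truth.
#'
#' @param config a [synth_config].
#' @param schedule a [stage_schedule].
#' @param participant,start_time metadata for the series.
#' @return list: `series` (an [eda_series] with artifacts in the values
#'   but an empty mask — detection is the pipeline's job), `clean`
#'   (numeric ground-truth trace), `artifact_mask` (logical ground truth).
#' @export
simulate_eda_series <- function(config = synth_config(),
                                schedule = default_schedule(config$sound_s),
                                participant = "p01", start_time = 1.7e9) {
  ec <- config$eda
  fs <- ec$sample_rate
  dur <- schedule_duration(schedule)
  n <- round(dur * fs)
  t_s <- (seq_len(n) - 1) / fs
  tonic0 <- stats::rnorm(1, ec$tonic_mean_us, ec$tonic_sd_us)
  levels <- as.list(tonic0 + ec$stage_increment_us[schedule$stage])
  names(levels) <- schedule$stage
  tonic <- stage_level_trace(t_s, schedule, levels, ec$ramp_s)
  drift <- ec$drift_amp_us * sin(2 * pi * t_s / ec$drift_period_s +
                                   stats::runif(1, 0, 2 * pi))
  phasic <- numeric(n)
  if (ec$scr_rate_hz > 0) {
    k <- scr_kernel(fs)
    t_ev <- 0
    repeat {
      t_ev <- t_ev + stats::rexp(1, ec$scr_rate_hz)
      if (t_ev >= dur) break
      i0 <- min(round(t_ev * fs) + 1, n)
      amp <- stats::rexp(1, 1 / ec$scr_amp_us)
      idx <- i0:min(n, i0 + length(k) - 1)
      phasic[idx] <- phasic[idx] + amp * k[seq_along(idx)]
    }
  }
  clean <- pmax(tonic + drift + phasic +
                  stats::rnorm(n, 0, ec$noise_sd_us), 0.01)
  # inject detachment artifacts, clear of stage boundaries
  mask <- logical(n)
  values <- clean
  n_art <- stats::rpois(1, ec$artifact_rate_per_min * dur / 60)
  boundary_idx <- unique(c(1, round(schedule$start_s * fs) + 1,
                           round(schedule$end_s * fs), n))
  guard <- 2 * fs   # samples around boundaries kept artifact-free
  if (n_art > 0) {
    for (a in seq_len(n_art)) {
      for (try in 1:50) {
        len <- round(stats::runif(1, ec$artifact_duration_s[1],
                                  ec$artifact_duration_s[2]) * fs)
        i0 <- sample.int(n - len - 1, 1) + 1
        idx <- i0:(i0 + len - 1)
        near_boundary <- any(vapply(boundary_idx, function(b) {
          any(abs(idx - b) <= guard)
        }, logical(1)))
        if (!near_boundary && !any(mask[idx])) {
          mask[idx] <- TRUE
          values[idx] <- clean[idx] * (1 - ec$artifact_drop_frac)
          break
        }
      }
    }
  }
  series <- eda_series(values, fs, start_time, participant,
                       events = tibble(time_s = schedule$start_s,
                                       label = schedule$stage))
  list(series = series, clean = clean, artifact_mask = mask)
}

#' Simulate one participant's raw fNIRS recording
#'
#' True per-channel haemoglobin traces (stage-level steps from the effect
#' map plus a slow in-band oscillation) are pushed through the forward
#' Beer-Lambert model — the same extinction table and DPF as the analysis
#' inverse — then physiological nuisance components are added in
#' optical-density space: a cardiac pulsation shared by both wavelengths
#' (scaled by the channel's coupling quality), Mayer waves, respiration
#' and white noise. Channels listed in `config$fnirs$decoupled_channels`
#' get zero cardiac coupling and extra independent noise, so they fail the
#' scalp-coupling-index screen by construction.
#'
#' @param config a [synth_config].
#' @param schedule a [stage_schedule].
#' @param montage an [fnirs_montage][read_montage].
#' @param participant,group,age_years participant metadata.
#' @param start_time recording start (epoch seconds).
#' @return list: `raw` (an [fnirs_raw]), `true_means` (tibble of true
#'   stage-mean dOHb/dHHb per channel), `decoupled` (channel ids).
#' @export
simulate_fnirs_raw <- function(config = synth_config(),
                               schedule = default_schedule(config$sound_s),
                               montage = default_montage(),
                               participant = "p01", group = "silence",
                               age_years = 23, start_time = 1.7e9) {
  fc <- config$fnirs
  fs <- fc$sample_rate
  dur <- schedule_duration(schedule)
  n <- round(dur * fs)
  t_s <- (seq_len(n) - 1) / fs
  wl <- montage$wavelengths_nm
  cardiac_phase <- stats::runif(1, 0, 2 * pi)
  cardiac <- sin(2 * pi * fc$cardiac_freq_hz * t_s + cardiac_phase)
  mayer <- fc$mayer_amp_od * sin(2 * pi * fc$mayer_freq_hz * t_s +
                                   stats::runif(1, 0, 2 * pi))
  resp <- fc$resp_amp_od * sin(2 * pi * fc$resp_freq_hz * t_s +
                                 stats::runif(1, 0, 2 * pi))
  od <- list()
  true_means <- list()
  for (ci in seq_len(nrow(montage$channels))) {
    ch <- montage$channels$channel_id[ci]
    hemi <- montage$channels$hemisphere[ci]
    d <- montage$channels$distance_cm[ci]
    lv_o <- lv_h <- list()
    for (stg in schedule$stage) {
      lv_o[[stg]] <- true_hemo_mean(fc, "ohb", ch, hemi, stg, group) +
        stats::rnorm(1, 0, fc$participant_sd)
      lv_h[[stg]] <- true_hemo_mean(fc, "hhb", ch, hemi, stg, group) +
        stats::rnorm(1, 0, fc$participant_sd)
    }
    osc_phase <- stats::runif(1, 0, 2 * pi)
    osc <- fc$slow_osc_amp * sin(2 * pi * fc$slow_osc_freq_hz * t_s +
                                   osc_phase)
    conc <- cbind(
      ohb = stage_level_trace(t_s, schedule, lv_o, ramp_s = 20) + osc,
      hhb = stage_level_trace(t_s, schedule, lv_h, ramp_s = 20) - 0.3 * osc
    )
    m <- hemo_to_od(conc, d, age_years, wl)
    decoupled <- ch %in% fc$decoupled_channels
    if (decoupled) {
      # a detached optode sees no tissue: independent sensor noise only
      noise_sd <- fc$od_noise_sd + fc$decoupled_noise_sd
      for (j in 1:2) m[, j] <- stats::rnorm(n, 0, noise_sd)
    } else {
      for (j in 1:2) {
        m[, j] <- m[, j] + fc$cardiac_amp_od * cardiac + mayer + resp +
          stats::rnorm(n, 0, fc$od_noise_sd)
      }
    }
    od[[ch]] <- m
    true_means[[ch]] <- tibble(channel_id = ch, stage = schedule$stage,
                               true_ohb = unlist(lv_o, use.names = FALSE),
                               true_hhb = unlist(lv_h, use.names = FALSE))
  }
  raw <- fnirs_raw(od, fs, montage, age_years, participant, start_time)
  list(raw = raw, true_means = bind_rows(true_means),
       decoupled = fc$decoupled_channels)
}

#' Generate a complete synthetic cohort on disk
#'
#' Writes a cohort directory in the pipeline's input layout —
#' `participants.csv` (id, group, age), `schedule.yaml`, `cortisol.csv`,
#' `eda/<id>_left.csv` and `_right.csv` with companion `_tags.txt` files,
#' `fnirs/<id>.edf` — together with a `manifest.json` and an in-memory
#' ground-truth object. Deterministic given `seed`.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [synth_config].
#' @param seed integer seed.
#' @param modalities subset of `c("cortisol", "eda", "fnirs")` to
#'   synthesise (signal modalities dominate runtime; cortisol-only cohorts
#'   are cheap).
#' @param montage an [fnirs_montage][read_montage].
#' @param start_time recording start epoch (s).
#' @return invisible list: `dir`, `manifest`, `ground_truth`.
#' @export
generate_cohort <- function(out_dir, config = synth_config(), seed = 1,
                            modalities = c("cortisol", "eda", "fnirs"),
                            montage = default_montage(),
                            start_time = 1.7e9) {
  set.seed(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  schedule <- config$schedule %||% default_schedule(config$sound_s)
  roster <- synth_roster(config)
  files <- character(0)
  gt <- list(roster = roster, schedule = schedule, seed = seed,
             config = config)

  readr::write_csv(roster, file.path(out_dir, "participants.csv"))
  write_schedule(schedule, file.path(out_dir, "schedule.yaml"))
  files <- c(files, "participants.csv", "schedule.yaml")

  if ("cortisol" %in% modalities) {
    cort <- simulate_cortisol_panel(config, roster)
    write_cortisol_csv(cort$panel, file.path(out_dir, "cortisol.csv"))
    gt$cortisol <- cort$truth
    files <- c(files, "cortisol.csv")
  }
  if ("eda" %in% modalities) {
    dir.create(file.path(out_dir, "eda"), showWarnings = FALSE)
    gt$eda <- list()
    for (i in seq_len(nrow(roster))) {
      p <- roster$participant[i]
      for (side in c("left", "right")) {
        sim <- simulate_eda_series(config, schedule, p, start_time)
        base <- sprintf("eda/%s_%s", p, side)
        write_eda_csv(sim$series, file.path(out_dir, paste0(base, ".csv")),
                      tags_path = file.path(out_dir, paste0(base, "_tags.txt")))
        gt$eda[[paste(p, side, sep = "_")]] <-
          list(clean = sim$clean, artifact_mask = sim$artifact_mask)
        files <- c(files, paste0(base, ".csv"), paste0(base, "_tags.txt"))
      }
    }
  }
  if ("fnirs" %in% modalities) {
    dir.create(file.path(out_dir, "fnirs"), showWarnings = FALSE)
    gt$fnirs <- list()
    for (i in seq_len(nrow(roster))) {
      p <- roster$participant[i]
      sim <- simulate_fnirs_raw(config, schedule, montage, p,
                                roster$group[i], roster$age[i], start_time)
      f <- sprintf("fnirs/%s.edf", p)
      write_fnirs_edf(sim$raw, file.path(out_dir, f))
      gt$fnirs[[p]] <- list(true_means = sim$true_means,
                            decoupled = sim$decoupled)
      files <- c(files, f)
    }
  }
  manifest <- list(seed = seed, modalities = modalities, files = files,
                   n_participants = nrow(roster),
                   groups = as.list(table(roster$group)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(dir = out_dir, manifest = manifest, ground_truth = gt))
}

#' @rdname generate_cohort
#' @export
generate_null_cohort <- function(out_dir, config = synth_config(), seed = 1,
                                 modalities = "cortisol",
                                 montage = default_montage(),
                                 start_time = 1.7e9) {
  generate_cohort(out_dir, null_config(config), seed, modalities, montage,
                  start_time)
}
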