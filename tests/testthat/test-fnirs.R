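test_that("DPF is positive, age-increasing and wavelength-dependent", {
  grid <- expand.grid(age = c(18, 23, 30, 35, 60), wl = c(700, 760, 808, 850))
  vals <- compute_dpf(grid$age, grid$wl)
  expect_true(all(vals > 0))
  # monotone in age at fixed wavelength over the study's age range
  for (wl in c(760, 850)) {
    ages <- 18:35
    d <- compute_dpf(ages, wl)
    expect_true(all(diff(d) > 0))
  }
  # the two device wavelengths give distinct factors at the same age
  expect_false(isTRUE(all.equal(compute_dpf(23, 760), compute_dpf(23, 850))))
  expect_error(compute_dpf(0, 760), class = "stressphys_parameter_error")
  expect_error(compute_dpf(25, 500), class = "stressphys_parameter_error")
})

test_that("Beer-Lambert inversion is exact on forward-generated data", {
  m <- default_montage()
  set.seed(4)
  # zero OD maps to zero concentrations
  z <- matrix(0, 50, 2, dimnames = list(NULL, c("760", "850")))
  raw0 <- fnirs_raw(list(`Tx1-Rx1` = z), 50, m, 23)
  h0 <- beer_lambert(raw0)
  expect_equal(max(abs(h0$channels[["Tx1-Rx1"]])), 0)

  # forward then inverse recovers concentrations to 1e-6 relative
  conc <- cbind(ohb = rnorm(500, 0, 0.5), hhb = rnorm(500, 0, 0.3))
  od <- hemo_to_od(conc, 3, 23)
  raw <- fnirs_raw(list(`Tx1-Rx1` = od), 50, m, 23)
  rec <- beer_lambert(raw)$channels[["Tx1-Rx1"]]
  expect_lt(max(abs(rec - conc)) / max(abs(conc)), 1e-6)

  # doubling the source-detector distance halves recovered concentrations
  m2 <- m
  m2$channels$distance_cm <- 6
  raw2 <- fnirs_raw(list(`Tx1-Rx1` = od), 50, m2, 23)
  rec2 <- beer_lambert(raw2)$channels[["Tx1-Rx1"]]
  expect_equal(rec2, rec / 2, tolerance = 1e-9)

  # a singular extinction matrix is a numerical error
  singular <- matrix(c(1, 1, 2, 2), 2, 2,
                     dimnames = list(c("760", "850"), c("ohb", "hhb")))
  expect_error(beer_lambert(raw, extinction = singular),
               class = "stressphys_numeric_error")
})

test_that("SCI separates shared-cardiac channels from decoupled noise", {
  m <- default_montage()
  n <- 30000; fs <- 50
  t <- (seq_len(n) - 1) / fs
  set.seed(10)
  # identical traces: perfect self-correlation
  x <- sin(2 * pi * 1.1 * t) + rnorm(n, 0, 0.1)
  od_same <- cbind(x, x); colnames(od_same) <- c("760", "850")
  raw <- fnirs_raw(list(`Tx1-Rx1` = od_same), fs, m, 23)
  expect_equal(compute_sci(raw, "Tx1-Rx1"), 1, tolerance = 1e-9)

  # independent white noise: near-zero correlation at this length
  od_noise <- cbind(rnorm(n), rnorm(n)); colnames(od_noise) <- c("760", "850")
  raw_n <- fnirs_raw(list(`Tx1-Rx1` = od_noise), fs, m, 23)
  expect_lt(abs(compute_sci(raw_n, "Tx1-Rx1")), 0.1)

  # shared cardiac + modest independent noise: high coupling
  card <- sin(2 * pi * 1.1 * t)
  od_card <- cbind(card + rnorm(n, 0, 0.15), card + rnorm(n, 0, 0.15))
  colnames(od_card) <- c("760", "850")
  raw_c <- fnirs_raw(list(`Tx1-Rx1` = od_card), fs, m, 23)
  expect_gt(compute_sci(raw_c, "Tx1-Rx1"), 0.9)

  # symmetric in the two wavelengths, invariant to positive rescaling
  od_swap <- od_card[, 2:1]; colnames(od_swap) <- c("760", "850")
  raw_s <- fnirs_raw(list(`Tx1-Rx1` = od_swap), fs, m, 23)
  expect_equal(compute_sci(raw_s, "Tx1-Rx1"), compute_sci(raw_c, "Tx1-Rx1"),
               tolerance = 1e-12)
  od_scaled <- od_card; od_scaled[, 1] <- od_scaled[, 1] * 7.3
  raw_sc <- fnirs_raw(list(`Tx1-Rx1` = od_scaled), fs, m, 23)
  expect_equal(compute_sci(raw_sc, "Tx1-Rx1"), compute_sci(raw_c, "Tx1-Rx1"),
               tolerance = 1e-9)

  # zero-variance trace: SCI defined as 0
  od_flat <- cbind(rep(0, n), rnorm(n)); colnames(od_flat) <- c("760", "850")
  raw_f <- fnirs_raw(list(`Tx1-Rx1` = od_flat), fs, m, 23)
  expect_equal(compute_sci(raw_f, "Tx1-Rx1"), 0)
})

test_that("channel rejection keeps the 0.75 boundary and is reproducible", {
  m <- default_montage()
  set.seed(12)
  cfg <- synth_config(fnirs = list(
    decoupled_channels = c("Tx2-Rx2", "Tx7-Rx5", "Tx9-Rx6")))
  sim <- simulate_fnirs_raw(cfg, short_schedule(), m)
  rep1 <- sci_report(sim$raw)
  expect_setequal(rep1$channel_id[!rep1$keep], cfg$fnirs$decoupled_channels)
  # pure function of the recording: identical on re-run
  rep2 <- sci_report(sim$raw)
  expect_identical(rep1$keep, rep2$keep)
  expect_identical(rep1$sci, rep2$sci)
  # boundary: keep exactly at threshold
  expect_true(all(rep1$keep == (rep1$sci >= 0.75)))

  # an all-well-coupled montage keeps 24/24
  set.seed(13)
  sim2 <- simulate_fnirs_raw(synth_config(), short_schedule(), m)
  expect_equal(sum(sci_report(sim2$raw)$keep), 24)
})

test_that("haemodynamic band-pass contracts hold and filters are zero-phase", {
  fs <- 50
  t <- seq(0, 600, by = 1 / fs)
  mid <- 10000:20000
  # 1.1 Hz cardiac tone attenuated by >= 40 dB
  y_card <- butter_bandpass_zp(sin(2 * pi * 1.1 * t), fs, c(0.02, 0.18))
  expect_lt(20 * log10(max(abs(y_card[mid]))), -40)
  # 0.1 Hz passes within 3 dB
  y_mid <- butter_bandpass_zp(sin(2 * pi * 0.1 * t), fs, c(0.02, 0.18))
  expect_gt(20 * log10(max(abs(y_mid[mid]))), -3)
  # zero in, zero out
  expect_equal(butter_bandpass_zp(rep(0, 1000), fs, c(0.02, 0.18)),
               rep(0, 1000))
  # zero phase: a symmetric pulse keeps its peak sample
  pulse <- exp(-((seq_len(4001) - 2001) / 150)^2)
  out <- butter_bandpass_zp(pulse, fs, c(0.02, 0.18))
  expect_equal(which.max(out), 2001)
  out_lp <- butter_lowpass_zp(pulse, fs, 0.5)
  expect_equal(which.max(out_lp), 2001)

  expect_error(butter_bandpass_zp(t, fs, c(0.18, 0.02)),
               class = "stressphys_parameter_error")
  expect_error(butter_bandpass_zp(t, fs, c(0.02, 30)),
               class = "stressphys_parameter_error")
})

test_that("stage averages cover retained channels only and recover constants", {
  m <- default_montage()
  sched <- stage_schedule(tibble::tibble(
    stage = c("baseline", "stress"), start_s = c(0, 60), end_s = c(60, 120)))
  n <- 120 * 50
  mk <- function(v) {
    x <- cbind(ohb = rep(v, n), hhb = rep(-v, n))
    x
  }
  h <- hemo_series(list(`Tx1-Rx1` = mk(0.4), `Tx6-Rx5` = mk(0.1)), 50,
                   "p01", retained_channels = "Tx1-Rx1")
  out <- hemo_stage_summary(h, sched, window_s = 20)
  expect_setequal(unique(out$channel_id), "Tx1-Rx1")
  expect_equal(out$mean_ohb, c(0.4, 0.4))
  expect_equal(out$mean_hhb, c(-0.4, -0.4))
})

test_that("a right-lateralised stress effect appears in right-channel stage means", {
  set.seed(31)
  m <- default_montage()
  sched <- short_schedule()
  sim <- simulate_fnirs_raw(synth_config(), sched, m)
  hemo <- beer_lambert(sim$raw)
  summ <- hemo_stage_summary(hemo, sched, window_s = 20)
  right <- m$channels$channel_id[m$channels$hemisphere == "right"]
  d <- summ |>
    dplyr::filter(.data$channel_id %in% right) |>
    tidyr::pivot_wider(id_cols = "channel_id", names_from = "stage",
                       values_from = "mean_ohb")
  # the +0.5 umol/L injected effect dominates the per-participant level
  # variation on average, and for nearly every individual channel
  expect_gt(mean(d$stress - d$baseline), 0.2)
  expect_gte(mean(d$stress > d$baseline), 10 / 12)
})
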