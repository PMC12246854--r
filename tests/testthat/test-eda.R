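test_that("artifact detection flags abrupt out-of-band excursions only", {
  # constant series: no differences, no flags
  s <- eda_series(rep(2, 600), 4)
  expect_false(any(eda_detect_artifacts(s)$artifact))

  # a slow ramp below the jump threshold is never flagged
  ramp <- eda_series(2 + 0.005 * seq_len(600), 4)
  expect_false(any(eda_detect_artifacts(ramp, jump_threshold = 0.01)$artifact))

  # an instantaneous 1 uS drop lasting 3 s is flagged exactly
  set.seed(42)
  x <- 3 + 0.01 * sin(seq_len(1200) / 40) + rnorm(1200, 0, 0.005)
  inj <- 501:512   # 3 s at 4 Hz
  x[inj] <- x[inj] - 1
  det <- eda_detect_artifacts(eda_series(x, 4))
  expect_equal(which(det$artifact), inj)
})

test_that("a series with no valid samples cannot be repaired", {
  s <- eda_series(rep(2, 20), 4, artifact = rep(TRUE, 20))
  expect_error(eda_repair_artifacts(s), "no valid",
               class = "stressphys_validation_error")
})

test_that("repair interpolates interior segments and extends at edges", {
  v <- c(2.0, 9, 9, 9, 9, 3.0, 3.2, 3.1)
  mask <- c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  s <- eda_series(v, 4, artifact = mask)
  r <- eda_repair_artifacts(s)
  expect_equal(r$conductance_us[2:5], c(2.2, 2.4, 2.6, 2.8))
  # unflagged samples are untouched and the mask is retained
  expect_equal(r$conductance_us[!mask], v[!mask])
  expect_equal(r$artifact, mask)

  # leading artifact: first valid value propagated backward
  s2 <- eda_series(c(9, 9, 2.0, 2.1), 4,
                   artifact = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(eda_repair_artifacts(s2)$conductance_us[1:2], c(2, 2))

  # repair is idempotent
  r2 <- eda_repair_artifacts(r)
  expect_identical(r2$conductance_us, r$conductance_us)
})

test_that("repair halves the error against the clean ground truth", {
  set.seed(9)
  cfg <- synth_config()
  sched <- short_schedule()
  for (i in 1:5) {
    sim <- simulate_eda_series(cfg, sched)
    det <- eda_detect_artifacts(sim$series)
    rep <- eda_repair_artifacts(det)
    if (!any(sim$artifact_mask)) next
    rmse_pre <- sqrt(mean((sim$series$conductance_us - sim$clean)^2))
    rmse_post <- sqrt(mean((rep$conductance_us - sim$clean)^2))
    expect_lt(rmse_post, 0.5 * rmse_pre)
  }
})

test_that("low-pass filtering is DC-preserving, linear and length-stable", {
  s <- eda_series(rep(1.5, 400), 4)
  out <- eda_lowpass(s)
  expect_equal(nrow(out), 400)
  expect_lt(max(abs(out$conductance_us - 1.5)), 1e-9)

  # cutoff at or above Nyquist is a parameter error
  expect_error(eda_lowpass(s, cutoff_hz = 2), "Nyquist",
               class = "stressphys_parameter_error")

  # linearity: filter(a + b) = filter(a) + filter(b)
  set.seed(1)
  a <- rnorm(400); b <- rnorm(400)
  fa <- butter_lowpass_zp(a, 4, 0.5)
  fb <- butter_lowpass_zp(b, 4, 0.5)
  fab <- butter_lowpass_zp(a + b, 4, 0.5)
  expect_lt(max(abs(fab - (fa + fb))), 1e-9)
})

test_that("min-max normalisation maps to [0,1] with the degenerate rule", {
  s <- eda_series(c(2, 4, 6), 4)
  expect_equal(eda_normalize(s)$conductance_us, c(0, 0.5, 1))
  const <- eda_series(rep(3, 10), 4)
  expect_equal(eda_normalize(const)$conductance_us, rep(0, 10))
  set.seed(2)
  r <- eda_normalize(eda_series(rnorm(100, 3), 4))$conductance_us
  expect_equal(range(r), c(0, 1))
})

test_that("stage summaries average rolling-window means per stage", {
  sched <- stage_schedule(tibble::tibble(
    stage = c("baseline", "stress"), start_s = c(0, 60), end_s = c(60, 120)))
  v <- c(rep(0.3, 240), rep(0.8, 240))
  s <- eda_series(v, 4, participant_id = "p09")
  out <- eda_stage_summary(s, sched, window_s = 20)
  expect_equal(out$stage, c("baseline", "stress"))
  expect_equal(out$tonic_mean, c(0.3, 0.8))
  expect_equal(out$participant, c("p09", "p09"))
  expect_equal(out$fraction_repaired, c(0, 0))

  # a window longer than the stage is a parameter error
  expect_error(eda_stage_summary(s, sched, window_s = 120),
               class = "stressphys_parameter_error")
  # a stage outside the recording is named
  bad <- stage_schedule(tibble::tibble(stage = "late", start_s = 100,
                                       end_s = 300))
  expect_error(eda_stage_summary(s, bad, window_s = 20), "late",
               class = "stressphys_validation_error")
})

test_that("stress raises the tonic level above baseline in every simulated participant", {
  set.seed(21)
  cfg <- synth_config()
  sched <- short_schedule()
  for (i in 1:4) {
    sim <- simulate_eda_series(cfg, sched)
    s <- sim$series |>
      eda_detect_artifacts() |>
      eda_repair_artifacts() |>
      eda_lowpass() |>
      eda_normalize()
    out <- eda_stage_summary(s, sched, window_s = 20)
    expect_gt(out$tonic_mean[out$stage == "stress"],
              out$tonic_mean[out$stage == "baseline"])
  }
})

test_that("device fusion averages only devices above the valid-fraction gate", {
  summ <- dplyr::bind_rows(
    tibble::tibble(participant = "p01", stage = c("baseline", "stress"),
                   tonic_mean = c(0.2, 0.6), n_valid_samples = c(100, 100),
                   fraction_repaired = 0, device = "left"),
    tibble::tibble(participant = "p01", stage = c("baseline", "stress"),
                   tonic_mean = c(0.4, 0.8), n_valid_samples = c(10, 10),
                   fraction_repaired = 0.9, device = "right")
  )
  fused <- fuse_eda_summaries(summ, min_valid_fraction = 0.7)
  # right device (10% valid) is dropped; left used alone
  expect_equal(fused$tonic_mean[fused$stage == "baseline"], 0.2)
  expect_equal(unique(fused$n_devices), 1)

  both <- summ
  both$fraction_repaired <- 0
  both$n_valid_samples <- 100
  fused2 <- fuse_eda_summaries(both, min_valid_fraction = 0.7)
  expect_equal(fused2$tonic_mean[fused2$stage == "baseline"], 0.3)
  expect_equal(unique(fused2$n_devices), 2)
})
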