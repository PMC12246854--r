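test_that("the default cohort reproduces the study's structure", {
  d <- withr::local_tempdir()
  out <- generate_cohort(file.path(d, "c"), synth_config(), seed = 1,
                         modalities = "cortisol")
  roster <- out$ground_truth$roster
  expect_equal(nrow(roster), 35)
  expect_equal(unname(table(roster$group)[c("soothing", "robotic",
                                            "silence")]),
               c(12, 11, 12), ignore_attr = TRUE)
  panel <- read_cortisol_csv(file.path(d, "c", "cortisol.csv"))
  expect_equal(nrow(panel), 35 * 5)
  expect_setequal(unique(panel$stage),
                  c("baseline", "stress", "sound", "rest1", "rest2"))
  expect_true(all(panel$nmol_per_l >= 0))
  expect_true(file.exists(file.path(d, "c", "manifest.json")))
})

test_that("generation is deterministic under a fixed seed", {
  d <- withr::local_tempdir()
  cfg <- small_cohort_config(schedule = short_schedule())
  generate_cohort(file.path(d, "a"), cfg, seed = 7,
                  modalities = c("cortisol", "eda"))
  generate_cohort(file.path(d, "b"), cfg, seed = 7,
                  modalities = c("cortisol", "eda"))
  for (f in c("cortisol.csv", "participants.csv", "eda/p01_left.csv")) {
    expect_identical(readLines(file.path(d, "a", f)),
                     readLines(file.path(d, "b", f)))
  }
  # a different seed changes the data
  generate_cohort(file.path(d, "c"), cfg, seed = 8, modalities = "cortisol")
  expect_false(identical(readLines(file.path(d, "a", "cortisol.csv")),
                         readLines(file.path(d, "c", "cortisol.csv"))))
})

test_that("a noise-free configuration is recovered exactly by the analysis path", {
  set.seed(50)
  m <- default_montage()
  sched <- short_schedule()
  cfg <- synth_config(fnirs = list(
    cardiac_amp_od = 0, mayer_amp_od = 0, resp_amp_od = 0, od_noise_sd = 0,
    slow_osc_amp = 0, participant_sd = 0))
  sim <- simulate_fnirs_raw(cfg, sched, m)
  hemo <- beer_lambert(sim$raw)
  summ <- hemo_stage_summary(hemo, sched, window_s = 20)
  j <- dplyr::inner_join(summ, sim$true_means, by = c("channel_id", "stage"))
  # stage interiors are flat; only boundary ramps could perturb the mean,
  # and the rolling window sits inside the stage
  expect_lt(max(abs(j$mean_ohb - j$true_ohb)), 0.06)
  expect_lt(max(abs(j$mean_hhb - j$true_hhb)), 0.06)
  # interior stages away from ramps recover to high precision
  base <- j[j$stage == "baseline", ]
  expect_lt(max(abs(base$mean_ohb - base$true_ohb)), 0.02)
})

test_that("EDA artifact injection avoids stage boundaries", {
  set.seed(51)
  cfg <- synth_config(eda = list(artifact_rate_per_min = 2))
  sched <- short_schedule()
  fs <- cfg$eda$sample_rate
  boundary_idx <- unique(c(round(sched$start_s * fs) + 1,
                           round(sched$end_s * fs)))
  for (i in 1:3) {
    sim <- simulate_eda_series(cfg, sched)
    expect_gt(sum(sim$artifact_mask), 0)
    expect_false(any(sim$artifact_mask[boundary_idx]))
  }
})

test_that("the null configuration zeroes every injected effect", {
  ncfg <- null_config()
  expect_equal(ncfg$cortisol$rise_mean, 0)
  expect_true(all(ncfg$eda$stage_increment_us == 0))
  expect_equal(ncfg$fnirs$sound_contrast_ohb, 0)
  set.seed(52)
  s <- simulate_cohort_summaries(ncfg)
  # haemodynamic stage means show no stress contrast beyond noise
  w <- tidyr::pivot_wider(s$hemo, id_cols = c("participant", "channel_id"),
                          names_from = "stage", values_from = "mean_ohb")
  d <- w$stress - w$baseline
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
})

test_that("EDF cohort files round-trip through the reader", {
  d <- withr::local_tempdir()
  cfg <- synth_config(n_per_group = c(soothing = 2, robotic = 2,
                                      silence = 2),
                      schedule = short_schedule())
  out <- generate_cohort(file.path(d, "c"), cfg, seed = 3,
                         modalities = "fnirs")
  m <- default_montage()
  raw <- read_fnirs_edf(file.path(d, "c", "fnirs", "p01.edf"), m,
                        age_years = out$ground_truth$roster$age[1])
  expect_equal(raw$sample_rate, 50)
  expect_equal(length(raw$od), 24)
  expect_equal(nrow(raw$od[[1]]), 270 * 50)
})
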