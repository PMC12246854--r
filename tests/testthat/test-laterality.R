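test_that("the laterality index follows its defining ratio", {
  expect_equal(compute_lir(1, 0), 1)
  expect_equal(compute_lir(0, 1), -1)
  expect_equal(compute_lir(2, 1), 1 / 3)
  expect_equal(compute_lir(1, 1), 0)
  expect_equal(compute_lir(0.3, 0.3), 0)
  # degenerate sum: undefined, never a number
  expect_true(is.na(compute_lir(1e-12, -1e-12)))
  expect_true(is.na(compute_lir(0, 0)))
})

test_that("LIR algebra: antisymmetry, scale invariance, bounds", {
  set.seed(99)
  for (i in 1:1000) {
    r <- runif(1, 0, 5); l <- runif(1, 0, 5); c <- runif(1, 0.1, 10)
    v <- compute_lir(r, l)
    if (is.na(v)) next
    expect_equal(compute_lir(l, r), -v, tolerance = 1e-12)
    expect_equal(compute_lir(c * r, c * l), v, tolerance = 1e-12)
    expect_lte(abs(v), 1)
  }
})

test_that("lir_table computes per-pair indices and skips rejected members", {
  m <- default_montage()
  summ <- tidyr::expand_grid(
    participant = c("a", "b"),
    channel_id = m$channels$channel_id,
    stage = c("baseline", "stress")
  )
  summ$mean_ohb <- 0.2 + 0.3 * (summ$stage == "stress") *
    (summ$channel_id %in% m$channels$channel_id[m$channels$hemisphere == "right"])
  summ$mean_hhb <- 0

  lt <- lir_table(summ, m$pairs, mode = "raw")
  expect_equal(nrow(lt), 2 * 7 * 2)
  base <- lt[lt$stage == "baseline", ]
  expect_true(all(base$lir == 0))
  stress <- lt[lt$stage == "stress", ]
  expect_true(all(stress$lir > 0))
  expect_equal(unique(stress$lir), (0.5 - 0.2) / (0.5 + 0.2))

  # swapping pair orientation negates every defined index
  swapped <- m$pairs
  names(swapped) <- c("left_channel", "right_channel")
  lt_sw <- lir_table(summ, swapped[, c("right_channel", "left_channel")],
                     mode = "raw")
  j <- dplyr::inner_join(
    as.data.frame(lt)[c("participant", "right_channel", "stage", "lir")],
    as.data.frame(lt_sw)[c("participant", "left_channel", "stage", "lir")],
    by = c(right_channel = "left_channel", participant = "participant",
           stage = "stage"))
  expect_equal(j$lir.x, -j$lir.y)

  # a pair with a rejected member is absent but logged
  drop <- summ[!(summ$participant == "a" & summ$channel_id == "Tx8-Rx7"), ]
  lt2 <- lir_table(drop, m$pairs)
  expect_equal(nrow(lt2), (2 * 7 - 1) * 2)
  sk <- attr(lt2, "skipped")
  expect_equal(nrow(sk), 1)
  expect_equal(sk$participant, "a")
  expect_equal(sk$left_channel, "Tx8-Rx7")
})

test_that("rectified mode keeps indices bounded when stage means go negative", {
  pairs <- tibble::tibble(right_channel = "Tx1-Rx1", left_channel = "Tx6-Rx5")
  summ <- tibble::tibble(
    participant = "a",
    channel_id = rep(c("Tx1-Rx1", "Tx6-Rx5"), each = 2),
    stage = rep(c("baseline", "stress"), 2),
    mean_ohb = c(-0.4, 0.6, -0.1, 0.1),
    mean_hhb = 0
  )
  lt <- lir_table(summ, pairs, mode = "rectified")
  expect_true(all(abs(lt$lir) <= 1, na.rm = TRUE))
  # raw mode reports the verbatim ratio, unbounded values allowed
  lt_raw <- lir_table(summ, pairs, mode = "raw")
  expect_equal(lt_raw$lir[lt_raw$stage == "baseline"],
               (-0.4 + 0.1) / (-0.4 - 0.1))
})

test_that("an injected right-dominant stress activation raises stress-stage LIR", {
  set.seed(55)
  m <- default_montage()
  s <- simulate_cohort_summaries(synth_config(), m)
  lt <- lir_table(s$hemo, m$pairs)
  agg <- dplyr::summarise(dplyr::group_by(lt, .data$stage),
                          lir = mean(.data$lir, na.rm = TRUE))
  expect_gt(agg$lir[agg$stage == "stress"], agg$lir[agg$stage == "baseline"])
})
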