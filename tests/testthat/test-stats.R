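test_that("Levene's test detects unequal variances and not equal ones", {
  set.seed(20)
  # identical groups: no variance difference, p near 1
  g1 <- rnorm(30)
  r <- levene_test(c(g1, g1), rep(c("a", "b"), each = 30))
  expect_gt(r$p_value, 0.99)
  expect_lt(r$statistic, 1e-10)
  # variances 1 vs 100 are flagged
  a <- rnorm(50, sd = 1); b <- rnorm(50, sd = 10)
  r2 <- levene_test(c(a, b), rep(c("a", "b"), each = 50))
  expect_lt(r2$p_value, 0.01)
  expect_error(levene_test(rnorm(10), rep("a", 10)),
               class = "stressphys_validation_error")
})

test_that("t-tests match closed forms and report signed Cohen's d", {
  x <- c(5, 6, 7)
  r0 <- paired_t_test(x, x)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_equal(r0$effect_size, 0)

  # differences 1, 2, 3: t = mean/ (sd/sqrt(n)) = 2 * sqrt(3)
  r <- paired_t_test(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df1, 2)
  expect_equal(r$effect_size, 2)

  # d sign follows the mean difference
  set.seed(30)
  a <- rnorm(12, 1); b <- rnorm(11, 0)
  ri <- independent_t_test(a, b)
  expect_equal(sign(ri$effect_size), sign(mean(a) - mean(b)))
  expect_equal(ri$df1, 21)
  expect_error(paired_t_test(c(1, 2), c(2, 3)),
               class = "stressphys_numeric_error")
})

test_that("pooled-sd Cohen's d is unbiased near the true effect", {
  set.seed(33)
  d_hat <- replicate(1000, {
    a <- rnorm(12, 0.8); b <- rnorm(11, 0)
    independent_t_test(a, b)$effect_size
  })
  expect_lt(abs(mean(d_hat) - 0.8), 0.1)
})

test_that("rm-ANOVA reduces to the squared paired t in the 2-level 1-group case", {
  set.seed(34)
  for (i in 1:5) {
    df <- tidyr::expand_grid(participant = sprintf("p%d", 1:9),
                             stage = c("s1", "s2"))
    df$value <- rnorm(18)
    fit <- rm_anova(df, between = NULL)
    w <- tidyr::pivot_wider(df, names_from = "stage",
                            values_from = "value")
    tt <- paired_t_test(w$s1, w$s2)
    t_row <- tidy(fit)
    expect_equal(t_row$statistic[t_row$effect == "stage"],
                 tt$statistic^2, tolerance = 1e-8)
    expect_equal(t_row$p_value[t_row$effect == "stage"], tt$p_value,
                 tolerance = 1e-8)
  }
})

test_that("rm-ANOVA sums of squares decompose additively", {
  set.seed(35)
  df <- tidyr::expand_grid(participant = sprintf("p%d", 1:12),
                           stage = c("baseline", "stress", "sound"))
  # one group per participant, balanced 4/4/4
  grp <- rep(c("soothing", "robotic", "silence"), each = 4)
  df$group <- grp[as.integer(sub("p", "", df$participant))]
  df$value <- rnorm(36) + (df$stage == "stress") * 0.5
  fit <- rm_anova(df)
  direct_total <- sum((df$value - mean(df$value))^2)
  expect_equal(fit$ss_total, direct_total, tolerance = 1e-8)
  parts <- sum(vapply(fit$strata, function(t) sum(t$`Sum Sq`), 0))
  expect_equal(parts, direct_total, tolerance = 1e-8)
})

test_that("rm-ANOVA matches a hand-rolled mixed-design decomposition", {
  # independent oracle: explicit SS formulas for a balanced mixed design
  set.seed(36)
  n_per <- 5
  groups <- c("a", "b", "c")
  stages <- c("s1", "s2", "s3")
  df <- tidyr::expand_grid(participant = sprintf("p%02d", 1:(n_per * 3)),
                           stage = stages)
  grp <- rep(groups, each = n_per)
  df$group <- grp[as.integer(sub("p", "", df$participant))]
  df$value <- rnorm(nrow(df))

  mu <- mean(df$value)
  k <- length(stages)
  subj_means <- tapply(df$value, df$participant, mean)
  grp_of <- tapply(df$group, df$participant, `[`, 1)
  grp_means <- tapply(df$value, df$group, mean)
  stage_means <- tapply(df$value, df$stage, mean)
  cell_means <- tapply(df$value, list(df$group, df$stage), mean)

  ss_group <- k * n_per * sum((grp_means - mu)^2)
  ss_subj_within <- k * sum((subj_means - grp_means[grp_of])^2)
  ss_stage <- n_per * 3 * sum((stage_means - mu)^2)
  # interaction SS: sum over cells of (cell - group - stage + mu)^2
  ss_inter <- n_per * sum((cell_means -
                             outer(grp_means, rep(1, k)) -
                             outer(rep(1, 3), stage_means) + mu)^2)
  fit <- rm_anova(df)
  t <- tidy(fit)
  expect_equal(t$sum_sq[t$effect == "group"], ss_group, tolerance = 1e-8)
  expect_equal(t$sum_sq[t$effect == "stage"], ss_stage, tolerance = 1e-8)
  expect_equal(t$sum_sq[t$effect == "group:stage"], ss_inter,
               tolerance = 1e-8)
  expect_equal(t$sum_sq_error[t$effect == "group"], ss_subj_within,
               tolerance = 1e-8)
  # F ratios follow from the same decomposition
  ms <- function(ss, d) ss / d
  expect_equal(t$statistic[t$effect == "group"],
               ms(ss_group, 2) / ms(ss_subj_within, 12), tolerance = 1e-8)
})

test_that("rm-ANOVA validates balance and factor levels", {
  df <- tidyr::expand_grid(participant = c("p1", "p2", "p3"),
                           stage = c("s1", "s2"))
  df$group <- "g"
  df$value <- rnorm(6)
  expect_error(rm_anova(df[-1, ]), "unbalanced",
               class = "stressphys_validation_error")
  df1 <- df[df$stage == "s1", ]
  expect_error(rm_anova(df1), class = "stressphys_validation_error")
})

test_that("glance reports the design dimensions", {
  df <- tidyr::expand_grid(participant = sprintf("p%d", 1:6),
                           stage = c("s1", "s2"))
  df$group <- c("a", "b")[as.integer(sub("p", "", df$participant)) %% 2 + 1]
  df$value <- rnorm(12)
  g <- glance(rm_anova(df))
  expect_equal(g$n_participants, 6)
  expect_equal(g$n_stages, 2)
  expect_equal(g$n_groups, 2)
})
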