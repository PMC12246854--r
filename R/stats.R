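#' Single-comparison tests with effect sizes
#'
#' Wrappers around the standard tests used throughout the stage-by-group
#' battery, each returning a one-row tibble in the common results schema:
#' `test`, `statistic`, `df1`, `df2`, `p_value`, `effect_size`,
#' `effect_size_kind`, `n`.
#'
#' * `levene_test()` — Brown-Forsythe variant of Levene's test (deviations
#'   from the group *median*), for variance homogeneity across groups.
#' * `paired_t_test()` — two-sided paired t; Cohen's d =
#'   `mean(x - y) / sd(x - y)`.
#' * `independent_t_test()` — two-sided two-sample t with pooled variance;
#'   Cohen's d = `(mean(a) - mean(b)) / s_pooled` with
#'   `s_pooled^2 = ((n_a-1)s_a^2 + (n_b-1)s_b^2) / (n_a + n_b - 2)`.
#'
#' @param values numeric response vector.
#' @param group grouping factor (>= 2 groups of >= 2 observations).
#' @return one-row tibble in the results schema.
#' @export
levene_test <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2) {
    abort("Levene's test needs at least 2 groups",
          class = "stressphys_validation_error")
  }
  if (any(table(group) < 2)) {
    abort("every group needs at least 2 observations",
          class = "stressphys_validation_error")
  }
  lt <- withCallingHandlers(
    car::leveneTest(values ~ group, center = median),
    # with n = 2 per group the absolute deviations from the group median
    # come in equal pairs and the auxiliary ANOVA fits perfectly; the test
    # statistic is still well-defined
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  tibble(test = "levene",
         statistic = lt[1, "F value"],
         df1 = lt[1, "Df"], df2 = lt[2, "Df"],
         p_value = lt[1, "Pr(>F)"],
         effect_size = NA_real_, effect_size_kind = NA_character_,
         n = length(values))
}

#' @rdname levene_test
#' @param x,y paired numeric samples of equal length (n >= 2).
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) {
    abort("paired samples must have equal length",
          class = "stressphys_validation_error")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) {
    abort("paired t-test needs at least 2 complete pairs",
          class = "stressphys_validation_error")
  }
  d <- x - y
  if (sd(d) == 0) {
    if (all(d == 0)) {
      # identical samples: no effect by construction
      return(tibble(test = "paired_t", statistic = 0,
                    df1 = length(d) - 1, df2 = NA_real_, p_value = 1,
                    effect_size = 0, effect_size_kind = "cohens_d",
                    n = length(d)))
    }
    abort("degenerate contrast: zero-variance paired differences",
          class = "stressphys_numeric_error")
  }
  tt <- t.test(x, y, paired = TRUE)
  tibble(test = "paired_t",
         statistic = unname(tt$statistic),
         df1 = unname(tt$parameter), df2 = NA_real_,
         p_value = tt$p.value,
         effect_size = mean(d) / sd(d),
         effect_size_kind = "cohens_d",
         n = length(d))
}

#' @rdname levene_test
#' @param a,b independent numeric samples (each n >= 2).
#' @export
independent_t_test <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("independent t-test needs n >= 2 per group",
          class = "stressphys_validation_error")
  }
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(test = "independent_t", statistic = 0,
                    df1 = length(a) + length(b) - 2, df2 = NA_real_,
                    p_value = 1, effect_size = 0,
                    effect_size_kind = "cohens_d", n = length(a) + length(b)))
    }
    abort("degenerate contrast: zero pooled variance",
          class = "stressphys_numeric_error")
  }
  tt <- t.test(a, b, var.equal = TRUE)
  tibble(test = "independent_t",
         statistic = unname(tt$statistic),
         df1 = unname(tt$parameter), df2 = NA_real_,
         p_value = tt$p.value,
         effect_size = (mean(a) - mean(b)) / sqrt(sp2),
         effect_size_kind = "cohens_d",
         n = length(a) + length(b))
}

#' Mixed repeated-measures ANOVA (stage within, group between)
#'
#' Fits the classical mixed-design ANOVA with one within-subject factor
#' (experimental stage) and an optional between-subject factor (group),
#' via the standard univariate sums-of-squares decomposition
#' (`aov` with an `Error(participant/stage)` stratum structure):
#' between-subject variation splits into group and subject-within-group,
#' within-subject variation into stage, stage-by-group and residual. Every
#' participant must contribute every stage (balanced within-factor).
#'
#' Effect sizes are partial eta-squared by default
#' (`SS_effect / (SS_effect + SS_error)` with the error term of the
#' effect's stratum); classical eta-squared (`SS_effect / SS_total`) is
#' also reported. No sphericity correction is applied by default;
#' Greenhouse-Geisser correction of the within-effect p-values is available
#' behind `gg_correction = TRUE`.
#'
#' @param data long-format data frame.
#' @param dv,within,between,id column names for the response, the
#'   within-subject factor, the between-subject factor (`NULL` for a
#'   single-group design) and the participant id.
#' @param gg_correction apply Greenhouse-Geisser correction to
#'   within-stratum p-values.
#' @return object of class `"rm_anova"`; see [tidy.rm_anova()].
#' @examples
#' df <- expand.grid(participant = paste0("p", 1:6),
#'                   stage = c("baseline", "stress"))
#' df$group <- rep(c("a", "b", "c"), 4)
#' set.seed(1); df$value <- rnorm(12)
#' fit <- rm_anova(df, dv = "value")
#' tidy(fit)
#' @export
rm_anova <- function(data, dv = "value", within = "stage", between = "group",
                     id = "participant", gg_correction = FALSE) {
  df <- as_tibble(data)
  need <- c(dv, within, id, between)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(sprintf("rm_anova: missing column(s) %s",
                  paste(missing_cols, collapse = ", ")),
          class = "stressphys_validation_error")
  }
  df <- tibble(value = df[[dv]],
               stage = factor(df[[within]], levels = unique(df[[within]])),
               participant = factor(df[[id]]),
               group = if (is.null(between)) factor("all")
                       else factor(df[[between]]))
  # balance check: every participant x stage cell exactly once
  cells <- table(df$participant, df$stage)
  if (any(cells != 1)) {
    bad <- which(cells != 1, arr.ind = TRUE)
    abort(sprintf("unbalanced design: missing/duplicated (participant, stage) cells, e.g. (%s, %s)",
                  rownames(cells)[bad[1, 1]], colnames(cells)[bad[1, 2]]),
          class = "stressphys_validation_error")
  }
  if (nlevels(df$stage) < 2) {
    abort("rm_anova needs at least 2 within-factor levels",
          class = "stressphys_validation_error")
  }
  has_between <- nlevels(df$group) > 1
  form <- if (has_between) {
    value ~ group * stage + Error(participant / stage)
  } else {
    value ~ stage + Error(participant / stage)
  }
  fit <- aov(form, data = df)
  st <- summary(fit)
  # locate the between-participant and within (participant:stage) strata
  strata <- lapply(st, function(s) as.data.frame(s[[1]]))
  names(strata) <- names(st)
  between_tab <- strata[["Error: participant"]]
  within_tab <- strata[["Error: participant:stage"]]
  ss_total <- sum(vapply(strata, function(t) sum(t$`Sum Sq`), 0))
  # constant data: total SS vanishes up to round-off; report zero effects
  degenerate <- ss_total < 1e-12 * max(1, sum(df$value^2))
  row_of <- function(tab, name) {
    i <- match(name, trimws(rownames(tab)))
    if (is.na(i)) NULL else tab[i, ]
  }
  mk <- function(tab, effect_name, label) {
    r <- row_of(tab, effect_name)
    res <- row_of(tab, "Residuals")
    if (is.null(r)) return(NULL)
    f <- r$`F value`
    p <- r$`Pr(>F)`
    eta_p <- r$`Sum Sq` / (r$`Sum Sq` + res$`Sum Sq`)
    # degenerate data (zero effect and zero error SS): no evidence of effect
    if (degenerate || !is.finite(f)) {
      f <- 0; p <- 1; eta_p <- 0
    }
    tibble(effect = label,
           df1 = r$Df, df2 = res$Df,
           sum_sq = r$`Sum Sq`, sum_sq_error = res$`Sum Sq`,
           statistic = f,
           p_value = p,
           eta_sq_partial = eta_p,
           eta_sq = if (degenerate) 0 else r$`Sum Sq` / ss_total)
  }
  tab <- bind_rows(
    if (has_between) mk(between_tab, "group", "group"),
    mk(within_tab, "stage", "stage"),
    if (has_between) mk(within_tab, "group:stage", "group:stage")
  )
  eps <- NA_real_
  if (gg_correction) {
    eps <- gg_epsilon(df)
    w <- tab$effect %in% c("stage", "group:stage")
    tab$p_value[w] <- stats::pf(tab$statistic[w],
                                eps * tab$df1[w], eps * tab$df2[w],
                                lower.tail = FALSE)
  }
  structure(
    list(table = tab, ss_total = ss_total, strata = strata,
         n_participants = nlevels(df$participant),
         n_stages = nlevels(df$stage),
         n_groups = nlevels(df$group),
         gg_epsilon = eps),
    class = "rm_anova"
  )
}

# Greenhouse-Geisser epsilon from the participant x stage covariance matrix
gg_epsilon <- function(df) {
  wide <- tidyr::pivot_wider(df[c("participant", "stage", "value")],
                             names_from = "stage", values_from = "value")
  m <- as.matrix(wide[, -1])
  s <- stats::cov(m)
  k <- ncol(s)
  dbar <- mean(diag(s)); sbar <- mean(s)
  rowbar <- rowMeans(s)
  eps <- (k * (dbar - sbar))^2 /
    ((k - 1) * (sum(s^2) - 2 * k * sum(rowbar^2) + k^2 * sbar^2))
  min(1, max(eps, 1 / (k - 1)))
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Mixed repeated-measures ANOVA: %d participants, %d stages, %d group(s)\n",
              x$n_participants, x$n_stages, x$n_groups))
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy methods for rm-ANOVA fits
#'
#' `tidy()` returns one row per effect (group, stage, interaction) with F,
#' degrees of freedom, p and both eta-squared variants; `glance()` returns
#' a one-row design summary.
#'
#' @param x an [rm_anova] fit.
#' @param ... unused.
#' @method tidy rm_anova
#' @export
tidy.rm_anova <- function(x, ...) x$table

#' @rdname tidy.rm_anova
#' @method glance rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble(n_participants = x$n_participants, n_stages = x$n_stages,
         n_groups = x$n_groups, ss_total = x$ss_total,
         gg_epsilon = x$gg_epsilon)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
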