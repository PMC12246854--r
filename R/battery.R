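#' Default stage-by-group analysis plan
#'
#' Enumerates the comparisons of the standard battery as a tibble with one
#' planned comparison per row:
#'
#' * cortisol — Levene's test per stage across groups; mixed rm-ANOVA over
#'   baseline/stress and over baseline/stress/sound; recovery contrast
#'   (rest2 minus baseline excess) soothing vs the pooled controls.
#' * EDA tonic level — mixed rm-ANOVA over the five sampled stages.
#' * haemodynamics (dOHb and dHHb, per channel) — paired t baseline vs
#'   stress; independent t at the sound stage for each group pairing.
#' * LIR (per pair) — paired t baseline vs stress; independent t at the
#'   sound stage for each group pairing.
#'
#' `stages` entries are comma-separated stage labels (for paired tests the
#' two stages compared, first minus second in the t statistic); `groups` is
#' either `"all"` or `"<side a>|<side b>"` where a side may pool groups
#' with `+` (e.g. `"soothing|robotic+silence"`).
#'
#' @return tibble: `measure`, `test`, `stages`, `groups`, `scope`.
#' @export
default_analysis_plan <- function() {
  group_pairs <- c("silence|soothing", "robotic|soothing", "silence|robotic")
  bind_rows(
    tibble(measure = "cortisol", test = "levene",
           stages = cortisol_stages(), groups = "all", scope = "pooled"),
    tibble(measure = "cortisol", test = "rm_anova",
           stages = c("baseline,stress", "baseline,stress,sound"),
           groups = "all", scope = "pooled"),
    tibble(measure = "cortisol_recovery", test = "independent_t",
           stages = "rest2", groups = "soothing|robotic+silence",
           scope = "pooled"),
    tibble(measure = "eda_tonic", test = "rm_anova",
           stages = "baseline,stress,sound,rest1,rest2",
           groups = "all", scope = "pooled"),
    tidyr::expand_grid(measure = c("hemo_ohb", "hemo_hhb"),
                       test = "paired_t", stages = "baseline,stress",
                       groups = "all", scope = "per_channel"),
    tidyr::expand_grid(measure = c("hemo_ohb", "hemo_hhb"),
                       test = "independent_t", stages = "sound",
                       groups = group_pairs, scope = "per_channel"),
    tibble(measure = "lir", test = "paired_t", stages = "baseline,stress",
           groups = "all", scope = "per_pair"),
    tidyr::expand_grid(measure = "lir", test = "independent_t",
                       stages = "sound", groups = group_pairs,
                       scope = "per_pair")
  )
}

split_group_spec <- function(spec) {
  sides <- strsplit(spec, "|", fixed = TRUE)[[1]]
  if (length(sides) != 2) {
    abort(sprintf("group spec '%s' must name two sides separated by '|'", spec),
          class = "stressphys_config_error")
  }
  lapply(sides, function(s) strsplit(s, "+", fixed = TRUE)[[1]])
}

# long-format (participant, group, stage, value) extraction per measure
battery_values <- function(data, measure) {
  groups <- data$groups
  join_group <- function(d) {
    if ("group" %in% names(d)) return(d)
    if (is.null(groups)) {
      abort("data$groups (participant, group) required for this measure",
            class = "stressphys_config_error")
    }
    left_join(d, groups, by = "participant")
  }
  switch(
    measure,
    cortisol = data$cortisol %>%
      rename(value = "nmol_per_l") %>%
      select("participant", "group", "stage", "value"),
    cortisol_recovery = data$cortisol %>%
      tidyr::pivot_wider(names_from = "stage", values_from = "nmol_per_l") %>%
      mutate(value = .data$rest2 - .data$baseline, stage = "rest2") %>%
      select("participant", "group", "stage", "value"),
    eda_tonic = join_group(data$eda) %>%
      rename(value = "tonic_mean") %>%
      select("participant", "group", "stage", "value"),
    hemo_ohb = join_group(data$hemo) %>%
      rename(value = "mean_ohb", unit = "channel_id") %>%
      select("participant", "group", "unit", "stage", "value"),
    hemo_hhb = join_group(data$hemo) %>%
      rename(value = "mean_hhb", unit = "channel_id") %>%
      select("participant", "group", "unit", "stage", "value"),
    lir = join_group(data$lir) %>%
      mutate(unit = paste0("[", .data$right_channel, ", ",
                           .data$left_channel, "]")) %>%
      rename(value = "lir") %>%
      select("participant", "group", "unit", "stage", "value"),
    abort(sprintf("unknown measure '%s'", measure),
          class = "stressphys_config_error")
  )
}

run_one_comparison <- function(vals, test, stages, groups) {
  stage_set <- strsplit(stages, ",", fixed = TRUE)[[1]]
  if (test == "levene") {
    v <- vals[vals$stage == stage_set[1], ]
    return(levene_test(v$value, v$group))
  }
  if (test == "rm_anova") {
    v <- vals[vals$stage %in% stage_set, ]
    v <- v[stats::complete.cases(v[c("value")]), ]
    fit <- rm_anova(v, dv = "value", within = "stage", between = "group",
                    id = "participant")
    t <- tidy(fit)
    return(tibble(test = paste0("rm_anova_", t$effect),
                  statistic = t$statistic, df1 = t$df1, df2 = t$df2,
                  p_value = t$p_value, effect_size = t$eta_sq_partial,
                  effect_size_kind = "partial_eta_sq",
                  n = fit$n_participants))
  }
  if (test == "paired_t") {
    wide <- vals[vals$stage %in% stage_set, ] %>%
      tidyr::pivot_wider(id_cols = "participant", names_from = "stage",
                         values_from = "value")
    if (!all(stage_set %in% names(wide))) {
      abort(sprintf("stage(s) missing for paired contrast: %s",
                    paste(setdiff(stage_set, names(wide)), collapse = ", ")),
            class = "stressphys_validation_error")
    }
    return(paired_t_test(wide[[stage_set[1]]], wide[[stage_set[2]]]))
  }
  if (test == "independent_t") {
    sides <- split_group_spec(groups)
    v <- vals[vals$stage == stage_set[1], ]
    a <- v$value[v$group %in% sides[[1]]]
    b <- v$value[v$group %in% sides[[2]]]
    return(independent_t_test(a, b))
  }
  abort(sprintf("unknown test '%s'", test), class = "stressphys_config_error")
}

#' Run the statistical battery over a cohort's summaries
#'
#' Executes every comparison of an analysis plan against the cohort's
#' stage summaries and emits one tidy results row per comparison (per
#' channel or pair for channel-scoped rows), in the channel-level report
#' schema with hemisphere and Brodmann-area annotation.
#'
#' @param data named list of inputs:
#'   `cortisol` ([cortisol_panel][read_cortisol_csv]),
#'   `eda` (stage summaries from [fuse_eda_summaries()] or
#'   [eda_stage_summary()]), `hemo` (bound [hemo_stage_summary()] rows),
#'   `lir` ([lir_table()]), `groups` (tibble `participant`, `group`) and
#'   optionally `montage` for annotation. Only the elements referenced by
#'   the plan are required.
#' @param plan analysis plan tibble (see [default_analysis_plan()]).
#' @param alpha significance level for the `significant` flag
#'   (default 0.05, uncorrected).
#' @param fdr also add a Benjamini-Hochberg adjusted `p_adjusted` column
#'   (adjusted within each (measure, test, stages, groups) family).
#' @return tibble with one row per executed comparison:
#'   `measure`, `test`, `unit` (channel or pair), `stages`, `groups`,
#'   `statistic`, `df1`, `df2`, `p_value`, `effect_size`,
#'   `effect_size_kind`, `n`, `significant`, plus `hemisphere` and
#'   `brodmann_area` where a channel is in scope.
#' @export
run_battery <- function(data, plan = default_analysis_plan(), alpha = 0.05,
                        fdr = FALSE) {
  if (!nrow(plan)) {
    return(tibble(measure = character(), test = character(),
                  unit = character(), stages = character(),
                  groups = character(), statistic = numeric(),
                  df1 = numeric(), df2 = numeric(), p_value = numeric(),
                  effect_size = numeric(), effect_size_kind = character(),
                  n = integer(), significant = logical()))
  }
  results <- purrr::pmap_dfr(plan, function(measure, test, stages, groups,
                                            scope) {
    vals <- battery_values(data, measure)
    if (scope == "pooled") {
      rows <- run_one_comparison(vals, test, stages, groups)
      rows$unit <- NA_character_
    } else {
      units <- sort(unique(vals$unit))
      rows <- purrr::map_dfr(units, function(u) {
        r <- run_one_comparison(vals[vals$unit == u, ], test, stages, groups)
        r$unit <- u
        r
      })
    }
    rows$measure <- measure
    rows$stages <- stages
    rows$groups <- groups
    rows
  })
  results$significant <- results$p_value < alpha
  if (fdr) {
    results <- results %>%
      group_by(.data$measure, .data$test, .data$stages, .data$groups) %>%
      mutate(p_adjusted = stats::p.adjust(.data$p_value, method = "BH")) %>%
      ungroup()
  }
  if (!is.null(data$montage)) {
    ann <- data$montage$channels[c("channel_id", "hemisphere",
                                   "brodmann_area")]
    results <- left_join(results, ann, by = c(unit = "channel_id"))
  }
  select(results, "measure", "test", "unit", "stages", "groups",
         "statistic", "df1", "df2", "p_value", "effect_size",
         "effect_size_kind", "n", "significant", dplyr::everything())
}
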