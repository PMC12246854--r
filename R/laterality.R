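#' Laterality Index Response
#'
#' The LIR quantifies hemispheric asymmetry of prefrontal activation over a
#' homologous right/left channel pair:
#' \deqn{LIR = \frac{R - L}{R + L}}
#' where `R` and `L` are the stage-mean dOHb activities of the right and
#' left channel. Positive values indicate right-dominant activation,
#' negative values left-dominant; with non-negative activities the index is
#' bounded in `[-1, 1]`.
#'
#' Stage-mean concentration *changes* can be negative, which would make the
#' raw ratio unbounded. Two modes are provided:
#' \describe{
#'   \item{`"rectified"` (default)}{activities are first shifted by the
#'     minimum over the participant-pair's stage means and floored at zero
#'     (`max(value - min, 0)`), restoring the `[-1, 1]` range while
#'     preserving the ordering of stages.}
#'   \item{`"raw"`}{the ratio is applied verbatim to the signed activities;
#'     values outside `[-1, 1]` are possible and are reported as computed.}
#' }
#' In either mode, when `|R + L|` falls below `floor` the index is
#' undefined and `NA` is returned (never a spurious 0 or infinity); `NA`
#' propagates to downstream statistics as a missing value.
#'
#' @param right_activity,left_activity stage-mean dOHb of the right and
#'   left channel of a pair (micromol/L).
#' @param floor degeneracy floor on `|R + L|` (default 1e-9).
#' @return the LIR value, or `NA` when degenerate.
#' @examples
#' compute_lir(1, 0)    # 1 (fully right-dominant)
#' compute_lir(2, 1)    # 1/3
#' compute_lir(1, 1)    # 0
#' @export
compute_lir <- function(right_activity, left_activity, floor = 1e-9) {
  s <- right_activity + left_activity
  out <- ifelse(abs(s) < floor, NA_real_,
                (right_activity - left_activity) / s)
  out
}

#' LIR table across participants, pairs and stages
#'
#' Computes one LIR per (participant, pair, stage) from haemodynamic stage
#' summaries. A pair contributes only when both members were retained for
#' that participant; pairs with a rejected member are skipped and listed in
#' the `skipped` attribute.
#'
#' @param summaries tibble from [hemo_stage_summary()] (one or several
#'   participants bound together), columns `participant`, `channel_id`,
#'   `stage`, `mean_ohb`.
#' @param pairs pair catalogue: tibble `right_channel`, `left_channel`
#'   (e.g. `default_montage()$pairs`).
#' @param mode `"rectified"` (bounded, default) or `"raw"` (verbatim
#'   ratio); see [compute_lir()].
#' @param floor degeneracy floor on `|R + L|`.
#' @return tibble: `participant`, `right_channel`, `left_channel`, `stage`,
#'   `right_activity`, `left_activity`, `lir`; skipped (participant, pair)
#'   combinations in `attr(, "skipped")`.
#' @export
lir_table <- function(summaries, pairs, mode = c("rectified", "raw"),
                      floor = 1e-9) {
  mode <- match.arg(mode)
  if (!all(c("right_channel", "left_channel") %in% names(pairs))) {
    abort("pairs must have columns right_channel, left_channel",
          class = "stressphys_config_error")
  }
  act <- summaries[c("participant", "channel_id", "stage", "mean_ohb")]
  right <- dplyr::inner_join(pairs, act,
                             by = c(right_channel = "channel_id"),
                             relationship = "many-to-many")
  both <- dplyr::inner_join(
    right,
    rename(act, left_activity = "mean_ohb"),
    by = c(left_channel = "channel_id", participant = "participant",
           stage = "stage")
  ) %>%
    rename(right_activity = "mean_ohb")
  # (participant, pair) combinations lost to a rejected member
  all_combos <- tidyr::expand_grid(
    participant = unique(summaries$participant), pairs)
  skipped <- dplyr::anti_join(
    all_combos, both,
    by = c("participant", "right_channel", "left_channel")) %>%
    distinct(.data$participant, .data$right_channel, .data$left_channel)
  if (mode == "rectified") {
    both <- both %>%
      group_by(.data$participant, .data$right_channel, .data$left_channel) %>%
      mutate(pair_min = min(c(.data$right_activity, .data$left_activity))) %>%
      ungroup() %>%
      mutate(right_activity = pmax(.data$right_activity - .data$pair_min, 0),
             left_activity = pmax(.data$left_activity - .data$pair_min, 0)) %>%
      select(-"pair_min")
  }
  out <- both %>%
    mutate(lir = compute_lir(.data$right_activity, .data$left_activity,
                             floor = floor)) %>%
    select("participant", "right_channel", "left_channel", "stage",
           "right_activity", "left_activity", "lir") %>%
    arrange(.data$participant, .data$right_channel, .data$stage)
  structure(out, skipped = skipped, mode = mode,
            class = c("lir_table", class(out)))
}
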