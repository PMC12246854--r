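#' Cortisol trajectory metrics
#'
#' A participant's cortisol trajectory is the ordered five-point sampling of
#' salivary cortisol around the stress task: `baseline` (about 15 min before
#' stress end), `stress` (immediately after the task, time 0), `sound`
#' (right after the intervention), `rest1` (+10 min after the sound) and
#' `rest2` (+20 min after the sound). `cortisol_trajectory()` extracts one
#' participant's trajectory from a panel; `stage_delta()` and
#' `baseline_return()` are the two metrics used to characterise reactivity
#' and recovery.
#'
#' @param panel a [cortisol_panel][read_cortisol_csv].
#' @param participant participant id present in the panel.
#' @param minutes optional named numeric vector of sampling times in minutes
#'   from stress end (defaults place `sound` at +15, `rest1` +25, `rest2`
#'   +35; the sound time varies with the audio track and can be overridden
#'   per participant).
#' @return a tibble of class `"cortisol_trajectory"` with columns `stage`,
#'   `minutes`, `nmol_per_l`, and attributes `participant` and `group`.
#' @export
cortisol_trajectory <- function(panel, participant,
                                minutes = c(baseline = -15, stress = 0,
                                            sound = 15, rest1 = 25,
                                            rest2 = 35)) {
  rows <- panel[panel$participant == participant, ]
  if (!nrow(rows)) {
    abort(sprintf("participant '%s' not in panel", participant),
          class = "stressphys_validation_error")
  }
  ord <- match(cortisol_stages(), rows$stage)
  rows <- rows[ord[!is.na(ord)], ]
  out <- tibble(stage = rows$stage,
                minutes = unname(minutes[rows$stage]),
                nmol_per_l = rows$nmol_per_l)
  structure(out,
            participant = participant,
            group = rows$group[1],
            class = c("cortisol_trajectory", class(out)))
}

traj_value <- function(traj, stage) {
  i <- match(stage, traj$stage)
  if (is.na(i)) {
    abort(sprintf("stage '%s' missing from trajectory", stage),
          class = "stressphys_validation_error")
  }
  traj$nmol_per_l[i]
}

#' @rdname cortisol_trajectory
#' @param traj a `cortisol_trajectory`.
#' @param from_stage,to_stage stage labels present in the trajectory.
#' @return `stage_delta()`: the concentration change `to - from` in nmol/L.
#' @examples
#' p <- cortisol_panel(tibble::tibble(
#'   participant = "p1", group = "soothing",
#'   stage = c("baseline", "stress", "sound", "rest1", "rest2"),
#'   nmol_per_l = c(10, 16, 13, 11, 10.2)))
#' tr <- cortisol_trajectory(p, "p1")
#' stage_delta(tr, "baseline", "stress")   # +6
#' baseline_return(tr)                     # "rest2"
#' @export
stage_delta <- function(traj, from_stage, to_stage) {
  traj_value(traj, to_stage) - traj_value(traj, from_stage)
}

#' @rdname cortisol_trajectory
#' @param tolerance_fraction how close to baseline counts as "returned":
#'   a post-stress sample returns when its concentration is at most
#'   `baseline * (1 + tolerance_fraction)`. Default 0.05 (within 5%).
#' @return `baseline_return()`: the earliest post-stress stage label at
#'   which the concentration is back within tolerance of baseline, or
#'   `NA_character_` when it never returns within the panel. Larger
#'   tolerances can only move the returned stage earlier, never later.
#' @export
baseline_return <- function(traj, tolerance_fraction = 0.05) {
  if (tolerance_fraction < 0) {
    abort("tolerance_fraction must be >= 0",
          class = "stressphys_parameter_error")
  }
  base <- traj_value(traj, "baseline")
  post <- traj[match(traj$stage, cortisol_stages()) > 2 & !is.na(match(traj$stage, cortisol_stages())), ]
  post <- post[order(match(post$stage, cortisol_stages())), ]
  hit <- which(post$nmol_per_l <= base * (1 + tolerance_fraction))
  if (!length(hit)) return(NA_character_)
  post$stage[hit[1]]
}

#' Per-group mean cortisol trajectories
#'
#' Averages trajectories across the participants of each group, yielding
#' one mean trajectory per group — the curve usually plotted for recovery
#' comparisons.
#'
#' @param panel a [cortisol_panel][read_cortisol_csv].
#' @return tibble with columns `group`, `stage`, `minutes`, `nmol_per_l`
#'   (group mean), `sem`.
#' @export
cortisol_group_means <- function(panel) {
  minutes <- c(baseline = -15, stress = 0, sound = 15, rest1 = 25, rest2 = 35)
  panel %>%
    group_by(.data$group, .data$stage) %>%
    summarise(sem = sd(.data$nmol_per_l) / sqrt(n()),
              nmol_per_l = mean(.data$nmol_per_l), .groups = "drop") %>%
    mutate(minutes = unname(minutes[.data$stage])) %>%
    arrange(.data$group, .data$minutes) %>%
    select("group", "stage", "minutes", "nmol_per_l", "sem")
}
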