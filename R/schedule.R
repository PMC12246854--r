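#' Experimental stage schedule
#'
#' The stage schedule is the single clock of the experiment: an ordered set
#' of half-open intervals `[start_s, end_s)` in seconds from recording
#' start, one per stage. All modalities (EDA, fNIRS) are segmented against
#' it, and cortisol samples are labelled by the stage they follow.
#'
#' `stage_schedule()` builds and validates a schedule from a data frame;
#' `default_schedule()` returns the standard protocol: 5 min baseline,
#' 5 min anticipation, 10 min stress task, 5 min intermediate rest, the
#' sound intervention (duration of the audio track, default 10 min), then
#' two 5-min recovery periods (`rest1`, `rest2`).
#'
#' @param x data frame with columns `stage`, `start_s`, `end_s`.
#' @param sound_s duration of the sound-intervention stage in seconds.
#' @return a tibble of class `"stage_schedule"` with columns
#'   `stage`, `start_s`, `end_s`.
#' @examples
#' default_schedule()
#' @export
stage_schedule <- function(x) {
  x <- as_tibble(x)
  need <- c("stage", "start_s", "end_s")
  if (!all(need %in% names(x))) {
    abort("schedule needs columns stage, start_s, end_s",
          class = "stressphys_config_error")
  }
  x <- x[need]
  x$stage <- as.character(x$stage)
  if (anyDuplicated(x$stage)) {
    abort("stage labels must be unique", class = "stressphys_config_error")
  }
  if (any(x$end_s <= x$start_s)) {
    abort("every stage must have end_s > start_s",
          class = "stressphys_config_error")
  }
  x <- arrange(x, .data$start_s)
  if (nrow(x) > 1 && any(x$start_s[-1] < x$end_s[-nrow(x)])) {
    abort("stage intervals must not overlap", class = "stressphys_config_error")
  }
  class(x) <- c("stage_schedule", class(x))
  x
}

#' @rdname stage_schedule
#' @export
default_schedule <- function(sound_s = 600) {
  durations <- c(baseline = 300, anticipation = 300, stress = 600,
                 intermediate_rest = 300, sound = sound_s,
                 rest1 = 300, rest2 = 300)
  ends <- cumsum(durations)
  stage_schedule(tibble(
    stage = names(durations),
    start_s = c(0, unname(ends[-length(ends)])),
    end_s = unname(ends)
  ))
}

#' @rdname stage_schedule
#' @param path YAML file with a `stages:` list of `{stage, start_s, end_s}`.
#' @export
read_schedule <- function(path) {
  raw <- yaml::read_yaml(path)
  stage_schedule(purrr::map_dfr(raw$stages, as_tibble))
}

#' @rdname stage_schedule
#' @param schedule a `stage_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  yaml::write_yaml(
    list(stages = purrr::pmap(schedule, function(stage, start_s, end_s) {
      list(stage = stage, start_s = start_s, end_s = end_s)
    })),
    path
  )
  invisible(path)
}

schedule_duration <- function(schedule) max(schedule$end_s)

#' Stages at which saliva is sampled, in trajectory order
#' @keywords internal
cortisol_stages <- function() c("baseline", "stress", "sound", "rest1", "rest2")
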