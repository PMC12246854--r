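# shared fixtures: a compressed stage schedule for fast signal-level tests
# (same stage sequence as the full protocol, 1/10 of the durations)
short_schedule <- function() {
  stage_schedule(tibble::tibble(
    stage = c("baseline", "anticipation", "stress", "intermediate_rest",
              "sound", "rest1", "rest2"),
    start_s = c(0, 30, 60, 120, 150, 210, 240),
    end_s = c(30, 60, 120, 150, 210, 240, 270)
  ))
}

jaccard <- function(a, b) {
  sum(a & b) / sum(a | b)
}

# small cohort configuration for end-to-end tests
small_cohort_config <- function(...) {
  synth_config(n_per_group = c(soothing = 2, robotic = 2, silence = 2), ...)
}
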