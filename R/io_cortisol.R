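#' Read and write salivary cortisol panels
#'
#' A cortisol panel is a tidy table with one row per saliva sample:
#' `participant`, `group` (`soothing`, `robotic`, `silence`), `stage`
#' (`baseline`, `stress`, `sound`, `rest1`, `rest2`) and `nmol_per_l`
#' (concentration; 1 nM = 1 nmol/L). Readers validate the panel: unknown
#' stage or group labels, duplicate `(participant, stage)` rows and
#' negative concentrations are rejected.
#'
#' @param path CSV file with columns `participant`, `group`, `stage`,
#'   `nmol_per_l`.
#' @return a validated tibble of class `"cortisol_panel"`.
#' @export
read_cortisol_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cortisol file not found: %s", path),
          class = "stressphys_io_error")
  }
  x <- readr::read_csv(path, show_col_types = FALSE)
  cortisol_panel(x)
}

#' @rdname read_cortisol_csv
#' @param x data frame with the panel columns.
#' @export
cortisol_panel <- function(x) {
  x <- as_tibble(x)
  need <- c("participant", "group", "stage", "nmol_per_l")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    abort(sprintf("cortisol panel missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "stressphys_format_error")
  }
  x <- x[need]
  x$participant <- as.character(x$participant)
  x$group <- as.character(x$group)
  x$stage <- as.character(x$stage)
  bad_stage <- setdiff(unique(x$stage), cortisol_stages())
  if (length(bad_stage)) {
    abort(sprintf("unknown cortisol stage label(s): %s",
                  paste(bad_stage, collapse = ", ")),
          class = "stressphys_validation_error")
  }
  bad_group <- setdiff(unique(x$group), c("soothing", "robotic", "silence"))
  if (length(bad_group)) {
    abort(sprintf("unknown group label(s): %s",
                  paste(bad_group, collapse = ", ")),
          class = "stressphys_validation_error")
  }
  if (any(!is.finite(x$nmol_per_l)) || any(x$nmol_per_l < 0)) {
    abort("cortisol concentrations must be finite and >= 0",
          class = "stressphys_validation_error")
  }
  dup <- duplicated(x[c("participant", "stage")])
  if (any(dup)) {
    d <- x[dup, ]
    abort(sprintf("duplicate (participant, stage) row(s): %s",
                  paste(sprintf("(%s, %s)", d$participant, d$stage),
                        collapse = ", ")),
          class = "stressphys_validation_error")
  }
  class(x) <- c("cortisol_panel", setdiff(class(x), "cortisol_panel"))
  x
}

#' @rdname read_cortisol_csv
#' @param panel a `cortisol_panel`.
#' @export
write_cortisol_csv <- function(panel, path) {
  readr::write_csv(panel, path)
  invisible(path)
}

#' Write a tidy statistical-results table
#'
#' Serialises battery output (one statistical comparison per row) to CSV in
#' the channel-level report schema: measure, haemoglobin/channel context,
#' test, statistic, degrees of freedom, p-value, effect size, hemisphere and
#' Brodmann area.
#'
#' @param results tibble of statistical results (see [run_battery()]).
#' @param path output CSV path.
#' @export
write_results_csv <- function(results, path) {
  readr::write_csv(results, path)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
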