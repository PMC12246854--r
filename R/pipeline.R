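#' End-to-end cohort pipeline
#'
#' Runs ingest, preprocessing, stage summarisation, laterality and the
#' statistical battery over a cohort directory laid out as written by
#' [generate_cohort()]: `participants.csv`, `schedule.yaml`, optionally
#' `cortisol.csv`, `eda/<id>_<device>.csv` (with `_tags.txt`) and
#' `fnirs/<id>.edf`. Modalities that are absent from the directory are
#' skipped; a participant whose files fail to read is skipped with a
#' logged warning, never silently dropped. Input files are never
#' modified.
#'
#' @param cohort_dir input cohort directory.
#' @param out_dir results directory (created; tidy CSVs, manifest, log).
#' @param montage an [fnirs_montage][read_montage].
#' @param eda_opts list: `jump_threshold` (uS), `cutoff_hz`, `filter_order`,
#'   `window_s`, `min_valid_fraction`, `band_k`.
#' @param fnirs_opts list: `sci_threshold`, `cardiac_band_hz`,
#'   `hemo_band_hz`, `window_s`, `bandpass` (apply the haemodynamic
#'   band-pass before stage averages; default TRUE).
#' @param lir_mode `"rectified"` or `"raw"` (see [compute_lir()]).
#' @param plan analysis plan (rows referencing unavailable measures are
#'   dropped); see [default_analysis_plan()].
#' @param alpha significance level for flagging.
#' @return invisible list: `results` (battery tibble), `eda`, `hemo`,
#'   `lir`, `sci`, `manifest`, `warnings` (count), `out_dir`.
#' @export
run_pipeline <- function(cohort_dir, out_dir,
                         montage = default_montage(),
                         eda_opts = list(), fnirs_opts = list(),
                         lir_mode = "rectified",
                         plan = default_analysis_plan(),
                         alpha = 0.05) {
  eo <- utils::modifyList(
    list(jump_threshold = 0.01, cutoff_hz = 0.5, filter_order = 4,
         window_s = 120, min_valid_fraction = 0.7, band_k = 3), eda_opts)
  fo <- utils::modifyList(
    list(sci_threshold = 0.75, cardiac_band_hz = c(0.7, 1.5),
         hemo_band_hz = c(0.02, 0.18), window_s = 120, bandpass = TRUE),
    fnirs_opts)

  pfile <- file.path(cohort_dir, "participants.csv")
  sfile <- file.path(cohort_dir, "schedule.yaml")
  if (!file.exists(pfile) || !file.exists(sfile)) {
    abort(sprintf("cohort directory %s lacks participants.csv / schedule.yaml",
                  cohort_dir),
          class = "stressphys_io_error")
  }
  roster <- readr::read_csv(pfile, show_col_types = FALSE)
  if (!nrow(roster)) {
    abort("empty cohort", class = "stressphys_validation_error")
  }
  schedule <- read_schedule(sfile)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  n_warn <- 0
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  warn_note <- function(fmt, ...) {
    n_warn <<- n_warn + 1
    note(paste0("WARNING: ", fmt), ...)
  }

  cortisol <- NULL
  cfile <- file.path(cohort_dir, "cortisol.csv")
  if (file.exists(cfile)) cortisol <- read_cortisol_csv(cfile)

  # --- EDA -----------------------------------------------------------------
  eda_summaries <- NULL
  if (dir.exists(file.path(cohort_dir, "eda"))) {
    per_device <- purrr::map_dfr(roster$participant, function(p) {
      fl <- Sys.glob(file.path(cohort_dir, "eda", paste0(p, "_*.csv")))
      purrr::map_dfr(fl, function(f) {
        device <- sub(sprintf("^%s_", p), "", sub("\\.csv$", "", basename(f)))
        tags <- sub("\\.csv$", "_tags.txt", f)
        tryCatch({
          s <- read_eda_csv(f, tags_path = if (file.exists(tags)) tags,
                            participant_id = p)
          s <- eda_detect_artifacts(s, jump_threshold = eo$jump_threshold,
                                    band_k = eo$band_k)
          s <- eda_repair_artifacts(s)
          s <- eda_lowpass(s, eo$cutoff_hz, eo$filter_order)
          s <- eda_normalize(s)
          out <- eda_stage_summary(s, schedule, eo$window_s)
          out$device <- device
          out
        }, error = function(e) {
          warn_note("EDA %s/%s skipped: %s", p, device, conditionMessage(e))
          NULL
        })
      })
    })
    if (nrow(per_device %||% tibble())) {
      eda_summaries <- fuse_eda_summaries(per_device, eo$min_valid_fraction)
      note("EDA: %d participants summarised",
           length(unique(eda_summaries$participant)))
    }
  }

  # --- fNIRS ---------------------------------------------------------------
  hemo_summaries <- NULL
  sci_all <- NULL
  if (dir.exists(file.path(cohort_dir, "fnirs"))) {
    res <- purrr::map(roster$participant, function(p) {
      f <- file.path(cohort_dir, "fnirs", paste0(p, ".edf"))
      if (!file.exists(f)) {
        warn_note("fNIRS %s: file missing", p)
        return(NULL)
      }
      age <- roster$age[roster$participant == p][1]
      tryCatch({
        raw <- read_fnirs_edf(f, montage, age_years = age, participant_id = p)
        rep <- sci_report(raw, threshold = fo$sci_threshold,
                          band = fo$cardiac_band_hz)
        hemo <- beer_lambert(raw)
        hemo$retained_channels <- rep$channel_id[rep$keep]
        if (fo$bandpass) hemo <- bandpass_hemo(hemo, fo$hemo_band_hz)
        summ <- hemo_stage_summary(hemo, schedule, fo$window_s)
        rep$participant <- p
        list(summ = summ, sci = rep)
      }, error = function(e) {
        warn_note("fNIRS %s skipped: %s", p, conditionMessage(e))
        NULL
      })
    })
    res <- purrr::compact(res)
    if (length(res)) {
      hemo_summaries <- purrr::map_dfr(res, "summ")
      sci_all <- purrr::map_dfr(res, "sci")
      note("fNIRS: %d participants, %d channel rejections", length(res),
           sum(!sci_all$keep))
    }
  }

  # --- LIR -----------------------------------------------------------------
  lir <- NULL
  if (!is.null(hemo_summaries) && nrow(hemo_summaries)) {
    lir <- lir_table(hemo_summaries, montage$pairs, mode = lir_mode)
    sk <- attr(lir, "skipped")
    if (nrow(sk)) {
      note("LIR: %d (participant, pair) combinations skipped for rejected channels",
           nrow(sk))
    }
  }

  # --- battery -------------------------------------------------------------
  available <- c(
    if (!is.null(cortisol)) c("cortisol", "cortisol_recovery"),
    if (!is.null(eda_summaries)) "eda_tonic",
    if (!is.null(hemo_summaries)) c("hemo_ohb", "hemo_hhb"),
    if (!is.null(lir)) "lir"
  )
  plan_used <- plan[plan$measure %in% available, ]
  data <- list(cortisol = cortisol, eda = eda_summaries,
               hemo = hemo_summaries, lir = lir,
               groups = roster[c("participant", "group")],
               montage = montage)
  results <- run_battery(data, plan_used, alpha = alpha)

  # --- outputs -------------------------------------------------------------
  outputs <- character(0)
  put <- function(x, name) {
    if (is.null(x)) return()
    f <- file.path(out_dir, name)
    readr::write_csv(as_tibble(x), f)
    outputs <<- c(outputs, name)
  }
  put(results, "results.csv")
  put(eda_summaries, "eda_summaries.csv")
  put(hemo_summaries, "hemo_summaries.csv")
  put(lir, "lir.csv")
  put(sci_all, "sci_report.csv")
  manifest <- list(
    cohort_dir = cohort_dir,
    options = list(eda = eo, fnirs = fo, lir_mode = lir_mode, alpha = alpha),
    n_participants = nrow(roster),
    n_comparisons = nrow(results),
    warnings = n_warn,
    outputs = outputs,
    version = as.character(utils::packageVersion("stressphys"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(list(results = results, eda = eda_summaries,
                 hemo = hemo_summaries, lir = lir, sci = sci_all,
                 manifest = manifest, warnings = n_warn, out_dir = out_dir))
}
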