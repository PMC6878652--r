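# End-to-end orchestration mirroring the analysis funnel:
# simulate? -> qc -> segment -> curate -> compare -> classify -> inherit
# -> report, with per-stage outputs and counts.

#' Run the full analysis pipeline
#'
#' Executes the stages in order on a cohort of profiles (simulated with
#' [simulate_cohort()] when none is given), writing every stage's output
#' under `out_dir` together with a log recording the config hash, seed and
#' per-stage counts. Re-running with the same config and inputs is
#' byte-identical.
#'
#' @param config a `cgh_config` list (see [default_config()]).
#' @param out_dir output directory, created if needed; `NULL` skips writing.
#' @param design a `cgh_design`; defaults to [build_design()] of the
#'   default region table.
#' @param cohort a `cgh_cohort` list (profiles/truth/manifest); `NULL`
#'   simulates a small demonstration cohort from `config$seed`.
#' @param db optional `pop_db` tibble for the comparison stage.
#' @param validation optional validation table for the classify stage.
#' @param transmission optional `transmission_test` for the report.
#' @return a list of stage results: `qc`, `calls`, `curated`, `classified`,
#'   `report` (character lines), `log` (named counts).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         design = NULL, cohort = NULL, db = NULL,
                         validation = NULL, transmission = NULL) {
  if (is.null(design)) design <- build_design()
  if (is.null(cohort)) {
    demo_cnvs <- tibble(chrom = "chr10", start = 43572000, end = 43575000,
                        type = "loss", copy_number = 1L, sample_id = "S01")
    cohort <- simulate_cohort(design, n_samples = 4, cnvs = demo_cnvs,
                              noise_sd = 0.15, seed = config$seed)
  }
  validate_manifest(cohort$manifest)
  write_out <- function(x, name) {
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      write_cgh_tsv(x, file.path(out_dir, name), seed = config$seed,
                    config = config)
    }
  }

  pp <- preprocess(cohort$profiles, dlrs_gate = config$qc$dlrs_gate)
  write_out(pp$qc, "qc_report.tsv")

  raw <- detect_aberrations(pp$profiles,
                            threshold = config$segmentation$threshold)
  rescued <- visual_rescue(pp$profiles, raw)
  calls <- dplyr::bind_rows(raw, rescued)
  class(calls) <- unique(c("cgh_calls", class(calls)))
  write_out(calls, "calls.tsv")

  curated <- calls %>%
    filter_calls(malr_min = config$curation$malr_min,
                 min_probes = config$curation$min_probes) %>%
    split_merge(pp$profiles) %>%
    triage(likely_gain = config$curation$triage$likely_gain,
           likely_loss = config$curation$triage$likely_loss,
           unlikely_malr = config$curation$triage$unlikely_malr,
           weak_two_probe = config$curation$triage$weak_two_probe) %>%
    replicate_concordance(pp$profiles, design,
                          threshold = config$segmentation$threshold)
  write_out(curated, "curated.tsv")

  if (!is.null(db)) {
    curated <- match_population(curated, db, design,
                                overlap_min = config$matching$overlap_min,
                                max_probe_diff = config$matching$max_probe_diff)
  }
  classified <- classify_truth(count_recurrence(curated, design))
  write_out(classified, "classified.tsv")

  log <- c(profiles = length(unique(cohort$profiles$sample_id)),
           calls = nrow(calls), curated = nrow(curated),
           true = sum(classified$is_true),
           novel_true = sum(classified$is_true & classified$novelty == "novel"))
  rpt <- report(list(calls = calls, curated = curated,
                     classified = classified, validation = validation,
                     transmission = transmission))
  if (!is.null(out_dir)) {
    writeLines(c(cgh_header(config$seed, config), rpt),
               file.path(out_dir, "report.txt"))
    writeLines(c(cgh_header(config$seed, config),
                 paste0(names(log), ": ", log)),
               file.path(out_dir, "log.txt"))
  }
  list(qc = pp$qc, calls = calls, curated = curated, classified = classified,
       report = rpt, log = log)
}

#' Render the analysis funnel and summaries as text
#'
#' Emits the funnel (calls, post-filter calls, true variants, novel true
#' variants), the validation confirmation count when a validation table is
#' supplied, and the maternal-transmission line when a transmission test is
#' supplied. Percentages are printed to 1 decimal.
#'
#' @param results a list with any of: `calls`, `curated`, `classified`
#'   (tibbles), `validation` (validation table), `transmission`
#'   (a `transmission_test`).
#' @return the report, a character vector of lines.
#' @export
report <- function(results) {
  lines <- character(0)
  if (!is.null(results$calls)) {
    lines <- c(lines, paste0("calls: ", nrow(results$calls)))
  }
  if (!is.null(results$curated)) {
    lines <- c(lines, paste0("filtered calls: ", nrow(results$curated)))
  }
  if (!is.null(results$classified)) {
    cl <- results$classified
    lines <- c(lines,
               paste0("true variants: ", sum(cl$is_true)),
               paste0("novel true variants: ",
                      sum(cl$is_true & cl$novelty == "novel")))
  }
  if (!is.null(results$validation)) {
    cls <- classify_validation(results$validation)
    lines <- c(lines,
               paste0("selected for validation: ", sum(cls$selected)),
               paste0("confirmed: ", count_confirmed(results$validation)),
               paste0("novel true (incl. replicate-only): ",
                      sum(cls$is_true & cls$novelty == "novel")))
  }
  if (!is.null(results$transmission)) {
    x <- results$transmission
    lines <- c(lines, sprintf(
      "maternal transmission p = %.4f (%d%% CI %.0f-%.0f%%)",
      x$p_value, round(100 * x$conf_level),
      100 * x$ci_lower, 100 * x$ci_upper))
  }
  if (length(lines) == 0) lines <- "empty results"
  lines
}
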