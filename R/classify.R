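# "True variant" classification and cohort summaries.
#
# A variant is true when it is reported in a population database, confirmed
# on a second array replicate, or validated with an orthogonal approach.

#' Classify curated calls as true / not true
#'
#' Combines the three evidence channels: a population-database match
#' (any frequency), replicate confirmation, and orthogonal validation.
#' Novelty is `"on_dgv"` only for calls matched in the DGV-like source at a
#' frequency above `rare_max`; calls matched only at very low frequency are
#' counted among the novel (not-reported) variants.
#'
#' @param calls matched curated calls; columns `matched`, `best_freq`,
#'   `match_sources` and `replicate_status` are used if present, and an
#'   optional `validation_outcome` column ("validated", "failed",
#'   "not_conclusive", "not_attempted").
#' @param dgv_source label of the DGV-like source (default "dgv").
#' @param rare_max frequency at or below which a database match still counts
#'   as novel (default 0.01).
#' @return the calls with added `is_true` (logical) and `novelty`
#'   (`"on_dgv"` / `"novel"`).
#' @export
classify_truth <- function(calls, dgv_source = "dgv", rare_max = 0.01) {
  n <- nrow(calls)
  matched <- if ("matched" %in% names(calls)) calls$matched else rep(FALSE, n)
  best_freq <- if ("best_freq" %in% names(calls)) calls$best_freq else rep(NA_real_, n)
  sources <- if ("match_sources" %in% names(calls)) calls$match_sources
             else rep(NA_character_, n)
  rep_status <- if ("replicate_status" %in% names(calls)) calls$replicate_status
                else rep("not_evaluable", n)
  validation <- if ("validation_outcome" %in% names(calls)) calls$validation_outcome
                else rep("not_attempted", n)
  matched[is.na(matched)] <- FALSE
  on_db <- matched
  sources[is.na(sources)] <- ""
  dgv_hit <- matched &
    vapply(strsplit(sources, ","), function(s) dgv_source %in% s, logical(1))
  out <- mutate(calls,
                is_true = on_db | rep_status == "confirmed" |
                  validation == "validated",
                novelty = ifelse(dgv_hit & !is.na(best_freq) & best_freq > rare_max,
                                 "on_dgv", "novel"))
  class(out) <- unique(c("cgh_calls", class(out)))
  out
}

#' Classify a validation table of selected variants
#'
#' Applies the true-variant rule to a per-variant validation table (as
#' produced by orthogonal wet-lab follow-up): a variant is true when its
#' validation outcome is `"validated"`, it was confirmed on a replicate, or
#' it is reported in the population database; it is `on_dgv` only when the
#' reported frequency exceeds `rare_max`.
#'
#' @param validation tibble with columns `outcome`, `replicate_confirmed`
#'   (logical) and `dgv_freq` (numeric, `NA` when not reported).
#' @param rare_max very-low-frequency cutoff (default 0.01).
#' @return the table with added `is_true` and `novelty` columns.
#' @export
classify_validation <- function(validation, rare_max = 0.01) {
  mutate(validation,
         is_true = .data$outcome == "validated" |
           (!is.na(.data$replicate_confirmed) & .data$replicate_confirmed) |
           (!is.na(.data$dgv_freq) & .data$dgv_freq > 0),
         novelty = ifelse(!is.na(.data$dgv_freq) & .data$dgv_freq > rare_max,
                          "on_dgv", "novel"))
}

#' Count confirmed variants in the validation selection set
#'
#' @param validation a validation table (see [classify_validation()]); only
#'   rows with `selected == TRUE` are counted.
#' @param rare_max passed to [classify_validation()].
#' @return the number of selection-set variants that are true.
#' @export
count_confirmed <- function(validation, rare_max = 0.01) {
  if (nrow(validation) == 0) return(0L)
  cls <- classify_validation(validation, rare_max = rare_max)
  sum(cls$selected & cls$is_true)
}

# map raw phenotype values onto summary strata
form_stratum <- function(x) {
  dplyr::case_when(x %in% c("L", "TCA", "L/TCA") ~ "L/TCA",
                   x %in% c("S", "ultraS", "S/ultraS") ~ "S/ultraS",
                   TRUE ~ "unknown")
}

ret_stratum <- function(x) {
  ifelse(x %in% c("mutation", "deletion"), "yes", "no")
}

#' Stratified cohort summary of aberrations
#'
#' Per patient stratum (HSCR form, gender, syndromic status, RET anomaly),
#' counts patients analyzed, with any aberration, with a true aberration,
#' and with true aberrations reported / not reported in the population
#' database. A patient is counted once per column even with multiple
#' qualifying CNVs, so novelty sub-columns can sum to more than the true
#' column.
#'
#' @param cnvs truth-annotated CNVs: `sample_id`, `is_true`, `novelty`.
#' @param patients patient records: `sample_id`, `sex`, `hscr_form`,
#'   `syndromic`, `ret_status`.
#' @return a tibble with one row per (feature, level): `analyzed`,
#'   `with_aberration`, `with_true`, `true_on_dgv`, `true_not_on_dgv`.
#' @export
cohort_summary <- function(cnvs, patients) {
  unknown <- setdiff(unique(cnvs$sample_id), patients$sample_id)
  if (length(unknown) > 0) {
    abort(paste("CNVs reference unknown patient(s):",
                paste(unknown, collapse = ", ")))
  }
  pats <- mutate(patients,
                 form = form_stratum(.data$hscr_form),
                 ret = ret_stratum(.data$ret_status))
  per_patient <- pats %>%
    left_join(cnvs %>%
                group_by(.data$sample_id) %>%
                summarise(
                  has_aberration = dplyr::n() > 0,
                  has_true = any(.data$is_true),
                  has_true_on_dgv = any(.data$is_true & .data$novelty == "on_dgv"),
                  has_true_novel = any(.data$is_true & .data$novelty == "novel"),
                  .groups = "drop"),
              by = "sample_id") %>%
    mutate(across(dplyr::starts_with("has_"), ~ !is.na(.x) & .x))
  strata <- list(hscr_form = "form", gender = "sex", syndromic = "syndromic",
                 ret_anomaly = "ret")
  rows <- purrr::imap_dfr(strata, function(col, feat) {
    per_patient %>%
      group_by(level = .data[[col]]) %>%
      summarise(analyzed = dplyr::n(),
                with_aberration = sum(.data$has_aberration),
                with_true = sum(.data$has_true),
                true_on_dgv = sum(.data$has_true_on_dgv),
                true_not_on_dgv = sum(.data$has_true_novel),
                .groups = "drop") %>%
      mutate(feature = feat, .before = 1)
  })
  total <- per_patient %>%
    summarise(feature = "total", level = "all", analyzed = dplyr::n(),
              with_aberration = sum(.data$has_aberration),
              with_true = sum(.data$has_true),
              true_on_dgv = sum(.data$has_true_on_dgv),
              true_not_on_dgv = sum(.data$has_true_novel))
  dplyr::bind_rows(rows, total)
}

#' Compare CNV sizes between patient groups
#'
#' CNV length is `outer_end - outer_start + 1` (or a supplied `size` column).
#' Group medians are reported with a two-sided Wilcoxon rank-sum p-value;
#' when either group is empty the medians are still reported and the
#' p-value is `NA`.
#'
#' @param cnvs truth-annotated CNVs with `sample_id` (and `size` or outer
#'   boundaries).
#' @param patients patient records.
#' @param group_var grouping column of `patients` (e.g. `"syndromic"`).
#' @return a one-row tibble: per-group medians and counts, `p_value`.
#' @export
size_comparison <- function(cnvs, patients, group_var = "syndromic") {
  sizes <- if ("size" %in% names(cnvs)) cnvs$size
           else cnvs$outer_end - cnvs$outer_start + 1
  dat <- tibble(sample_id = cnvs$sample_id, size = sizes) %>%
    left_join(select(patients, "sample_id", dplyr::all_of(group_var)),
              by = "sample_id") %>%
    rename(group = dplyr::all_of(group_var))
  levels <- sort(unique(dat$group))
  if (length(levels) > 2) abort("size_comparison expects a two-level grouping")
  g1 <- dat$size[dat$group == levels[1]]
  g2 <- if (length(levels) == 2) dat$size[dat$group == levels[2]] else numeric(0)
  p <- if (length(g1) > 0 && length(g2) > 0) {
    suppressWarnings(stats::wilcox.test(g1, g2, exact = NULL)$p.value)
  } else NA_real_
  tibble(group1 = levels[1],
         group2 = if (length(levels) == 2) levels[2] else NA_character_,
         n1 = length(g1), n2 = length(g2),
         median1 = median(g1), median2 = if (length(g2)) median(g2) else NA_real_,
         p_value = p)
}

#' Bundled example cohort: patient records
#'
#' A 59-patient targeted Hirschsprung-disease cohort bundled with the
#' package: sex, disease form (S / L / TCA / unknown), syndromic status,
#' RET status (coding mutation, locus deletion, none, unknown) and RET risk
#' haplotype class. Used in examples and regression tests of the
#' classification stage.
#'
#' @return a tibble with one row per patient.
#' @export
hscr_patients <- function() {
  read_tsv_commented(system.file("extdata", "hscr59_patients.tsv",
                                 package = "cghcnv"))
}

#' Bundled example cohort: validation table
#'
#' Follow-up table for the aberrations of the bundled cohort that entered
#' orthogonal validation (plus one replicate-only confirmation): per
#' variant, the validation method and outcome, replicate confirmation,
#' population-database frequency when reported, selection status and
#' parental origin where parents were available.
#'
#' @return a tibble with one row per variant call.
#' @export
hscr_validation <- function() {
  read_tsv_commented(system.file("extdata", "hscr59_validation.tsv",
                                 package = "cghcnv"))
}
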