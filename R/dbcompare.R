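# Consistency matching of calls against population-CNV databases
# (DGV/gnomAD/DDD-style tables), frequency classification and
# case-control frequency tests.

# design probes (by coordinate) inside [s, e] on chrom
probes_in <- function(design, chrom, s, e) {
  which(design$chrom == chrom & design$start <= e & design$end >= s)
}

# The consistency rule shared by database matching, replicate concordance
# and parental-origin assignment: same kind (gain/loss), overlap at least
# `overlap_min` of the query call (optionally reciprocal), and no more than
# `max_probe_diff` differing probes on either side, counted on the design.
# When per-probe ratios for the query are supplied, only differing probes
# with a compatible amplitude (|log2 ratio| >= 0.3) are counted.
intervals_consistent <- function(call, entry, design, ratios = NULL,
                                 overlap_min = 0.8, max_probe_diff = 2,
                                 reciprocal = FALSE, compatible_abs = 0.3) {
  if (call$type != entry$type || call$chrom != entry$chrom) return(FALSE)
  ov <- min(call$inner_end, entry$end) - max(call$inner_start, entry$start) + 1
  if (ov <= 0) return(FALSE)
  len_call <- call$inner_end - call$inner_start + 1
  if (ov / len_call < overlap_min) return(FALSE)
  if (reciprocal) {
    len_entry <- entry$end - entry$start + 1
    if (ov / len_entry < overlap_min) return(FALSE)
  }
  p_call <- probes_in(design, call$chrom, call$inner_start, call$inner_end)
  p_entry <- probes_in(design, entry$chrom, entry$start, entry$end)
  out_call <- setdiff(p_call, p_entry)
  if (!is.null(ratios)) {
    out_call <- out_call[abs(ratios[out_call]) >= compatible_abs]
  }
  if (length(out_call) > max_probe_diff) return(FALSE)
  if (length(setdiff(p_entry, p_call)) > max_probe_diff) return(FALSE)
  TRUE
}

#' Match curated calls against population-CNV databases
#'
#' A call is consistent with a database entry when both are of the same kind
#' (gain or loss), they overlap by at least `overlap_min` of the call, and
#' neither extends beyond the other by more than `max_probe_diff` probes of
#' the design. Each call is annotated with its best (highest-frequency)
#' match per the databases provided.
#'
#' @param calls a `cgh_calls`/curated tibble.
#' @param db a `pop_db` tibble (possibly several sources bound together).
#' @param design the probe design, used to count differing probes.
#' @param overlap_min minimum overlap fraction of the call (default 0.80).
#' @param max_probe_diff maximum differing probes on either side (default 2).
#' @param reciprocal also require `overlap_min` of the database entry.
#' @return the calls with added columns `matched` (logical), `match_sources`
#'   (comma-separated labels), `best_freq` (highest matched frequency, `NA`
#'   when unmatched) and `frequency_class`.
#' @export
match_population <- function(calls, db, design, overlap_min = 0.8,
                             max_probe_diff = 2, reciprocal = FALSE) {
  unknown <- setdiff(unique(db$chrom), unique(design$chrom))
  if (length(unknown) > 0) {
    warn(paste("skipping database entries on unknown chromosome(s):",
               paste(unknown, collapse = ", ")))
    db <- db[!db$chrom %in% unknown, ]
  }
  res <- purrr::map_dfr(seq_len(nrow(calls)), function(i) {
    call <- calls[i, ]
    hit <- vapply(seq_len(nrow(db)), function(j) {
      intervals_consistent(call, db[j, ], design,
                           overlap_min = overlap_min,
                           max_probe_diff = max_probe_diff,
                           reciprocal = reciprocal)
    }, logical(1))
    if (!any(hit)) {
      return(tibble(matched = FALSE, match_sources = NA_character_,
                    best_freq = NA_real_))
    }
    tibble(matched = TRUE,
           match_sources = paste(sort(unique(db$source[hit])), collapse = ","),
           best_freq = max(db$frequency[hit]))
  })
  out <- dplyr::bind_cols(calls, res)
  out$frequency_class <- frequency_class(out$matched, out$best_freq)
  class(out) <- unique(c("cgh_calls", class(out)))
  out
}

#' Frequency class of a database match
#'
#' `common` above 5%, `rare` at or below 1% (but above zero), `intermediate`
#' in between, `novel` with no match at all.
#'
#' @param matched logical, was any consistent database entry found.
#' @param best_freq best matched frequency (ignored when unmatched).
#' @param common_min,rare_max class boundaries (defaults 0.05 and 0.01).
#' @return a character vector of classes.
#' @export
frequency_class <- function(matched, best_freq, common_min = 0.05,
                            rare_max = 0.01) {
  dplyr::case_when(
    !matched ~ "novel",
    best_freq > common_min ~ "common",
    best_freq > rare_max ~ "intermediate",
    TRUE ~ "rare"
  )
}

# two-sided exact Fisher p for a 2x2 table (the frequency_test fisher path)
fisher_p <- function(tab) stats::fisher.test(tab)$p.value

#' Case-control CNV frequency test
#'
#' Tests a 2x2 carriers-by-cohort table with Fisher's exact test, or the
#' chi-square test with Yates continuity correction when all expected cell
#' counts are at least 5. The odds ratio is taken from the raw table;
#' a Haldane 0.5 correction is applied (and flagged) only when a zero cell
#' makes it undefined.
#'
#' @param case_carriers,case_n carriers and total in the case cohort.
#' @param control_carriers,control_n carriers and total in the controls.
#' @return a `cgh_freq_test` object with elements `odds_ratio`, `p_value`,
#'   `method` (`"fisher"` or `"chisq_yates"`), `haldane`, `table`.
#' @export
#' @examples
#' frequency_test(3, 59, 3, 1000)
frequency_test <- function(case_carriers, case_n, control_carriers, control_n) {
  if (case_n <= 0 || control_n <= 0) abort("both cohorts must be non-empty")
  stopifnot(case_carriers >= 0, control_carriers >= 0,
            case_carriers <= case_n, control_carriers <= control_n)
  tab <- matrix(c(case_carriers, case_n - case_carriers,
                  control_carriers, control_n - control_carriers),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("case", "control"), c("carrier", "non_carrier")))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (!degenerate && all(expected >= 5)) {
    method <- "chisq_yates"
    p <- stats::chisq.test(tab, correct = TRUE)$p.value
  } else {
    method <- "fisher"
    p <- if (degenerate) 1 else fisher_p(tab)
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  haldane <- any(tab == 0)
  if (haldane) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
  structure(list(odds_ratio = (a * d) / (b * c_), p_value = p,
                 method = method, haldane = haldane, table = tab),
            class = "cgh_freq_test")
}

#' @export
print.cgh_freq_test <- function(x, ...) {
  cat(sprintf("CNV frequency test (%s): OR = %.3f%s, p = %.4g\n",
              x$method, x$odds_ratio,
              if (x$haldane) " [Haldane-corrected]" else "", x$p_value))
  invisible(x)
}

#' @method tidy cgh_freq_test
#' @export
tidy.cgh_freq_test <- function(x, ...) {
  tibble(estimate = x$odds_ratio, p.value = x$p_value, method = x$method,
         haldane = x$haldane)
}

#' @method glance cgh_freq_test
#' @export
glance.cgh_freq_test <- function(x, ...) tidy(x)

#' Per-locus cohort frequency report
#'
#' Groups the cohort's curated calls into consistent variants (recurrence
#' counting via the database consistency rule), then reports, per variant,
#' the sample frequency, each database source's frequency, and the
#' case-control frequency test against that source. Sources with no
#' consistent entry are reported as not tested.
#'
#' @param calls matched curated calls (from [match_population()]).
#' @param db a `pop_db` tibble with one or more sources.
#' @param design the probe design.
#' @param n_samples number of samples in the cohort.
#' @return a tibble with one row per (variant, source): variant coordinates,
#'   `carriers`, `sample_freq`, `source`, `db_freq`, `odds_ratio`,
#'   `p_value`, `method` (`NA` where not tested).
#' @export
cohort_frequency_report <- function(calls, db, design, n_samples) {
  if (nrow(calls) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  type = character(), carriers = integer(),
                  sample_freq = numeric(), source = character(),
                  db_freq = numeric(), odds_ratio = numeric(),
                  p_value = numeric(), method = character()))
  }
  grouped <- group_recurrent(calls, design)
  sources <- unique(db$source)
  purrr::map_dfr(unique(grouped$variant_group), function(g) {
    members <- grouped[grouped$variant_group == g, ]
    rep_call <- members[1, ]
    carriers <- length(unique(members$sample_id))
    purrr::map_dfr(sources, function(src) {
      sdb <- db[db$source == src, ]
      hit <- vapply(seq_len(nrow(sdb)), function(j) {
        intervals_consistent(rep_call, sdb[j, ], design)
      }, logical(1))
      base <- tibble(chrom = rep_call$chrom, start = rep_call$inner_start,
                     end = rep_call$inner_end, type = rep_call$type,
                     carriers = carriers,
                     sample_freq = carriers / n_samples, source = src)
      if (!any(hit)) {
        return(mutate(base, db_freq = NA_real_, odds_ratio = NA_real_,
                      p_value = NA_real_, method = NA_character_))
      }
      entry <- sdb[which(hit)[which.max(sdb$frequency[hit])], ]
      ft <- frequency_test(carriers, n_samples, entry$carriers, entry$cohort)
      mutate(base, db_freq = entry$frequency, odds_ratio = ft$odds_ratio,
             p_value = ft$p_value, method = ft$method)
    })
  })
}

# assign calls to recurrence groups: a call joins the first group whose
# representative (first member) it is consistent with
group_recurrent <- function(calls, design) {
  calls <- arrange(calls, chrom_factor(.data$chrom), .data$inner_start,
                   .data$inner_end)
  groups <- list()
  gid <- integer(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    assigned <- FALSE
    for (g in seq_along(groups)) {
      if (intervals_consistent(calls[i, ],
                               tibble(chrom = groups[[g]]$chrom,
                                      start = groups[[g]]$inner_start,
                                      end = groups[[g]]$inner_end,
                                      type = groups[[g]]$type),
                               design)) {
        gid[i] <- g
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      groups[[length(groups) + 1]] <- calls[i, ]
      gid[i] <- length(groups)
    }
  }
  mutate(calls, variant_group = gid)
}

#' Count cohort recurrence of each call's consistent variant
#'
#' @param calls curated calls for the whole cohort.
#' @param design the probe design.
#' @return the calls with `variant_group` and `recurrence` (number of
#'   distinct samples sharing the consistent variant).
#' @export
count_recurrence <- function(calls, design) {
  if (nrow(calls) == 0) {
    return(mutate(calls, variant_group = integer(), recurrence = integer()))
  }
  grouped <- group_recurrent(calls, design)
  grouped %>%
    group_by(.data$variant_group) %>%
    mutate(recurrence = length(unique(.data$sample_id))) %>%
    ungroup()
}
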