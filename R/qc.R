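# Per-sample QC and normalization: DLRS noise estimation, the replication
# gate, median centralization and linear GC correction.

# DLRS of one log2 vector split by chromosome; differences are never taken
# across chromosome boundaries. IQR(diff)/(1.349*sqrt(2)) estimates the
# per-probe noise SD robustly.
dlrs_vector <- function(x, chrom) {
  if (length(x) < 3) abort("DLRS undefined for fewer than 3 probes")
  d <- unlist(lapply(split(x, factor(chrom, levels = unique(chrom))), diff),
              use.names = FALSE)
  stats::IQR(d) / (1.349 * sqrt(2))
}

#' Derivative log ratio spread (DLRS) per sample
#'
#' DLRS is the robust per-sample noise estimate: the IQR of consecutive-probe
#' log2-ratio differences within chromosomes, divided by `1.349 * sqrt(2)` so
#' that an i.i.d. Gaussian profile with SD sigma measures approximately sigma.
#'
#' @param profiles a `cgh_profiles` tibble (one or many samples).
#' @return a tibble: `sample_id`, `dlrs`.
#' @export
compute_dlrs <- function(profiles) {
  profiles %>%
    group_by(.data$sample_id) %>%
    summarise(dlrs = dlrs_vector(.data$log2ratio, .data$chrom),
              .groups = "drop")
}

#' QC gate: flag noisy samples for replication
#'
#' Samples with DLRS at or above `gate` get `replicate_required`; the
#' boundary is inclusive.
#'
#' @param profiles a `cgh_profiles` tibble.
#' @param gate DLRS threshold (default 0.3).
#' @return a QC report tibble: `sample_id`, `dlrs`, `qc_flag`.
#' @export
qc_gate <- function(profiles, gate = 0.3) {
  compute_dlrs(profiles) %>%
    mutate(qc_flag = ifelse(.data$dlrs >= gate, "replicate_required", "pass"))
}

#' Centralize profiles so the median log2 ratio is zero
#'
#' Subtracts the per-sample median over autosomal probes (all probes on
#' chrX/chrY are excluded from the estimate but shifted along). Idempotent.
#'
#' @param profiles a `cgh_profiles` tibble.
#' @return the profiles with `log2ratio` recentred.
#' @export
centralize <- function(profiles) {
  out <- profiles %>%
    group_by(.data$sample_id) %>%
    mutate(log2ratio = .data$log2ratio -
             median(.data$log2ratio[!.data$chrom %in% c("chrX", "chrY")])) %>%
    ungroup()
  class(out) <- class(profiles)
  out
}

#' Remove a linear GC trend from each sample
#'
#' Fits `log2ratio ~ (gc - mean(gc))` by least squares per sample and
#' subtracts the fitted trend, leaving the residual correlation with GC
#' near zero. With constant GC across probes the profile is returned
#' unchanged with a warning.
#'
#' @param profiles a `cgh_profiles` tibble carrying a `gc` column.
#' @return the corrected profiles.
#' @export
gc_correct <- function(profiles) {
  if (stats::var(profiles$gc) == 0) {
    warn("gc is constant across probes; GC correction is a no-op")
    return(profiles)
  }
  out <- profiles %>%
    group_by(.data$sample_id) %>%
    mutate(log2ratio = {
      gcc <- .data$gc - mean(.data$gc)
      slope <- sum(gcc * .data$log2ratio) / sum(gcc^2)
      .data$log2ratio - slope * gcc
    }) %>%
    ungroup()
  class(out) <- class(profiles)
  out
}

#' Full preprocessing: centralization then GC correction, plus QC report
#'
#' @param profiles a `cgh_profiles` tibble.
#' @param dlrs_gate DLRS replication gate (applied after correction).
#' @return a list: `profiles` (corrected), `qc` (per-sample report).
#' @export
preprocess <- function(profiles, dlrs_gate = 0.3) {
  corrected <- gc_correct(centralize(profiles))
  list(profiles = corrected, qc = qc_gate(corrected, gate = dlrs_gate))
}
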