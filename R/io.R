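# Interchange formats and run configuration.
#
# Internal coordinates are 1-based, fully closed ("chr:start-end"); BED
# (0-based, half-open) is produced/consumed only at the I/O boundary.
# Every output file carries a header comment with tool version, config
# hash and seed; readers skip comment lines.

# stable polynomial hash of a string, hex-encoded (no digest dependency);
# exact in doubles: intermediates stay far below 2^53
str_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

cgh_header <- function(seed = NULL, config = NULL) {
  paste0("# cghcnv ", as.character(packageVersion("cghcnv")),
         "; seed=", if (is.null(seed)) "NA" else seed,
         "; config=", if (is.null(config)) "NA"
         else str_hash(yaml::as.yaml(config)))
}

#' Write a table as TSV with a provenance header comment
#'
#' @param x a data frame.
#' @param path output path.
#' @param seed,config recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_cgh_tsv <- function(x, path, seed = NULL, config = NULL) {
  writeLines(cgh_header(seed, config), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_tsv_commented <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Read a table written by [write_cgh_tsv()]
#' @param path input path.
#' @return a tibble.
#' @export
read_cgh_tsv <- function(path) read_tsv_commented(path)

#' Convert 1-based closed intervals to BED (0-based half-open) and back
#'
#' @param start,end interval boundaries.
#' @return a tibble with converted boundaries.
#' @export
to_bed_coords <- function(start, end) tibble(start = start - 1, end = end)

#' @rdname to_bed_coords
#' @export
from_bed_coords <- function(start, end) tibble(start = start + 1, end = end)

#' Export a probe design as BED6
#'
#' @param design a `cgh_design` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design_bed <- function(design, path) {
  bed <- tibble(chrom = design$chrom, start = design$start - 1,
                end = design$end, name = design$probe_id, score = 0,
                strand = ".")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Export calls as extended BED
#'
#' BED columns use the outer boundaries (0-based half-open) with the
#' absolute score capped at 1000; the extra columns keep type, probe
#' count, MALR, 1-based inner coordinates and source.
#'
#' @param calls a `cgh_calls` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path) {
  bed <- tibble(chrom = calls$chrom, start = calls$outer_start - 1,
                end = calls$outer_end, name = calls$sample_id,
                score = pmin(round(abs(ifelse(is.na(calls$score), 0,
                                              calls$score)), 2), 1000),
                strand = ".", type = calls$type,
                probe_count = calls$probe_count, malr = calls$malr,
                inner_start = calls$inner_start, inner_end = calls$inner_end,
                source = calls$source)
  readr::write_tsv(bed, path, col_names = TRUE)
  invisible(path)
}

#' Read calls from the extended BED dialect
#' @param path input path.
#' @return a `cgh_calls`-shaped tibble (1-based internal coordinates).
#' @export
read_calls_bed <- function(path) {
  bed <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  out <- tibble(sample_id = bed$name, chrom = bed$chrom,
                inner_start = bed$inner_start, inner_end = bed$inner_end,
                outer_start = bed$start + 1, outer_end = bed$end,
                type = bed$type, probe_count = bed$probe_count,
                score = bed$score, malr = bed$malr, source = bed$source)
  class(out) <- c("cgh_calls", class(out))
  out
}

#' Validate a cohort manifest
#'
#' @param manifest a tibble with at least `sample_id`.
#' @return the manifest, invisibly; duplicate sample ids are an error that
#'   names the offending rows.
#' @export
validate_manifest <- function(manifest) {
  dup <- which(duplicated(manifest$sample_id))
  if (length(dup) > 0) {
    abort(paste0("duplicate sample_id in manifest at row(s) ",
                 paste(dup, collapse = ", "), ": ",
                 paste(unique(manifest$sample_id[dup]), collapse = ", ")))
  }
  invisible(manifest)
}

## ---- run configuration ----------------------------------------------------

#' Default run configuration
#'
#' All thresholds of the pipeline in one nested list: segmentation score
#' threshold 6, curation MALR > 0.30 with >= 2 probes, DLRS replication
#' gate 0.3, database-matching overlap >= 0.80 with <= 2 differing probes,
#' frequency bands at 5% / 1%, alpha 0.05 and a one-sided binomial
#' transmission test.
#'
#' @param seed integer seed recorded with every run.
#' @return a named list of class `cgh_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    segmentation = list(threshold = 6),
    qc = list(dlrs_gate = 0.3),
    curation = list(malr_min = 0.30, min_probes = 2,
                    triage = list(likely_gain = 0.5, likely_loss = -1.0,
                                  unlikely_malr = 0.35, weak_two_probe = 0.4)),
    matching = list(overlap_min = 0.80, max_probe_diff = 2),
    frequency = list(common = 0.05, rare = 0.01),
    stats = list(alpha = 0.05, binomial_sided = "one")
  ), class = "cgh_config")
}

check_config_keys <- function(config, reference, path = "") {
  extra <- setdiff(names(config), names(reference))
  if (length(extra) > 0) {
    abort(paste0("unknown config key(s): ",
                 paste0(path, extra, collapse = ", ")))
  }
  for (k in names(config)) {
    if (is.list(reference[[k]])) {
      check_config_keys(config[[k]], reference[[k]], paste0(path, k, "."))
    }
  }
  invisible(config)
}

#' Read / write a run configuration (YAML)
#'
#' Unknown keys are errors, not warnings; missing keys fall back to the
#' defaults, so a config round-trips losslessly through its file.
#'
#' @param path YAML file path.
#' @return `read_config()` returns a `cgh_config` list; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ref <- default_config()
  check_config_keys(raw, ref)
  merged <- utils::modifyList(ref, raw)
  class(merged) <- "cgh_config"
  merged
}

#' @rdname read_config
#' @param config a `cgh_config` list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
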