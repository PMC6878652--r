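# Interval-score segmentation: a documented stand-in for commercial
# aberration detection (ADM-style) run at score threshold 6, plus the
# deterministic emulation of whole-genome visual inspection.

#' Interval score of a probe interval
#'
#' `S = sum(log2 ratios) / (sigma * sqrt(probe count))`; the sign of `S`
#' gives the aberration type. Scale-equivariant: multiplying the ratios and
#' `sigma` by the same positive constant leaves `S` unchanged.
#'
#' @param x numeric log2 ratios of the member probes.
#' @param sigma noise SD (> 0), typically the sample DLRS.
#' @return the interval score, a single real.
#' @export
#' @examples
#' interval_score(rep(0.58, 10), sigma = 0.2)
interval_score <- function(x, sigma) {
  if (sigma <= 0) abort("sigma must be > 0")
  if (length(x) == 0) abort("interval is empty")
  sum(x) / (sigma * sqrt(length(x)))
}

# assemble an AberrationCall tibble from chromosome-local probe indices.
# inner boundaries: first/last aberrant probe; outer: flanking normal probes
# (clamped to the inner boundary at chromosome ends).
build_calls <- function(sub, idx_mat, sample_id, source) {
  if (nrow(idx_mat) == 0) return(empty_calls())
  purrr::map_dfr(seq_len(nrow(idx_mat)), function(k) {
    i <- as.integer(idx_mat[k, 1]); j <- as.integer(idx_mat[k, 2])
    member <- sub$log2ratio[i:j]
    tibble(
      sample_id = sample_id,
      chrom = sub$chrom[1],
      inner_start = sub$start[i], inner_end = sub$end[j],
      outer_start = if (i > 1) sub$start[i - 1] else sub$start[i],
      outer_end = if (j < nrow(sub)) sub$end[j + 1] else sub$end[j],
      type = if (mean(member) > 0) "gain" else "loss",
      probe_count = j - i + 1L,
      score = idx_mat[k, 3],
      mean_ratio = mean(member),
      malr = mean(abs(member)),
      source = source
    )
  })
}

empty_calls <- function() {
  out <- tibble(sample_id = character(), chrom = character(),
                inner_start = numeric(), inner_end = numeric(),
                outer_start = numeric(), outer_end = numeric(),
                type = character(), probe_count = integer(),
                score = numeric(), mean_ratio = numeric(), malr = numeric(),
                source = character())
  class(out) <- c("cgh_calls", class(out))
  out
}

#' Detect aberrant intervals by maximal interval score
#'
#' Per sample and chromosome, repeatedly extracts the interval with maximal
#' absolute score `S = sum(x) / (sigma * sqrt(n))`, keeps it when
#' `|S| >= threshold`, and recurses on the flanks, yielding disjoint maximal
#' intervals. Ties are broken by leftmost start, then shortest length.
#' `sigma` defaults to each sample's DLRS.
#'
#' @param profiles a centralized, GC-corrected `cgh_profiles` tibble.
#' @param threshold score threshold (default 6).
#' @param sigma noise SD; `NULL` (default) uses each sample's DLRS, a single
#'   number applies to all samples.
#' @return a `cgh_calls` tibble of aberration calls with inner/outer
#'   boundaries, probe count, score, mean ratio, MALR and `source`
#'   `"software"`.
#' @export
detect_aberrations <- function(profiles, threshold = 6, sigma = NULL) {
  sig_tbl <- if (is.null(sigma)) compute_dlrs(profiles) else NULL
  samples <- unique(profiles$sample_id)
  out <- purrr::map_dfr(samples, function(s) {
    prof <- profiles[profiles$sample_id == s, ]
    sig <- if (is.null(sigma)) sig_tbl$dlrs[sig_tbl$sample_id == s] else sigma
    if (sig <= 0) abort("sigma must be > 0")
    purrr::map_dfr(split(seq_len(nrow(prof)), factor(prof$chrom,
                                                     levels = unique(prof$chrom))),
                   function(rows) {
      sub <- prof[rows, ]
      m <- greedy_max_intervals(sub$log2ratio, sig, threshold)
      build_calls(sub, m, s, "software")
    })
  })
  if (nrow(out) == 0) return(empty_calls())
  out <- arrange(out, .data$sample_id, chrom_factor(.data$chrom), .data$inner_start)
  class(out) <- c("cgh_calls", class(out))
  out
}

# run starts/ends of a logical vector
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Deterministic emulation of the visual-inspection rescue step
#'
#' Whole-genome manual review pays attention to log2 ratios above 0.5 and
#' below -1.0. This emulation flags runs of at least `min_run` consecutive
#' probes all above `gain_cut` (gain) or all below `loss_cut` (loss) that do
#' not overlap an existing call of the sample, and marks them
#' `source = "visual"`.
#'
#' @param profiles a `cgh_profiles` tibble.
#' @param calls existing software calls (a `cgh_calls` tibble).
#' @param gain_cut,loss_cut amplitude cuts (defaults +0.5 / -1.0, strict).
#' @param min_run minimum run length (default 2 probes).
#' @return the rescued calls only, a `cgh_calls` tibble with
#'   `source = "visual"` and `score = NA`.
#' @export
visual_rescue <- function(profiles, calls, gain_cut = 0.5, loss_cut = -1.0,
                          min_run = 2) {
  out <- purrr::map_dfr(unique(profiles$sample_id), function(s) {
    prof <- profiles[profiles$sample_id == s, ]
    scalls <- calls[calls$sample_id == s, ]
    purrr::map_dfr(split(seq_len(nrow(prof)), factor(prof$chrom,
                                                     levels = unique(prof$chrom))),
                   function(rows) {
      sub <- prof[rows, ]
      cc <- scalls[scalls$chrom == sub$chrom[1], ]
      hits <- NULL
      for (dir in c("gain", "loss")) {
        flag <- if (dir == "gain") sub$log2ratio > gain_cut
                else sub$log2ratio < loss_cut
        rn <- runs_of(flag)
        rn <- rn[rn[, 2] - rn[, 1] + 1L >= min_run, , drop = FALSE]
        if (nrow(rn) == 0) next
        # drop runs overlapping an existing call (by probe coordinates)
        keep <- vapply(seq_len(nrow(rn)), function(k) {
          s0 <- sub$start[rn[k, 1]]; e0 <- sub$end[rn[k, 2]]
          !any(cc$inner_start <= e0 & cc$inner_end >= s0)
        }, logical(1))
        rn <- rn[keep, , drop = FALSE]
        if (nrow(rn) > 0) {
          hits <- rbind(hits, cbind(rn, score = NA_real_))
        }
      }
      if (is.null(hits)) return(empty_calls())
      build_calls(sub, hits, s, "visual")
    })
  })
  if (nrow(out) == 0) return(empty_calls())
  out <- arrange(out, .data$sample_id, chrom_factor(.data$chrom), .data$inner_start)
  class(out) <- c("cgh_calls", class(out))
  out
}
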