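# Rule-based curation of raw aberration calls: probe-count and MALR
# filters, split/merge of nearby intervals, triage emulation of visual
# classification, and replicate concordance.

#' Filter raw calls on probe count and MALR
#'
#' Software calls are retained with at least `min_probes` consecutive probes
#' and a mean absolute log2 ratio strictly above `malr_min`. Calls from the
#' visual-inspection rescue are exempt from the MALR filter (the probe-count
#' rule still applies).
#'
#' @param calls a `cgh_calls` tibble.
#' @param malr_min MALR threshold (default 0.30, strict).
#' @param min_probes minimum consecutive probes (default 2).
#' @return the retained calls (a subset of the input; idempotent).
#' @export
filter_calls <- function(calls, malr_min = 0.30, min_probes = 2) {
  out <- dplyr::filter(calls,
                       .data$probe_count >= min_probes,
                       .data$source == "visual" | .data$malr > malr_min)
  class(out) <- unique(c("cgh_calls", class(out)))
  out
}

#' Split and merge nearby aberrant intervals into distinct CNVs
#'
#' Two passes, both idempotent in combination. Split: a call whose interior
#' contains a run of at least 2 consecutive probes opposing the call's sign
#' at |log2 ratio| > `oppose_abs` is cut at that run — the flanks are
#' evidence of distinct events. Merge: adjacent calls of the same sample,
#' chromosome and type separated by at most `max_gap` intervening probes
#' are merged into one CNV, unless the intervening region contains a probe
#' opposing the calls' sign at |log2 ratio| > `oppose_abs`. More than
#' `max_gap` intervening probes always keeps them separate.
#'
#' @param calls a `cgh_calls` tibble.
#' @param profiles the profiles the calls were made on (used to inspect
#'   intervening probes and recompute merged-call statistics).
#' @param max_gap maximum intervening probes to merge across (default 2).
#' @param oppose_abs amplitude above which an intervening probe of opposite
#'   sign blocks merging (default 0.3).
#' @param sigma noise SD for rescoring merged calls; `NULL` uses each
#'   sample's DLRS.
#' @return the calls with qualifying neighbours merged.
#' @export
# recompute a call row over chromosome-local probe rows i..j
rebuild_call <- function(call, prof, i, j, sig) {
  x <- prof$log2ratio[i:j]
  call$inner_start <- prof$start[i]
  call$inner_end <- prof$end[j]
  call$outer_start <- if (i > 1) prof$start[i - 1] else prof$start[i]
  call$outer_end <- if (j < nrow(prof)) prof$end[j + 1] else prof$end[j]
  call$probe_count <- as.integer(j - i + 1)
  call$score <- interval_score(x, sig)
  call$mean_ratio <- mean(x)
  call$malr <- mean(abs(x))
  call
}

# cut one call at interior runs of >= 2 probes opposing its sign
split_one <- function(call, prof, type, oppose_abs, sig) {
  member <- which(prof$start <= call$inner_end & prof$end >= call$inner_start)
  if (length(member) == 0) return(call)
  i0 <- min(member); j0 <- max(member)
  opp <- if (type == "gain") prof$log2ratio < -oppose_abs
         else prof$log2ratio > oppose_abs
  r <- rle(opp[i0:j0])
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= 2 & starts > 1 & ends < (j0 - i0 + 1))
  if (length(runs) == 0) return(rebuild_call(call, prof, i0, j0, sig))
  cut <- runs[1]
  left <- rebuild_call(call, prof, i0, i0 + starts[cut] - 2L, sig)
  right <- call
  right$inner_start <- prof$start[i0 + ends[cut]]
  dplyr::bind_rows(left, split_one(right, prof, type, oppose_abs, sig))
}

split_merge <- function(calls, profiles, max_gap = 2, oppose_abs = 0.3,
                        sigma = NULL) {
  if (nrow(calls) == 0) return(calls)
  # contract check: overlapping same-sample calls of opposite type
  for (s in unique(calls$sample_id)) {
    cc <- calls[calls$sample_id == s, ]
    if (nrow(cc) > 1) {
      for (i in seq_len(nrow(cc) - 1)) {
        for (j in (i + 1):nrow(cc)) {
          if (cc$chrom[i] == cc$chrom[j] && cc$type[i] != cc$type[j] &&
              cc$inner_start[i] <= cc$inner_end[j] &&
              cc$inner_end[i] >= cc$inner_start[j]) {
            abort("overlapping opposite-type calls in one sample: segmentation contract violated")
          }
        }
      }
    }
  }
  sig_tbl <- if (is.null(sigma)) compute_dlrs(profiles) else NULL
  out <- calls %>%
    group_by(.data$sample_id, .data$chrom, .data$type) %>%
    dplyr::group_modify(function(grp, key) {
      prof <- profiles[profiles$sample_id == key$sample_id &
                         profiles$chrom == key$chrom, ]
      prof <- arrange(prof, .data$start)
      sig <- if (is.null(sigma)) sig_tbl$dlrs[sig_tbl$sample_id == key$sample_id]
             else sigma
      # split pass: cut calls at interior opposing runs of >= 2 probes
      grp <- purrr::map_dfr(seq_len(nrow(grp)), function(i) {
        split_one(grp[i, ], prof, key$type, oppose_abs, sig)
      })
      if (nrow(grp) < 2) return(grp)
      grp <- arrange(grp, .data$inner_start)
      merged <- grp[1, ]
      for (i in 2:nrow(grp)) {
        cur <- merged[nrow(merged), ]
        nxt <- grp[i, ]
        between <- prof$start > cur$inner_end & prof$end < nxt$inner_start
        gap_ratios <- prof$log2ratio[between]
        opposes <- if (key$type == "gain") gap_ratios < -oppose_abs
                   else gap_ratios > oppose_abs
        if (sum(between) <= max_gap && !any(opposes)) {
          member <- prof$start >= cur$inner_start & prof$end <= nxt$inner_end
          x <- prof$log2ratio[member]
          cur$inner_end <- nxt$inner_end
          cur$outer_end <- nxt$outer_end
          cur$probe_count <- sum(member)
          cur$score <- interval_score(x, sig)
          cur$mean_ratio <- mean(x)
          cur$malr <- mean(abs(x))
          cur$source <- if (any(c(cur$source, nxt$source) == "software"))
            "software" else "visual"
          merged[nrow(merged), ] <- cur
        } else {
          merged <- dplyr::bind_rows(merged, nxt)
        }
      }
      merged
    }) %>%
    ungroup() %>%
    select(dplyr::all_of(names(calls))) %>%
    arrange(.data$sample_id, chrom_factor(.data$chrom), .data$inner_start)
  class(out) <- unique(c("cgh_calls", class(out)))
  out
}

#' Triage calls as likely / possible / unlikely
#'
#' Deterministic emulation of visual classification: `likely` when the mean
#' ratio reaches the visual attention bands (>= `likely_gain` for gains,
#' <= `likely_loss` for losses); `unlikely` when the MALR is at or below
#' `unlikely_malr`, or the call has exactly 2 probes with |mean| below
#' `weak_two_probe`; `possible` otherwise. Triage only labels calls, it
#' never removes them.
#'
#' @param calls a `cgh_calls` tibble.
#' @param likely_gain,likely_loss attention bands (defaults +0.5 / -1.0).
#' @param unlikely_malr MALR at or below which a call is unlikely (0.35).
#' @param weak_two_probe |mean ratio| below which a 2-probe call is
#'   unlikely (0.4).
#' @return the calls with an added `triage` column.
#' @export
triage <- function(calls, likely_gain = 0.5, likely_loss = -1.0,
                   unlikely_malr = 0.35, weak_two_probe = 0.4) {
  out <- mutate(calls, triage = dplyr::case_when(
    .data$type == "gain" & .data$mean_ratio >= likely_gain ~ "likely",
    .data$type == "loss" & .data$mean_ratio <= likely_loss ~ "likely",
    .data$malr <= unlikely_malr ~ "unlikely",
    .data$probe_count == 2 & abs(.data$mean_ratio) < weak_two_probe ~ "unlikely",
    TRUE ~ "possible"
  ))
  class(out) <- unique(c("cgh_calls", class(out)))
  out
}

#' Replicate concordance of each call
#'
#' For a call of a replicated sample: `confirmed` when a consistent call
#' (same consistency rule as database matching) exists in a replicate
#' array; `not_excluded` when some replicate trends in the same direction
#' over the call's interval (matching mean sign, |mean| > `trend_abs`)
#' without a call; `not_confirmed` otherwise; `not_evaluable` when the
#' sample has no replicate. Replicate linkage is read from the profiles'
#' `replicate_group` column.
#'
#' @param calls a `cgh_calls` tibble for the primary samples.
#' @param profiles all profiles, including replicate arrays.
#' @param design the probe design.
#' @param rep_calls optional precomputed calls on the replicate arrays;
#'   computed with [detect_aberrations()] at `threshold` when `NULL`.
#' @param threshold segmentation threshold for replicate calls.
#' @param trend_abs same-direction trend threshold (default 0.15).
#' @return the calls with an added `replicate_status` column.
#' @export
replicate_concordance <- function(calls, profiles, design, rep_calls = NULL,
                                  threshold = 6, trend_abs = 0.15) {
  rep_map <- profiles %>%
    distinct(.data$sample_id, .data$replicate_group) %>%
    dplyr::filter(!is.na(.data$replicate_group),
                  .data$sample_id != .data$replicate_group)
  if (is.null(rep_calls) && nrow(rep_map) > 0) {
    rep_prof <- profiles[profiles$sample_id %in% rep_map$sample_id, ]
    rep_calls <- detect_aberrations(rep_prof, threshold = threshold)
  }
  status <- vapply(seq_len(nrow(calls)), function(i) {
    call <- calls[i, ]
    reps <- rep_map$sample_id[rep_map$replicate_group == call$sample_id]
    if (length(reps) == 0) return("not_evaluable")
    rc <- rep_calls[rep_calls$sample_id %in% reps, ]
    if (nrow(rc) > 0) {
      hit <- vapply(seq_len(nrow(rc)), function(j) {
        intervals_consistent(call, tibble(chrom = rc$chrom[j],
                                          start = rc$inner_start[j],
                                          end = rc$inner_end[j],
                                          type = rc$type[j]), design)
      }, logical(1))
      if (any(hit)) return("confirmed")
    }
    trend <- vapply(reps, function(r) {
      sub <- profiles[profiles$sample_id == r &
                        profiles$chrom == call$chrom &
                        profiles$start <= call$inner_end &
                        profiles$end >= call$inner_start, ]
      if (nrow(sub) == 0) return(FALSE)
      m <- mean(sub$log2ratio)
      abs(m) > trend_abs && sign(m) == (if (call$type == "gain") 1 else -1)
    }, logical(1))
    if (any(trend)) "not_excluded" else "not_confirmed"
  }, character(1))
  out <- mutate(calls, replicate_status = status)
  class(out) <- unique(c("cgh_calls", class(out)))
  out
}
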