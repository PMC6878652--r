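truth_call <- function(sample_id, is_true = TRUE, novelty = "novel",
                       size = 10000) {
  tibble::tibble(sample_id = sample_id, is_true = is_true, novelty = novelty,
                 size = size)
}

test_that("classify_truth combines the three evidence channels", {
  base <- tibble::tibble(sample_id = "S1", chrom = "chr1",
                         inner_start = 1e6, inner_end = 1.1e6,
                         type = "loss", probe_count = 5L)
  # on DGV at 6%: true, on_dgv, no other evidence needed
  a <- classify_truth(dplyr::mutate(base, matched = TRUE, best_freq = 0.06,
                                    match_sources = "dgv"))
  expect_true(a$is_true)
  expect_equal(a$novelty, "on_dgv")
  # no match, failed validation, no replicate: not true
  b <- classify_truth(dplyr::mutate(base, matched = FALSE,
                                    best_freq = NA_real_,
                                    match_sources = NA_character_,
                                    validation_outcome = "failed"))
  expect_false(b$is_true)
  # inconclusive validation but replicate-confirmed: true
  c_ <- classify_truth(dplyr::mutate(base, matched = FALSE,
                                     best_freq = NA_real_,
                                     match_sources = NA_character_,
                                     replicate_status = "confirmed",
                                     validation_outcome = "not_conclusive"))
  expect_true(c_$is_true)
  expect_equal(c_$novelty, "novel")
  # matched on DGV only at very low frequency: true but counted novel
  d_ <- classify_truth(dplyr::mutate(base, matched = TRUE, best_freq = 0.008,
                                     match_sources = "dgv"))
  expect_true(d_$is_true)
  expect_equal(d_$novelty, "novel")
})

test_that("classify_truth is monotone in added evidence", {
  base <- tibble::tibble(sample_id = "S1", chrom = "chr1", inner_start = 1e6,
                         inner_end = 1.1e6, type = "loss", probe_count = 5L,
                         matched = FALSE, best_freq = NA_real_,
                         match_sources = NA_character_,
                         replicate_status = "not_evaluable",
                         validation_outcome = "not_attempted")
  expect_false(classify_truth(base)$is_true)
  for (extra in list(
    dplyr::mutate(base, matched = TRUE, best_freq = 0.2, match_sources = "dgv"),
    dplyr::mutate(base, replicate_status = "confirmed"),
    dplyr::mutate(base, validation_outcome = "validated")
  )) {
    expect_true(classify_truth(extra)$is_true)
  }
})

test_that("the bundled validation table reproduces its confirmation funnel", {
  v <- hscr_validation()
  expect_equal(sum(v$selected), 18)
  expect_equal(count_confirmed(v), 11)
  cls <- classify_validation(v)
  # replicate-confirmed unselected variant joins the novel true set
  expect_equal(sum(cls$is_true & cls$novelty == "novel"), 12)
  expect_equal(length(unique(cls$sample_id[cls$selected & cls$is_true])), 11)
  # all outcomes failed: nothing confirmed
  none <- dplyr::mutate(v, outcome = "failed", replicate_confirmed = NA,
                        dgv_freq = NA_real_)
  expect_equal(count_confirmed(none), 0)
})

test_that("cohort_summary reproduces the bundled cohort's strata", {
  pats <- hscr_patients()
  expect_equal(nrow(pats), 59)
  cls <- classify_validation(hscr_validation())
  cnvs <- dplyr::filter(cls, is_true)
  s <- cohort_summary(cnvs, pats)
  ret_yes <- s[s$feature == "ret_anomaly" & s$level == "yes", ]
  expect_equal(ret_yes$analyzed, 14)
  expect_equal(ret_yes$true_not_on_dgv, 5)
  tot <- s[s$feature == "total", ]
  expect_equal(tot$analyzed, 59)
  expect_equal(tot$true_not_on_dgv, 11)
  f <- s[s$feature == "gender" & s$level == "F", ]
  expect_equal(f$analyzed, 17)
  expect_equal(f$true_not_on_dgv, 4)
  sform <- s[s$feature == "hscr_form" & s$level == "S/ultraS", ]
  expect_equal(sform$analyzed, 30)
  expect_equal(sform$true_not_on_dgv, 7)
})

test_that("patients with multiple true CNVs are counted once per column", {
  pats <- tibble::tibble(sample_id = c("P1", "P2"), sex = "M",
                         hscr_form = "S", syndromic = "no",
                         ret_status = "none")
  cnvs <- dplyr::bind_rows(
    truth_call("P1", novelty = "on_dgv"),
    truth_call("P1", novelty = "novel"),
    truth_call("P2", is_true = FALSE)
  )
  s <- cohort_summary(cnvs, pats)
  tot <- s[s$feature == "total", ]
  expect_equal(tot$with_aberration, 2)
  expect_equal(tot$with_true, 1)
  # one patient contributes to both novelty columns: their sum exceeds with_true
  expect_equal(tot$true_on_dgv + tot$true_not_on_dgv, 2)
  # column ordering invariants
  expect_lte(tot$with_true, tot$with_aberration)
  expect_lte(tot$true_on_dgv, tot$with_true)
  expect_lte(tot$true_not_on_dgv, tot$with_true)
  # no CNVs at all: zero everywhere
  s0 <- cohort_summary(cnvs[0, ], pats)
  expect_true(all(s0$with_aberration == 0 & s0$with_true == 0))
  expect_error(cohort_summary(truth_call("P9"), pats), "unknown patient")
})

test_that("size comparison reports medians and a rank-sum p-value", {
  pats <- tibble::tibble(sample_id = sprintf("P%d", 1:6), sex = "M",
                         hscr_form = "S",
                         syndromic = rep(c("yes", "no"), each = 3),
                         ret_status = "none")
  # equal groups: p = 1
  eq <- size_comparison(
    dplyr::bind_rows(purrr::map2_dfr(pats$sample_id, rep(c(1e4, 2e4, 3e4), 2),
                                     ~truth_call(.x, size = .y))),
    pats)
  expect_equal(eq$median1, eq$median2)
  expect_gt(eq$p_value, 0.99)
  # syndromic group planted multi-Mb vs multi-kb: larger median, small p
  pats2 <- tibble::tibble(sample_id = sprintf("Q%d", 1:20), sex = "M",
                          hscr_form = "S",
                          syndromic = rep(c("yes", "no"), each = 10),
                          ret_status = "none")
  sizes <- c(stats::runif(10, 1e6, 5e6), stats::runif(10, 5e3, 5e4))
  big <- purrr::map2_dfr(pats2$sample_id, sizes, ~truth_call(.x, size = .y))
  sc <- size_comparison(big, pats2)
  expect_gt(sc$median2, sc$median1)  # "yes" sorts after "no"? check below
  expect_lt(sc$p_value, 0.05)
  # single-element groups: medians reported, p near 1
  pats3 <- tibble::tibble(sample_id = c("R1", "R2"), sex = "M",
                          hscr_form = "S", syndromic = c("yes", "no"),
                          ret_status = "none")
  one <- size_comparison(dplyr::bind_rows(truth_call("R1", size = 200),
                                          truth_call("R2", size = 100)),
                         pats3)
  expect_equal(sort(c(one$median1, one$median2)), c(100, 200))
  expect_gt(one$p_value, 0.5)
})
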