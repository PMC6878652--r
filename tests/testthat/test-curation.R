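mk_call <- function(probe_count, malr, source = "software", type = "gain",
                    mean_ratio = malr, chrom = "chr1",
                    inner_start = 1e6, inner_end = 1.01e6, sample_id = "S1") {
  tibble::tibble(sample_id = sample_id, chrom = chrom,
                 inner_start = inner_start, inner_end = inner_end,
                 outer_start = inner_start - 1000, outer_end = inner_end + 1000,
                 type = type, probe_count = as.integer(probe_count),
                 score = 8, mean_ratio = mean_ratio, malr = malr,
                 source = source)
}

test_that("filter_calls enforces >=2 probes and MALR > 0.30, visual exempt", {
  calls <- dplyr::bind_rows(
    mk_call(1, 0.9),                    # dropped: single probe
    mk_call(5, 0.25),                   # dropped: MALR at/below 0.30
    mk_call(5, 0.30),                   # dropped: strict inequality
    mk_call(2, 0.28, source = "visual"),# retained: visual exempt from MALR
    mk_call(1, 0.9, source = "visual"), # dropped: probe rule applies to all
    mk_call(3, 0.31)                    # retained
  )
  kept <- filter_calls(calls)
  expect_equal(nrow(kept), 2)
  expect_setequal(kept$source, c("visual", "software"))
  # pure filter: subset of input, idempotent
  expect_true(all(kept$malr %in% calls$malr))
  expect_identical(filter_calls(kept), kept)
})

# helper: profile with two same-type events separated by a configurable gap
gap_profile <- function(d, gap_vals, type = "gain") {
  amp <- if (type == "gain") 0.8 else -0.8
  x <- numeric(nrow(d))
  x[11:16] <- amp
  gap_rows <- 17:(16 + length(gap_vals))
  x[gap_rows] <- gap_vals
  x[(max(gap_rows) + 1):(max(gap_rows) + 5)] <- amp
  render_profile(d, x, noise_sd = 0)
}

# two gain calls over known probe rows of the small design
two_calls <- function(d, rows1, rows2) {
  dplyr::bind_rows(
    mk_call(length(rows1), 0.8, inner_start = d$start[min(rows1)],
            inner_end = d$end[max(rows1)]),
    mk_call(length(rows2), 0.8, inner_start = d$start[min(rows2)],
            inner_end = d$end[max(rows2)])
  )
}

test_that("split_merge keeps events apart across >2 intervening probes", {
  d <- small_design()
  p <- gap_profile(d, c(0, 0, 0))
  calls <- two_calls(d, 11:16, 20:24)  # 3 intervening probes
  merged <- split_merge(calls, p, sigma = 0.15)
  expect_equal(nrow(merged), 2)
  expect_equal(merged$probe_count, c(6L, 5L))
})

test_that("split_merge merges across <=2 quiet probes and recomputes stats", {
  d <- small_design()
  p <- gap_profile(d, c(0.05, -0.02))
  calls <- two_calls(d, 11:16, 19:23)  # 2 quiet intervening probes
  merged <- split_merge(calls, p, sigma = 0.15)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$probe_count, 13L)  # 6 + 2 intervening + 5
  expect_equal(merged$inner_start, d$start[11])
  expect_equal(merged$inner_end, d$end[23])
  expect_equal(merged$malr, mean(abs(p$log2ratio[11:23])))
  # idempotent
  expect_equal(split_merge(merged, p, sigma = 0.15), merged)
})

test_that("an interior opposite-sign run keeps / makes events separate", {
  d <- small_design()
  p <- gap_profile(d, c(-0.5, -0.5))
  # as two calls: the opposing gap blocks merging
  calls <- two_calls(d, 11:16, 19:23)
  expect_equal(nrow(split_merge(calls, p, sigma = 0.15)), 2)
  # as one bridged call (what maximal-score detection returns): it is split
  detected <- detect_aberrations(p, threshold = 6, sigma = 0.15)
  expect_equal(nrow(detected), 1)  # the spanning interval scores highest
  split <- split_merge(detected, p, sigma = 0.15)
  expect_equal(nrow(split), 2)
  expect_equal(split$probe_count, c(6L, 5L))
  expect_true(all(split$type == "gain"))
})

test_that("overlapping opposite-type calls violate the contract", {
  bad <- dplyr::bind_rows(mk_call(5, 0.8, type = "gain"),
                          mk_call(5, 0.8, type = "loss"))
  d <- small_design()
  p <- render_profile(d, noise_sd = 0)
  expect_error(split_merge(bad, p, sigma = 0.15), "contract")
})

test_that("triage bands label likely / possible / unlikely", {
  calls <- dplyr::bind_rows(
    mk_call(6, 0.62, mean_ratio = 0.62, type = "gain"),   # likely
    mk_call(5, 0.45, mean_ratio = -0.45, type = "loss"),  # possible
    mk_call(2, 0.32, mean_ratio = 0.32, type = "gain"),   # unlikely (band)
    mk_call(4, 1.1, mean_ratio = -1.1, type = "loss"),    # likely (<= -1)
    mk_call(6, 0.34, mean_ratio = 0.34, type = "gain")    # unlikely (malr)
  )
  t <- triage(calls)
  expect_equal(t$triage, c("likely", "possible", "unlikely", "likely",
                           "unlikely"))
  expect_equal(nrow(t), nrow(calls))  # triage labels, never deletes
})

test_that("replicate concordance distinguishes all four outcomes", {
  d <- small_design()
  rows <- 30:37
  exp_vec <- expected_profile(d, probe_cnv(d, rows, "loss", 1))
  main <- render_profile(d, exp_vec, noise_sd = 0.1, sample_id = "A", seed = 1)
  reps <- make_replicates(main, d, k = 2, noise_sd = 0.1, seed = 50)
  # B has a spurious call and a clean replicate
  spurious <- numeric(nrow(d)); spurious[80:83] <- -0.9
  main_b <- render_profile(d, spurious, noise_sd = 0.1, sample_id = "B", seed = 2)
  rep_b <- render_profile(d, noise_sd = 0.1, sample_id = "B_rep1",
                          seed = 60, replicate_group = "B")
  # C has no replicate at all
  main_c <- render_profile(d, exp_vec, noise_sd = 0.1, sample_id = "C", seed = 3)
  profiles <- dplyr::bind_rows(main, reps, main_b, rep_b, main_c)
  calls <- detect_aberrations(
    dplyr::bind_rows(main, main_b, main_c), threshold = 6, sigma = 0.1)
  out <- replicate_concordance(calls, profiles, d)
  get <- function(sid) out$replicate_status[out$sample_id == sid]
  expect_equal(get("A"), "confirmed")
  expect_equal(get("B"), "not_confirmed")
  expect_equal(get("C"), "not_evaluable")
  # not_excluded: replicate trends the same way but below calling strength
  trend <- exp_vec * 0.2  # mean -0.2: below calling strength, |mean| > 0.15
  rep_d <- render_profile(d, trend, noise_sd = 0.1, sample_id = "D_rep1",
                          seed = 70, replicate_group = "D")
  main_d <- render_profile(d, exp_vec, noise_sd = 0.1, sample_id = "D", seed = 4)
  calls_d <- detect_aberrations(main_d, threshold = 6, sigma = 0.1)
  out_d <- replicate_concordance(calls_d, dplyr::bind_rows(main_d, rep_d), d)
  expect_equal(out_d$replicate_status, "not_excluded")
})
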