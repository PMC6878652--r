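db_entry <- function(d, rows, type = "loss", carriers = 6, cohort = 100,
                     source = "dgv") {
  make_population_db(tibble::tibble(chrom = d$chrom[min(rows)],
                                    start = d$start[min(rows)],
                                    end = d$end[max(rows)], type = type,
                                    carriers = carriers, cohort = cohort),
                     source = source)
}

call_over <- function(d, rows, type = "loss", sample_id = "S1") {
  tibble::tibble(sample_id = sample_id, chrom = d$chrom[min(rows)],
                 inner_start = d$start[min(rows)], inner_end = d$end[max(rows)],
                 outer_start = d$start[max(min(rows) - 1, 1)],
                 outer_end = d$end[min(max(rows) + 1, nrow(d))],
                 type = type, probe_count = length(rows), score = 9,
                 mean_ratio = if (type == "loss") -1 else 0.6,
                 malr = 1, source = "software")
}

test_that("matching requires same type, >=80% overlap and <=2 probe diff", {
  d <- small_design()
  call <- call_over(d, 20:39)  # 20 probes at 1 kb
  # identical interval, same type: match (reflexive)
  m <- match_population(call, db_entry(d, 20:39), d)
  expect_true(m$matched)
  expect_equal(m$frequency_class, "common")
  # same type but different kind of aberration: no match
  m2 <- match_population(call, db_entry(d, 20:39, type = "gain"), d)
  expect_false(m2$matched)
  # overlap below 80% of the call: no match
  m3 <- match_population(call, db_entry(d, 20:34), d)  # 15/20 = 75%
  expect_false(m3$matched)
  # entry overhangs the call by 3 design probes: no match either way
  m4 <- match_population(call, db_entry(d, 20:42), d)
  expect_false(m4$matched)
  # overhang of exactly 2 probes is tolerated
  m5 <- match_population(call, db_entry(d, 20:41), d)
  expect_true(m5$matched)
})

test_that("entries on unknown chromosomes are skipped with a warning", {
  d <- small_design()
  call <- call_over(d, 20:29)
  db <- make_population_db(
    tibble::tibble(chrom = c("chr1", "chr7"), start = c(d$start[20], 1),
                   end = c(d$end[29], 1e6), type = "loss",
                   carriers = 6, cohort = 100), source = "dgv")
  expect_warning(m <- match_population(call, db, d), "unknown chromosome")
  expect_true(m$matched)
})

test_that("frequency classes follow the 5% / 1% bands", {
  expect_equal(frequency_class(TRUE, 0.06), "common")
  expect_equal(frequency_class(TRUE, 0.008), "rare")
  expect_equal(frequency_class(TRUE, 0.03), "intermediate")
  expect_equal(frequency_class(FALSE, NA), "novel")
})

test_that("frequency_test picks Fisher or Yates chi-square appropriately", {
  # small expected counts: Fisher
  ft <- frequency_test(3, 59, 3, 1000)
  expect_equal(ft$method, "fisher")
  expect_lt(ft$p_value, 0.01)
  expect_gt(ft$odds_ratio, 1)
  # all expected counts >= 5: Yates chi-square
  ct <- frequency_test(20, 100, 40, 100)
  expect_equal(ct$method, "chisq_yates")
  expect_equal(ct$p_value,
               chisq.test(matrix(c(20, 80, 40, 60), 2, byrow = TRUE),
                          correct = TRUE)$p.value)
  # identical frequencies: OR 1, p 1
  eq <- frequency_test(5, 100, 5, 100)
  expect_equal(eq$odds_ratio, 1)
  expect_equal(eq$p_value, 1)
  # degenerate all-zero carriers: p 1, Haldane OR 1 flagged
  dg <- frequency_test(0, 10, 0, 10)
  expect_equal(dg$p_value, 1)
  expect_equal(dg$odds_ratio, 1)
  expect_true(dg$haldane)
  expect_error(frequency_test(1, 0, 1, 10), "non-empty")
})

test_that("odds ratio is invariant under swapping both rows and columns", {
  a <- frequency_test(7, 30, 3, 50)
  b <- frequency_test(50 - 3, 50, 30 - 7, 30)  # swap rows + swap columns
  expect_equal(a$odds_ratio, b$odds_ratio, tolerance = 1e-12)
})

test_that("Fisher p-values match hypergeometric enumeration on sampled tables", {
  set.seed(1)
  for (rep in 1:50) {
    tot <- sample(4:60, 1)
    a <- sample(0:tot, 1); b <- sample(0:(tot - a), 1)
    c_ <- sample(0:(tot - a - b), 1); d_ <- tot - a - b - c_
    if ((a + b) == 0 || (c_ + d_) == 0 || (a + c_) == 0 || (b + d_) == 0) next
    # enumeration oracle: sum of hypergeometric probabilities <= observed
    m <- a + c_; n_ <- b + d_; k <- a + b
    support <- max(0, k - n_):min(k, m)
    probs <- dhyper(support, m, n_, k)
    p_enum <- sum(probs[probs <= dhyper(a, m, n_, k) * (1 + 1e-7)])
    expect_equal(fisher.test(matrix(c(a, b, c_, d_), 2, byrow = TRUE))$p.value,
                 min(1, p_enum), tolerance = 1e-10)
  }
})

test_that("cohort frequency report covers tested and untested sources", {
  d <- small_design()
  calls <- dplyr::bind_rows(
    call_over(d, 20:29, sample_id = "S1"),
    call_over(d, 20:29, sample_id = "S2"),   # recurrent variant
    call_over(d, 60:69, sample_id = "S3")    # only in gnomad fixture
  )
  db <- dplyr::bind_rows(
    db_entry(d, 20:29, carriers = 5, cohort = 100, source = "dgv"),
    db_entry(d, 60:69, carriers = 1, cohort = 200, source = "gnomad")
  )
  rep <- cohort_frequency_report(calls, db, d, n_samples = 10)
  expect_equal(nrow(rep), 4)  # 2 variants x 2 sources
  v1_dgv <- rep[rep$start == d$start[20] & rep$source == "dgv", ]
  expect_equal(v1_dgv$carriers, 2)
  expect_equal(v1_dgv$sample_freq, 0.2)
  expect_equal(v1_dgv$db_freq, 0.05)
  expect_false(is.na(v1_dgv$p_value))
  v1_gno <- rep[rep$start == d$start[20] & rep$source == "gnomad", ]
  expect_true(is.na(v1_gno$p_value))  # not tested: no consistent entry
  # empty cohort: empty table
  expect_equal(nrow(cohort_frequency_report(calls[0, ], db, d, 10)), 0)
})

test_that("recurrence counts distinct samples sharing a consistent variant", {
  d <- small_design()
  calls <- dplyr::bind_rows(
    call_over(d, 20:29, sample_id = "S1"),
    call_over(d, 20:29, sample_id = "S2"),
    call_over(d, 60:69, sample_id = "S1")
  )
  rc <- count_recurrence(calls, d)
  expect_equal(sort(rc$recurrence), c(1, 2, 2))
})

test_that("an enriched locus is flagged against the fixture database", {
  d <- small_design()
  # planted at 20% in a 59-sample cohort vs 5% in controls
  calls <- purrr::map_dfr(sprintf("S%02d", 1:12), function(s)
    call_over(d, 20:29, sample_id = s))
  db <- db_entry(d, 20:29, carriers = 50, cohort = 1000, source = "gnomad")
  rep <- cohort_frequency_report(calls, db, d, n_samples = 59)
  expect_lt(rep$p_value, 0.05)
  expect_gt(rep$odds_ratio, 1)
})
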