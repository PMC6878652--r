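library(dplyr)

# a small two-chromosome design used by most unit tests:
# 120 probes at 1 kb on chr1, 80 probes at 2 kb on chr2
small_design <- function() {
  regions <- tibble::tibble(
    region = c("locusA", "locusB"),
    chrom = c("chr1", "chr2"),
    anchor = c(1e6, 2e6),
    spacing_nt = c(1000, 2000),
    padding_kb = c(0, 0),
    n_probes = c(120L, 80L),
    times = 1L
  )
  build_design(regions)
}

# plant one CNV covering design probe rows `rows` of `chrom`
probe_cnv <- function(design, rows, type = "loss", copy_number = 1L,
                      sample_id = "S01") {
  sub <- design[rows, ]
  tibble::tibble(chrom = sub$chrom[1], start = min(sub$start),
                 end = max(sub$end), type = type,
                 copy_number = as.integer(copy_number),
                 sample_id = sample_id)
}

# independent exhaustive maximal-interval oracle: enumerates every
# interval score by direct summation, then applies the same greedy
# mask-and-recurse semantics as the detector
oracle_intervals <- function(x, sigma, threshold) {
  recurse <- function(l, r) {
    if (l > r) return(NULL)
    best <- -1; bi <- NA; bj <- NA; bs <- NA
    for (i in l:r) {
      for (j in i:r) {
        s <- sum(x[i:j]) / (sigma * sqrt(j - i + 1))
        if (abs(s) > best) { best <- abs(s); bi <- i; bj <- j; bs <- s }
      }
    }
    if (best < threshold) return(NULL)
    rbind(c(bi, bj, bs), recurse(l, bi - 1), recurse(bj + 1, r))
  }
  m <- recurse(1, length(x))
  if (is.null(m)) m <- matrix(numeric(0), ncol = 3)
  colnames(m) <- c("start", "end", "score")
  m[order(m[, 1]), , drop = FALSE]
}
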