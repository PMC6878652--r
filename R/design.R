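# Probe design generation for a custom targeted aCGH chip.
#
# A design is the coordinate scaffold for everything downstream: an ordered
# tibble of 60-mer probes with region labels and simulated GC content.
# Coordinates are 1-based, fully closed; BED conversion happens only at I/O.

# GRCh37 chromosome lengths (bp), chr1..chr22 — used to spread backbone probes
.grch37_len <- c(
  249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
  159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
  115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
  59128983, 63025520, 48129895, 51304566
)

#' Default region table for the targeted Hirschsprung-disease array design
#'
#' Mirrors a 15K-style custom design: 20 candidate regions/genes at
#' region-specific probe densities, a genome-wide backbone, and a set of
#' probes replicated five times for within-array reproducibility checks.
#' Spacing is the average inter-probe distance in nt; padding extends the
#' locus on both sides.
#'
#' @param backbone_probes number of genome-wide backbone probes.
#' @param replicated_probes number of distinct probe positions replicated
#'   `replicate_times` times each.
#' @param replicate_times copies per replicated probe position.
#' @return a tibble with one row per design block: `region`, `chrom`
#'   (`"genome"` for genome-wide blocks), `anchor` (locus start, bp),
#'   `spacing_nt`, `padding_kb`, `n_probes`, `times`.
#' @export
#' @examples
#' design_regions_default()
design_regions_default <- function(backbone_probes = 3130,
                                   replicated_probes = 301,
                                   replicate_times = 5) {
  regions <- tibble::tribble(
    ~region,      ~chrom,   ~anchor,     ~spacing_nt, ~padding_kb, ~n_probes,
    "RET",        "chr10",  43572000,    300,         100,         813,
    "9q31",       "chr9",   109200000,   2500,        0,           1824,
    "9p24.1",     "chr9",   5400000,     3500,        0,           142,
    "PHOX2B",     "chr4",   41744000,    500,         10,          49,
    "NRG1",       "chr8",   32400000,    500,         10,          473,
    "SEMA3A/3D",  "chr7",   83580000,    2500,        10,          508,
    "6q25.1",     "chr6",   151000000,   3500,        0,           714,
    "21q22",      "chr21",  36000000,    50000,       0,           202,
    "3p21",       "chr3",   44000000,    3500,        0,           1141,
    "19q12",      "chr19",  30000000,    3500,        0,           1085,
    "NRTN",       "chr19",  5810000,     800,         5,           18,
    "16q23.3",    "chr16",  81000000,    3500,        0,           714,
    "NKX2-1",     "chr14",  36985000,    800,         5,           17,
    "SOX10",      "chr22",  38368000,    800,         5,           27,
    "22q11.2",    "chr22",  18000000,    50000,       0,           162,
    "ECE1",       "chr1",   21543000,    800,         5,           103,
    "ZEB2",       "chr2",   145141000,   800,         0,           165,
    "EDNRB",      "chr13",  78469000,    800,         5,           112,
    "GDNF",       "chr5",   37812000,    800,         5,           42,
    "EDN3",       "chr20",  57875000,    800,         5,           44
  )
  regions$times <- 1L
  dplyr::bind_rows(
    regions,
    tibble(region = "backbone", chrom = "genome", anchor = NA_real_,
           spacing_nt = NA_real_, padding_kb = 0,
           n_probes = backbone_probes, times = 1L),
    tibble(region = "replicated", chrom = "genome", anchor = NA_real_,
           spacing_nt = NA_real_, padding_kb = 0,
           n_probes = replicated_probes, times = as.integer(replicate_times))
  )
}

# deterministic pseudo-GC: smooth positional waves clipped into [0.30, 0.65];
# simulated, not FASTA-derived
simulate_gc <- function(start) {
  gc <- 0.45 + 0.08 * sin(2 * pi * start / 7e6) + 0.04 * cos(2 * pi * start / 9.1e5)
  pmin(pmax(gc, 0.30), 0.65)
}

place_genome_wide <- function(n, offset_frac = 0.5) {
  # spread n probes over chr1..chr22 proportionally to GRCh37 lengths,
  # exact total via largest-remainder apportionment
  quota <- n * .grch37_len / sum(.grch37_len)
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  purrr::map_dfr(seq_along(base), function(i) {
    k <- base[i]
    if (k == 0) return(tibble(chrom = character(), start = numeric()))
    step <- .grch37_len[i] / k
    tibble(chrom = paste0("chr", i),
           start = round(step * (seq_len(k) - 1 + offset_frac)) + 1)
  })
}

#' Build a probe design from a region table
#'
#' Places probes at the stated average spacing across each locus extended by
#' its padding; genome-wide blocks (`chrom == "genome"`) are spread over
#' chr1-chr22 proportionally to chromosome length. Probe counts match the
#' region table exactly. Replicated blocks emit `times` copies of each probe
#' position sharing a `probe_id` and distinguished by `replicate`.
#'
#' @param regions a region table as returned by [design_regions_default()].
#' @param probe_length probe length in nt (Agilent-style 60-mers by default).
#' @return a `cgh_design` tibble: `chrom`, `start`, `end`, `probe_id`,
#'   `region`, `gc`, `replicate`, sorted by (chromosome, start).
#' @export
#' @examples
#' build_design(design_regions_default())
build_design <- function(regions = design_regions_default(), probe_length = 60) {
  if (nrow(regions) == 0) {
    out <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  probe_id = character(), region = character(),
                  gc = numeric(), replicate = integer())
    class(out) <- c("cgh_design", class(out))
    return(out)
  }
  regions <- as_tibble(regions)
  if (!"times" %in% names(regions)) regions$times <- 1L
  targeted <- dplyr::filter(regions, .data$chrom != "genome")
  bad <- dplyr::filter(
    targeted,
    .data$n_probes > 0 & (is.na(.data$spacing_nt) | .data$spacing_nt <= 0)
  )
  if (nrow(bad) > 0) {
    abort(paste0("region '", bad$region[1],
                 "' has zero length (non-positive spacing) but a nonzero probe count"))
  }

  probes <- purrr::pmap_dfr(targeted, function(region, chrom, anchor, spacing_nt,
                                               padding_kb, n_probes, times, ...) {
    if (n_probes == 0) {
      return(tibble(chrom = character(), start = numeric(),
                    region = character(), times = integer()))
    }
    first <- max(1, anchor - padding_kb * 1000)
    tibble(chrom = chrom,
           start = first + spacing_nt * (seq_len(n_probes) - 1),
           region = region, times = as.integer(times))
  })

  genome <- dplyr::filter(regions, .data$chrom == "genome")
  offset <- 0.5
  gprobes <- purrr::pmap_dfr(genome, function(region, n_probes, times, ...) {
    # stagger successive genome-wide blocks so they do not collide
    pl <- place_genome_wide(n_probes, offset_frac = offset)
    offset <<- offset + 0.17
    dplyr::mutate(pl, region = region, times = as.integer(times))
  })

  out <- dplyr::bind_rows(probes, gprobes)
  out <- tidyr::uncount(out, weights = .data$times, .id = "replicate")
  out <- out %>%
    mutate(chrom = chrom_factor(.data$chrom)) %>%
    arrange(.data$chrom, .data$start, .data$replicate) %>%
    mutate(chrom = as.character(.data$chrom),
           end = .data$start + probe_length - 1,
           gc = simulate_gc(.data$start),
           replicate = as.integer(.data$replicate))
  # probe_id keyed on position so replicated copies share it
  key <- paste0(out$chrom, ":", out$start)
  out$probe_id <- sprintf("P%05d", match(key, unique(key)))
  out <- select(out, "chrom", "start", "end", "probe_id", "region", "gc", "replicate")
  class(out) <- c("cgh_design", class(out))
  out
}
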