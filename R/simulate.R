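# Synthetic cohort generator: planted CNVs, Gaussian probe noise calibrated
# to a target DLRS, optional GC-correlated bias, replicate arrays, trios
# with known parental origin, and population-frequency fixtures.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Expected log2-ratio shifts for planted CNVs
#'
#' Probes inside a planted CNV take the shift `log2(copy_number / 2)`
#' (copy 3 gives +0.585, copy 1 gives -1, copy 0 is capped at `floor`);
#' probes outside stay at 0.
#'
#' @param design a `cgh_design` tibble from [build_design()].
#' @param cnvs a tibble of planted CNVs: `chrom`, `start`, `end`,
#'   `type` ("gain"/"loss"), `copy_number`, `sample_id`; optional `origin`.
#' @param floor finite stand-in for `log2(0)` used for homozygous losses;
#'   `NULL` makes copy-number 0 an error.
#' @return a tibble with one row per (sample, probe): `sample_id`,
#'   `probe_id` and `expected` aligned to the design row order.
#' @export
plant_cnvs <- function(design, cnvs, floor = -4) {
  cnvs <- as_tibble(cnvs)
  if (nrow(cnvs) == 0) {
    return(tibble(sample_id = character(), probe_id = character(),
                  expected = numeric()))
  }
  stopifnot(all(c("chrom", "start", "end", "type", "copy_number", "sample_id")
                %in% names(cnvs)))
  if (any(cnvs$type == "loss" & cnvs$copy_number >= 2) ||
      any(cnvs$type == "gain" & cnvs$copy_number <= 2)) {
    abort("CNV type inconsistent with copy_number (loss needs <2, gain >2)")
  }
  if (any(cnvs$copy_number == 0) && is.null(floor)) {
    abort("copy_number 0 with no log2 floor configured (log of zero)")
  }
  samples <- unique(cnvs$sample_id)
  purrr::map_dfr(samples, function(s) {
    exp_vec <- expected_profile(design, cnvs[cnvs$sample_id == s, ], floor = floor)
    tibble(sample_id = s, probe_id = design$probe_id, expected = exp_vec)
  })
}

#' Expected log2 vector for a single sample's planted CNVs
#'
#' @param design a `cgh_design` tibble.
#' @param cnvs planted CNVs for one sample (see [plant_cnvs()]).
#' @param floor finite stand-in for `log2(0)`.
#' @return a numeric vector aligned to the design rows.
#' @export
expected_profile <- function(design, cnvs, floor = -4) {
  exp_vec <- numeric(nrow(design))
  if (nrow(cnvs) == 0) return(exp_vec)
  for (i in seq_len(nrow(cnvs))) {
    hit <- design$chrom == cnvs$chrom[i] &
      design$start <= cnvs$end[i] & design$end >= cnvs$start[i]
    if (!any(hit)) {
      abort(sprintf("planted CNV %s:%d-%d covers no probe of the design",
                    cnvs$chrom[i], cnvs$start[i], cnvs$end[i]))
    }
    cn <- cnvs$copy_number[i]
    shift <- if (cn == 0) floor else log2(cn / 2)
    if (!is.null(floor)) shift <- max(shift, floor)
    exp_vec[hit] <- shift
  }
  exp_vec
}

#' Render a noisy sample profile from expected log2 shifts
#'
#' Adds i.i.d. Gaussian probe noise with standard deviation `noise_sd`
#' (calibrated so the measured DLRS of a null profile is close to
#' `noise_sd`) and an optional GC-correlated additive bias
#' `gc_slope * (gc - mean(gc))`.
#'
#' @param design a `cgh_design` tibble.
#' @param expected numeric vector of expected log2 shifts aligned to the
#'   design (defaults to all zero, i.e. copy-neutral).
#' @param noise_sd per-probe Gaussian noise SD in log2 units; must be >= 0.
#' @param gc_slope slope of the injected GC bias (log2 units per GC fraction).
#' @param sample_id sample label.
#' @param seed optional integer; identical seeds give identical profiles.
#' @param replicate_group replicate-linkage label (`NA` when unreplicated).
#' @return a `cgh_profiles` tibble, one row per probe: design columns plus
#'   `sample_id`, `replicate_group`, `expected`, `log2ratio`.
#' @export
render_profile <- function(design, expected = NULL, noise_sd = 0.15,
                           gc_slope = 0, sample_id = "S1", seed = NULL,
                           replicate_group = NA_character_) {
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  n <- nrow(design)
  if (is.null(expected)) expected <- numeric(n)
  stopifnot(length(expected) == n)
  noise <- with_seed(seed, rnorm(n, 0, noise_sd))
  gc_term <- if (gc_slope != 0) gc_slope * (design$gc - mean(design$gc)) else 0
  out <- tibble(
    sample_id = sample_id,
    chrom = design$chrom, start = design$start, end = design$end,
    probe_id = design$probe_id, region = design$region, gc = design$gc,
    replicate_group = replicate_group,
    expected = expected,
    log2ratio = expected + gc_term + noise
  )
  class(out) <- c("cgh_profiles", class(out))
  out
}

#' Re-render replicate arrays of a sample
#'
#' Same expected log2 vector, fresh independent noise; replicate linkage is
#' recorded through `replicate_group` (the parent sample id) on both the
#' original and its replicates.
#'
#' @param profile a single-sample `cgh_profiles` tibble carrying `expected`.
#' @param design the design the profile was rendered on.
#' @param k number of replicates (>= 1).
#' @param noise_sd,gc_slope,seed as in [render_profile()].
#' @return a `cgh_profiles` tibble with samples `<id>_rep1` ... `<id>_repk`.
#' @export
make_replicates <- function(profile, design, k = 1, noise_sd = 0.15,
                            gc_slope = 0, seed = NULL) {
  if (k < 1) abort("k must be >= 1")
  sid <- unique(profile$sample_id)
  stopifnot(length(sid) == 1)
  seeds <- if (is.null(seed)) rep(list(NULL), k) else as.list(seed + seq_len(k) - 1)
  purrr::map_dfr(seq_len(k), function(i) {
    render_profile(design, expected = profile$expected, noise_sd = noise_sd,
                   gc_slope = gc_slope,
                   sample_id = paste0(sid, "_rep", i),
                   seed = seeds[[i]], replicate_group = sid)
  })
}

#' Build a synthetic population-CNV database table
#'
#' Emulates DGV/gnomAD/DDD-style frequency tables used for consistency
#' matching: each entry carries an interval, a type and a carrier frequency.
#'
#' @param entries tibble with `chrom`, `start`, `end`, `type`, `carriers`,
#'   `cohort`.
#' @param source database label (e.g. "dgv", "gnomad", "ddd", "fixture").
#' @return a `pop_db` tibble with an added `frequency` column.
#' @export
make_population_db <- function(entries, source = "fixture") {
  entries <- as_tibble(entries)
  stopifnot(all(c("chrom", "start", "end", "type", "carriers", "cohort")
                %in% names(entries)))
  if (any(entries$cohort <= 0)) abort("zero or negative cohort size")
  if (any(entries$carriers > entries$cohort)) {
    abort("carrier count exceeds cohort size")
  }
  out <- mutate(entries, frequency = .data$carriers / .data$cohort,
                source = source)
  class(out) <- c("pop_db", class(out))
  out
}

#' Simulate a cohort of profiles with planted CNVs
#'
#' @param design a `cgh_design` tibble.
#' @param n_samples cohort size; samples are labelled `S01`, `S02`, ...
#' @param cnvs planted-CNV tibble as in [plant_cnvs()] (may reference any
#'   subset of the sample labels); `NULL` for a fully null cohort.
#' @param noise_sd,gc_slope as in [render_profile()].
#' @param seed integer seed; per-sample seeds are derived from it.
#' @return a list of class `cgh_cohort`: `profiles` (long tibble over all
#'   samples), `truth` (the planted CNVs) and `manifest` (sample table).
#' @export
simulate_cohort <- function(design, n_samples, cnvs = NULL, noise_sd = 0.15,
                            gc_slope = 0, seed = NULL) {
  ids <- sprintf("S%02d", seq_len(n_samples))
  cnvs <- if (is.null(cnvs)) tibble(chrom = character(), start = numeric(),
                                    end = numeric(), type = character(),
                                    copy_number = integer(),
                                    sample_id = character())
          else as_tibble(cnvs)
  profiles <- purrr::map_dfr(seq_along(ids), function(i) {
    exp_vec <- expected_profile(design, cnvs[cnvs$sample_id == ids[i], ])
    render_profile(design, exp_vec, noise_sd = noise_sd, gc_slope = gc_slope,
                   sample_id = ids[i],
                   seed = if (is.null(seed)) NULL else seed + i)
  })
  structure(list(profiles = profiles, truth = cnvs,
                 manifest = tibble(sample_id = ids)),
            class = "cgh_cohort")
}

#' Simulate parent-child trios with known CNV origin
#'
#' Each trio carries one planted CNV in the child; maternally or paternally
#' inherited CNVs are planted in exactly one parent, de novo CNVs in neither.
#' All members are rendered on the same design.
#'
#' @param design a `cgh_design` tibble.
#' @param trio_cnvs tibble with one row per trio: `chrom`, `start`, `end`,
#'   `type`, `copy_number`, `origin` ("maternal", "paternal" or "de_novo").
#' @param noise_sd per-probe noise SD.
#' @param seed integer seed.
#' @return a list of class `cgh_trios`: `profiles` (children + parents),
#'   `manifest` (child/mother/father sample labels, all available) and
#'   `truth` (planted CNVs with origin).
#' @export
simulate_trios <- function(design, trio_cnvs, noise_sd = 0.15, seed = NULL) {
  trio_cnvs <- as_tibble(trio_cnvs)
  n <- nrow(trio_cnvs)
  manifest <- tibble(
    child = sprintf("T%03d_c", seq_len(n)),
    mother = sprintf("T%03d_m", seq_len(n)),
    father = sprintf("T%03d_f", seq_len(n)),
    mother_available = TRUE, father_available = TRUE
  )
  profiles <- purrr::map_dfr(seq_len(n), function(i) {
    cnv <- trio_cnvs[i, ]
    exp_child <- expected_profile(design, cnv)
    exp_null <- numeric(nrow(design))
    exp_mother <- if (cnv$origin == "maternal") exp_child else exp_null
    exp_father <- if (cnv$origin == "paternal") exp_child else exp_null
    base <- if (is.null(seed)) NULL else seed + 3L * i
    dplyr::bind_rows(
      render_profile(design, exp_child, noise_sd, sample_id = manifest$child[i],
                     seed = base),
      render_profile(design, exp_mother, noise_sd, sample_id = manifest$mother[i],
                     seed = if (is.null(base)) NULL else base + 1L),
      render_profile(design, exp_father, noise_sd, sample_id = manifest$father[i],
                     seed = if (is.null(base)) NULL else base + 2L)
    )
  })
  truth <- mutate(trio_cnvs, sample_id = manifest$child)
  structure(list(profiles = profiles, manifest = manifest, truth = truth),
            class = "cgh_trios")
}
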