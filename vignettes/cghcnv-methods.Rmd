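---
title: "Copy-number calling on targeted aCGH designs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number calling on targeted aCGH designs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cghcnv)
library(dplyr)
```

## The problem

Targeted array-CGH measures, per oligonucleotide probe, the log2 ratio of
test versus reference DNA abundance: roughly 0 at copy number 2, +0.58 at
copy 3, and -1 at copy 1. On a custom design that tiles disease-candidate
regions at high probe density — here, a 15K-style design centred on
Hirschsprung-disease loci such as *RET*, *NRG1*, *SEMA3A/3D*, *PHOX2B* and
9q31, with a low-density genome-wide backbone — the analytical tasks are:
flag noisy hybridizations, detect aberrant probe intervals, curate the raw
calls with reproducible rules, decide which calls are credible ("true")
variants using population databases, replicates and orthogonal validation,
and, for inherited variants, assign a parental origin from trio profiles
and test transmission bias.

`cghcnv` implements that whole chain along with a synthetic-data generator,
so every stage is testable without access to raw arrays.

## The synthetic-data generator

`build_design()` places probes at each region's stated average spacing over
the locus extended by its padding; `design_regions_default()` mirrors the package's reference 20-region
targeted HSCR design (e.g. *RET*: 300 nt spacing, 100 kb
padding, 813 probes; a 3,130-probe genome-wide backbone; 301 positions
replicated five times). Coordinates are 1-based fully closed; BED (0-based,
half-open) appears only at the I/O boundary.

Simulated profiles are `expected + GC bias + noise`:

* planted CNVs shift member probes by `log2(copy_number / 2)`; copy 0 is
  capped at a configurable floor, default -4 — finite, yet far below any
  loss threshold;
* noise is i.i.d. Gaussian per probe with SD `noise_sd`, chosen so a null
  profile's measured DLRS equals `noise_sd`. Real arrays also show
  autocorrelated "waves" and outlier probes, which the generator does not
  model — passing tests therefore demonstrate correctness of the
  algorithms under calibrated white noise, not performance on every real
  artifact;
* optional GC bias is linear, `gc_slope * (gc - mean(gc))`, with
  `gc` a smooth deterministic positional surrogate (no FASTA lookup).

The reference design table states no genome-wide backbone spacing; probes are spread proportionally to GRCh37 chromosome lengths
(about one per megabase), which reproduces the observed behaviour that
backbone calls of a few probes span hundreds of kilobases to megabases.
Trios are rendered on the same design, with inherited CNVs planted in
exactly one parent and de novo CNVs in neither.

The generator's defaults are the study conditions used throughout the test
suite: `noise_sd = 0.15` (a good-quality hybridization; the QC gate sits at
0.3), planted events of 2-15 probes, cohorts of tens of samples.

## Quality control and normalization

DLRS — the derivative log ratio spread — is the per-sample noise metric:

\[
\mathrm{DLRS} = \frac{\mathrm{IQR}(\Delta)}{1.349 \sqrt{2}},
\]

where \(\Delta\) are differences of consecutive probes *within* a
chromosome. For i.i.d. noise with SD \(\sigma\), consecutive differences
have SD \(\sigma\sqrt2\) and IQR \(1.349\,\sigma\sqrt2\), so DLRS estimates
\(\sigma\) robustly: a CNV of \(k \ll n\) probes perturbs only \(2\)
differences and leaves the IQR nearly unchanged. The commercial software
that popularised DLRS does not publish a formula; this standard robust
definition is adopted because it makes the metric exactly the quantity the
QC gate needs. Samples with DLRS \(\ge 0.3\) (boundary inclusive) are
flagged `replicate_required`. The gate is applied after correction; whether
the original workflow gated before or after normalization is not
documented, and at these noise levels the difference is negligible.

Centralization subtracts the per-sample median of autosomal log2 ratios
(median rather than a mode estimator: deterministic, robust, idempotent).
GC correction fits a least-squares line of ratio on centred GC and removes
it; a linear fit (not loess) keeps the injected-bias recovery test
well-posed and suffices for the linear bias the generator produces.
On simulated data the order of the two corrections is immaterial.

## Segmentation: maximal interval scores

Commercial ADM-style detection is proprietary; `detect_aberrations()`
implements the documented interval-score family it belongs to. An interval
\(I\) scores

\[
S(I) = \frac{\sum_{i \in I} x_i}{\sigma \sqrt{|I|}},
\]

with \(\sigma\) the sample's DLRS by default. Per chromosome, the detector
finds the interval with maximal \(|S|\) (exhaustively, in compiled code),
keeps it if \(|S| \ge 6\) — the conventional detection threshold — and recurses
on the flanks, yielding disjoint maximal intervals. Ties are broken by
leftmost start, then shortest length, making the output deterministic.
The greedy extraction is verified against an independent exhaustive
enumeration for profiles up to 200 probes. Scores are scale-equivariant
(doubling both profile and \(\sigma\) changes nothing), and probe quality
weights are not modelled — simulated probes have no quality differences.

Call boundaries follow the inner/outer convention: inner = first/last
aberrant probe, outer = flanking normal probes, with the true breakpoint
somewhere between; at chromosome ends the outer boundary collapses onto
the inner one.

A deterministic emulation of whole-genome visual inspection
(`visual_rescue()`) adds runs of at least 2 consecutive probes all above
+0.5 (gain) or all below -1.0 (loss) that the software missed, marked
`source = "visual"`. The human step it emulates also weighed overall
profile quality and cohort context; the emulation is declared an
approximation, and visual-source calls stay distinguishable downstream.

## Curation rules

* **Filter**: software calls need \(\ge 2\) consecutive probes and a mean
  absolute log2 ratio (MALR) strictly above 0.30; visual calls are exempt
  from the MALR filter (the probe-count rule still applies).
* **Split/merge**: nearby same-type intervals with more than 2 intervening
  probes stay separate CNVs, as do those separated by a run of 2 probes
  opposing the call sign at |log2 ratio| > 0.3; at most 2 quiet intervening
  probes merge. Because a maximal-score interval can bridge a short
  opposing run, the same rule is also applied inside each call, cutting it
  at interior opposing runs. The conventional statement of the opposite-ratio rule is ambiguous about
  which sign belongs to which event type; it is applied here as: the intervening probes
  oppose the flanking call's sign at magnitude > 0.3 — the reading under
  which the probes are genuinely opposite in sign to the events they
  separate.
* **Triage** is a labelled emulation of a human judgement: `likely` when
  the mean ratio reaches the visual attention bands (\(\ge +0.5\) gain,
  \(\le -1.0\) loss), `unlikely` when MALR \(\le 0.35\) or a 2-probe call
  has |mean| < 0.4, `possible` otherwise. All three bands are configurable;
  triage labels calls and never deletes them.
* **Replicate concordance**: `confirmed` when a replicate array carries a
  consistent call (the same consistency rule as database matching);
  `not_excluded` when a replicate trends the same direction over the
  interval (|mean| > 0.15, half the MALR filter — an invented but
  documented threshold) without a call; `not_confirmed` otherwise;
  `not_evaluable` without a replicate.

## Database consistency and frequency tests

A call is *consistent* with a population-database entry when both are the
same kind (gain/loss), the overlap covers at least 80% of the call, and
neither extends beyond the other by more than 2 design probes (call-side
overhanging probes count only at a compatible amplitude,
|log2 ratio| \(\ge\) 0.3). The overlap denominator is the detected call —
the unit being classified — with a `reciprocal` switch available. Database
entries have no probe-level data, so probe counting uses the array design
as a proxy, as the output metadata states.

Matched frequencies classify as `common` (> 5%), `rare` (\(\le\) 1%),
`intermediate` between, `novel` with no match. Case-control carrier counts
are tested with Fisher's exact test, switching to the chi-square test with
Yates continuity correction when every expected cell count is at least 5
(the usual operationalization of "when feasible"); odds ratios come from
the raw 2x2 table, with a flagged Haldane 0.5 correction only when a zero
cell would make the ratio undefined. The Fisher path is verified against
brute-force hypergeometric enumeration.

## True variants, cohort summaries

A variant is **true** when any evidence channel fires: reported in a
population database (any frequency), confirmed on a replicate, or
validated orthogonally. For novelty accounting, a variant matched in the
DGV-like source only below 1% frequency is still counted among the
*not-reported* (novel) variants — so a variant known only as a very rare
population event still counts as a novel finding. The classifier is monotone:
adding evidence never demotes a variant.

`cohort_summary()` stratifies patients by disease form, gender, syndromic
status and RET anomaly (coding mutation or locus deletion), counting each
patient once per column; a patient with one database-reported and one novel
true CNV appears in both novelty columns, so those columns can sum to more
than the "true" column. CNV size comparisons between groups report group
medians with a two-sided Wilcoxon rank-sum p-value — group medians are the
reported statistic and the rank-sum test is the package's choice of a
distribution-free test for them, so only the direction of the effect
should be compared across analyses.

The package bundles a 59-patient example cohort (patient strata plus the
19-variant validation table) encoding its validation follow-up: 18
aberrations selected for validation, 11 confirmed, 12 novel true CNVs
including one confirmed only on replicates.

## Parental origin and transmission bias

A parent transmits a child variant when their profile yields a consistent
call. One positive parent gives that origin; two available negative
parents give de novo; a missing parent with no positive elsewhere gives
unknown; two positive parents are surfaced as `ambiguous` rather than
resolved. Origin assignment is purely CNV-consistency based — no SNP
phasing.

The transmission test is the exact binomial tail
\(P(X \ge k \mid n, 0.5)\). One-sided is the default: under a null of
equal parental transmission, 7 maternal of 7 inherited gives exactly
\(0.5^7 = 0.0078\);
`sided = "two"` doubles the smaller tail. The accompanying interval is the
exact two-sided 95% Clopper-Pearson interval — at \(k = n\) its lower edge
is \((\alpha/2)^{1/n}\), e.g. \(0.025^{1/7} \approx 0.59\).

```{r example}
binomial_bias_test(7, 7)
```

## Numerical and design choices

* Seeds control every random draw; identical seeds give byte-identical
  simulations, and the RNG state of the caller is restored afterwards.
* Score ties in segmentation: leftmost start, then shortest length.
* Degenerate inputs: DLRS needs \(\ge 3\) probes; constant GC makes GC
  correction a warned no-op; an empty 2x2 margin returns p = 1 with a
  flagged odds ratio; zero inherited CNVs make the transmission test an
  error, not a silent 1.
* Problem sizes in the test-suite simulations: 100 profiles of up to 200
  probes for the segmentation oracle, 50 cohorts plus 50 null cohorts on
  the full 15K design at `noise_sd = 0.15` for recovery/specificity, 20
  seeds per sigma for DLRS calibration, 200 trios for origin recovery —
  sizes at which the Monte-Carlo proportions are stable to a percent or
  two.
* The pipeline surface is R functions composed with the pipe (plus
  `run_pipeline()` for the staged, file-writing form); thresholds live in
  a YAML-serializable config whose unknown keys are errors.

## Known limitations

* The noise model is white Gaussian noise: no wave artifacts, dye bias, or
  probe-specific quality, so real-data false-positive rates will exceed
  the simulated ones.
* Visual inspection and triage are deterministic emulations of a human
  step and cannot reproduce individual expert judgement calls.
* Cohort-scale discovery numbers from the original raw arrays are not
  reproducible without those arrays; only the bundled table arithmetic
  and the simulation-based operating characteristics are checked.
* Sex chromosomes get no copy-number baseline adjustment, and mosaic
  fractions are not modelled.
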