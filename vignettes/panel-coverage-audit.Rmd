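---
title: "Auditing exome-capture coverage of a clinical gene panel"
author: "panelcov"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing exome-capture coverage of a clinical gene panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Whole-exome sequencing is routinely used to screen clinically relevant gene
panels, but a panel is only as good as its coverage. Two distinct failure
modes matter:

1. **Representation.** Capture kits are designed against a conservative
   annotation of protein-coding sequence (a CCDS-like database). Any exonic
   base known only to a broader annotation (a Known-Gene-like database,
   which adds isoforms and additional transcripts) cannot be captured at
   all, no matter how deeply one sequences.
2. **Coverage.** Even inside the designed footprint, read depth is
   non-uniform between genes, within genes, and (to a much smaller degree)
   between samples — driven substantially by GC content and, more weakly,
   by gene size.

`panelcov` quantifies both failure modes for an arbitrary panel, given two
BED annotations, per-sample per-base depth tables (the 3-column text that
`samtools depth`/`mpileup` workflows emit), and a genome FASTA.

## Statistics computed

All base counting is done on *unique locations*: interval collections are
collapsed into canonical disjoint sets (0-based half-open, BED convention)
so no base is ever counted twice. On those sets the audit computes:

* **Representation**: per gene `g`, the fraction of the superset-database
  bases that also occur in the subset database,
  `|subset_g ∩ superset_g| / |superset_g|`; and a pooled overall fraction
  computed on the union over genes *before* counting, so exons shared
  between gene models are not double-counted. The pooled rule matches the
  unique-base framing of total panel sizes and is not a mean of per-gene
  percentages.
* **Capture fraction** at depth `d`: share of target bases whose
  *cross-sample mean* depth is at least `d`. A base absent from a sample's
  depth file is depth 0 (uncaptured, not missing); denominators are always
  the full target. Defaults follow clinical usage: `d = 3` (minimum to see
  a heterozygous variant) and `d = 30` (confident genotype call), with a
  full cumulative curve over `d = 1..200`.
* **Per-gene uniformity**: median and quartiles of per-base mean depth per
  gene, with two flags — `median_below_optimal` (strict `< 30`) and
  `iqr_above_optimal` (`q1 ≥ 30`, i.e. the box of the gene's box-plot
  clears the optimal depth).
* **Inter-sample variability**: per base, the normal-approximation 95% CI
  half-width `1.96·s/√n` (sample SD, `n−1` denominator) of depth across
  samples, summarized as the fraction of bases within ±k reads
  (default k = 5, 10).
* **Drivers**: ordinary least squares of per-gene median coverage on GC
  fraction and on gene size (slope, `r²`, two-sided slope t-test on `n−2`
  df), plus a Welch t-test comparing GC of the 5 best- against the 5
  worst-covered genes.

## Design choices

Several conventions are genuinely open in this kind of audit; the package
fixes them as follows and exposes the alternatives where reasonable.

* **Coordinates** are 0-based half-open throughout (BED semantics); depth
  files are 1-based (pileup convention) and shifted by −1 at the parser
  boundary only. Chromosome names compare verbatim (`"chr1" ≠ "1"`), with
  an explicit `normalize_chroms()` helper.
* **Abutting intervals merge**: two intervals covering a contiguous base
  run are one unique location (distance-0 merging, the interval-merge
  default in standard tools).
* **Strand is ignored** — coverage is strandless.
* **Captured at `d`** is judged on the cross-sample *mean* track, with `≥`
  semantics; "below optimal" is strict `<`. These are centralized in
  `audit_config()` so no stage can drift.
* **Quantiles** use linear interpolation between order statistics
  (`stats::quantile` type 7, the default of mainstream statistical
  environments); configurable via `quantile_type` because conventions
  disagree at small n.
* **"IQR above 30X"** is read as `q1 ≥ 30`; the alternative width reading
  (`q3 − q1 ≥ 30`) is available via `iqr_rule = "width"`.
* **CI** uses the normal approximation, appropriate for the cohort sizes
  the audit targets (tens of samples); no bootstrap.
* **GC** counts A/C/G/T case-insensitively; ambiguity codes are excluded
  from numerator and denominator, so the statistic is the GC share among
  unambiguous bases. Genes with no unambiguous base are excluded from
  regressions with a warning. GC is computed over the subset-database
  regions — the same territory over which coverage is summarized.
* **Predictors enter untransformed** (GC as a fraction, size in bases);
  the regressions are deliberately simple single-predictor fits reported
  separately, not a multiple regression.
* **Degenerate extremes comparison**: if both GC groups have zero
  variance, equal means return p = 1 and unequal means return p → 0 with a
  warning rather than an error.
* **Interval arithmetic** is exact integer sweep-line work on sorted
  vectors, validated against a brute-force per-base oracle and against
  GenomicRanges in the test suite; `GRanges` remains the user-facing
  container throughout.

## The simulator

Because real exome BAMs and specific annotation-table versions are
external inputs, the package ships a generator
(`sim_config()`/`simulate_panel()`) that emits a complete, self-contained
study — genome FASTA, nested superset/subset BED, per-kit footprint BED,
per-sample depth TSVs, manifest, and a `truth.json` of every recoverable
parameter. Its defaults describe the study design the audit is meant for:

* 50 genes (2 chromosomes, 4 exons of 120–300 bp each) with per-gene
  subset fractions evenly spanning 0.10–0.97 — the range observed between
  conservative and broad annotations of real clinical panels;
* four capture-kit generations with footprints covering 92/97/98/99% of
  the subset database, sequenced in cohorts of 20/94/93/6 samples at
  target mean depths 30.5/80/48/63X;
* per-gene GC targets evenly spanning 0.35–0.65, assigned to genes in
  shuffled order so GC is not confounded with gene size or subset
  fraction;
* depth at a captured base of gene `g` in sample `s` drawn
  `NegBin(mean = exp(α_kit + β·GC_g + ε_s), size = φ)` with `β = −2`
  (a log-linear GC penalty keeps means positive and the fitted linear
  GC–coverage trend approximately linear over the simulated GC range),
  `φ = 40` (overdispersion is universal in capture data, but inter-sample
  reproducibility of capture depth is high — with this dispersion the
  larger simulated cohorts keep most per-base 95% CIs within ±5 reads,
  the regime the audit is designed around; `φ = ∞` gives the Poisson
  limit), and `ε_s ~ N(0, 0.05²)` (multiplicative sample effects,
  so inter-sample CI half-widths grow with depth). `α_kit` is anchored so
  the kit's target mean depth is met at the footprint's base-weighted mean
  GC.
* kit footprints drop the missing fraction from interval tails in
  shuffled order, so dropout is contiguous and exon-like rather than salt
  and pepper.

All randomness flows from one master seed through fixed substreams, so a
seed reproduces every emitted file byte for byte and each stage can be
regenerated independently.

**What the simulator does not emulate**: mappability and alignment
artifacts, duplicate reads, quality filtering inside pileup, copy-number
variation, and read-level error. Passing the recovery tests therefore
shows that the audit's arithmetic is correct and that its statistics
recover the generating parameters — not that any particular real capture
kit behaves like the model. Depth files are treated as ground truth;
upstream filters change the numbers.

A consequence of the default effect size worth knowing: at `β = −2` the
below-30X gene subpopulation appears in the *shallowest* (30.5X) cohort,
where per-gene means span roughly 23–41X, while at 80X no gene median
falls below 30X. The qualitative pattern — a low-coverage subpopulation
concentrated at high GC — is therefore asserted against the shallow kit.

## Worked example

```{r, eval = FALSE}
library(panelcov)

cfg <- sim_config(seed = 1)
sim <- simulate_panel(cfg, "study")
acfg <- audit_config(sim$paths$superset_bed, sim$paths$subset_bed,
                     sim$paths$fasta, sim$paths$manifest, "study/audit")
report <- run_report(acfg)

report$representation$overall_fraction   # pooled subset-in-superset fraction
sapply(report$kits, `[[`, "observed_mean_depth")
report$gc_analysis$fit_gc                # negative GC slope, r², p
```

Every table is written twice, as TSV (6 significant digits) and JSON, and
`report.json` aggregates the headline numbers plus an inventory of all
emitted tables. Re-running on identical inputs reproduces identical bytes.

## Validation suite sizes

The package's property tests run the interval algebra against a
brute-force per-base oracle on 1,000 random instances (≤ 200 intervals,
coordinates < 10⁴, ≤ 5 chromosomes) and against GenomicRanges on 25;
quartiles are checked against a hand-rolled interpolation oracle on 100
random genes; GC-slope recovery and type-I calibration each use 100
seeded replicates of a 50-gene panel (2 exons of 50–80 bp per gene, one
full-footprint kit, 2 samples at 40X); the end-to-end check runs the full
default study above. These sizes are the package's validation choices:
large enough to pin the arithmetic and the stochastic calibration, small
enough to run routinely.

## Limitations

* Gene-level only: no per-exon summaries, no transcript-level reporting.
* No alignment-file ingestion: the depth contract is 3-column text; any
  pileup producer works, with its filter settings owned by the caller.
* Simple generic outputs; no attempt at publication figure styling.
* The GC and size models are single-predictor OLS by design; genuinely
  multivariate structure (e.g. GC confounded with size) is out of scope.
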