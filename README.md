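# panelcov

Coverage audit of clinical gene panels on exome-capture sequencing data.

## The problem

When a clinical gene panel is screened by whole-exome sequencing, two
independent things limit what can be found:

1. **Representation** — capture kits are designed against a conservative
   annotation of coding sequence (CCDS-like). Exonic bases known only to a
   broader annotation (Known-Gene-like, which adds isoforms and further
   transcripts) are never targeted, at any depth.
2. **Coverage** — inside the designed footprint, read depth is non-uniform
   between and within genes, driven largely by GC content and weakly by
   gene size, while being highly reproducible between samples.

`panelcov` quantifies both for an arbitrary panel. Inputs are plain,
tool-agnostic formats: two 4-column BED annotations (a superset and a
subset database), per-sample per-base depth tables
(`chrom<TAB>pos<TAB>depth`, 1-based, as produced by `samtools depth` /
`mpileup` workflows), a sample manifest, and a genome FASTA.

## What it computes

With `T` a target region (unique bases, 0-based half-open intervals) and
`d̄(b)` the cross-sample mean depth at base `b` (bases absent from a
sample's file count as 0 — uncaptured, not missing):

* **Representation**: per gene `g`,
  `|subset_g ∩ superset_g| / |superset_g|`, plus a pooled overall fraction
  computed on the union over genes before counting;
* **Capture fraction** at depth `d`: `|{b ∈ T : d̄(b) ≥ d}| / |T|`,
  reported at 3X (minimum to see a heterozygous variant) and 30X
  (confident genotype), plus the full cumulative curve over `d = 1..200`;
* **Per-gene uniformity**: median, q1, q3 of `d̄` over each gene model
  (type-7 quantiles), with flags `median < 30` and `q1 ≥ 30`;
* **Inter-sample variability**: per-base 95% CI half-width
  `1.96·s(b)/√n` and the fraction of bases within ±k reads;
* **Drivers**: OLS of per-gene median coverage on GC fraction and on gene
  size (slope, r², two-sided slope t-test on n−2 df), and a Welch t-test
  of GC between the 5 best- and 5 worst-covered genes.

A built-in simulator (`sim_config()` / `simulate_panel()`) generates a
complete synthetic study — genome, nested annotations, capture-kit
footprints of increasing size, and GC-biased negative-binomial depth
tracks for multi-sample cohorts — with every generating parameter recorded
in a `truth.json`, so the whole audit can be validated against known
ground truth.

## Worked example

Simulate the default study (50 genes, four capture kits with footprints
92/97/98/99% of the subset database, cohorts of 20/94/93/6 samples at
target depths 30.5/80/48/63X, GC penalty on log depth) and audit it:

```r
library(panelcov)

cfg  <- sim_config(seed = 1)
sim  <- simulate_panel(cfg, "study")
acfg <- audit_config(sim$paths$superset_bed, sim$paths$subset_bed,
                     sim$paths$fasta, sim$paths$manifest, "study/audit")
report <- run_report(acfg)

round(report$representation$overall_fraction, 4)
#> [1] 0.5284
round(sapply(report$kits, `[[`, "observed_mean_depth"), 1)
#>   V2   V3   V4   V5
#> 28.3 79.3 47.8 64.5
report$kits$V2$n_genes_median_below_optimal
#> [1] 26
report$gc_analysis$fit_gc
#> OLS fit (n = 50): y = 151.6 + -147.5 x;  r^2 = 0.5306,  p = 2.02e-09
```

Reading: only ~53% of the broad annotation's bases are even present in the
subset database the kits target; the shallowest cohort leaves 26 of 50
genes below the optimal 30X median; and GC content alone explains ~53% of
the between-gene variance in median coverage, with the expected negative
slope. `study/audit/` holds every table as TSV + JSON
(`representation`, per-kit `curve_*`, `gene_summary_*`, `variability_*`,
`gene_features`, `regressions`) and `report.json` aggregates the headline
numbers. The first lines of `representation.tsv`:

```
gene	subset_bases	superset_bases	percent
GENE001	92	920	10.00
GENE002	99	837	11.83
```

A thin command-line front end is included at
`inst/scripts/panelcov.R` (`simulate|represent|coverage|gc|report`, YAML
config).

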