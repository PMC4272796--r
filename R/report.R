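#' Configuration for a full coverage audit
#'
#' Collects the input paths and thresholds that every audit stage shares,
#' so threshold semantics (mean depth >= d is "captured"; "below optimal"
#' is strictly <) are defined once and cannot drift between stages.
#'
#' @param superset_bed,subset_bed 4-column BED files for the broad and the
#'   conservative annotation database.
#' @param fasta genome FASTA for GC content.
#' @param manifest sample manifest (see [read_manifest()]).
#' @param out_dir directory for all emitted tables.
#' @param min_depth minimum callable depth threshold (default 3).
#' @param optimal_depth confident-genotype depth threshold (default 30);
#'   must exceed `min_depth`.
#' @param max_depth upper end of coverage curves (default 200).
#' @param ci_bounds CI half-width bounds (reads) for the variability
#'   profile (default `c(5, 10)`).
#' @param extremes_k group size for the best-vs-worst-covered GC
#'   comparison (default 5).
#' @return an `audit_config` list.
#' @export
audit_config <- function(superset_bed, subset_bed, fasta, manifest, out_dir,
                         min_depth = 3, optimal_depth = 30, max_depth = 200L,
                         ci_bounds = c(5, 10), extremes_k = 5L) {
  if (min_depth >= optimal_depth)
    stop("audit_config: min_depth must be below optimal_depth")
  for (p in c(superset_bed, subset_bed, fasta, manifest))
    if (!file.exists(p)) stop(sprintf("audit_config: missing input: %s", p))
  structure(list(superset_bed = superset_bed, subset_bed = subset_bed,
                 fasta = fasta, manifest = manifest, out_dir = out_dir,
                 min_depth = min_depth, optimal_depth = optimal_depth,
                 max_depth = as.integer(max_depth), ci_bounds = ci_bounds,
                 extremes_k = as.integer(extremes_k)),
            class = "audit_config")
}

# every emitted table gets a TSV (floats at 6 significant digits) and a
# byte-stable JSON twin
write_table <- function(df, stem) {
  out <- as.data.frame(df)
  num <- vapply(out, function(x) is.numeric(x) && !is.integer(x) &&
                  !all(x == round(x), na.rm = TRUE), logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 6))
  data.table::fwrite(out, paste0(stem, ".tsv"), sep = "\t", quote = FALSE)
  jsonlite::write_json(out, paste0(stem, ".json"), digits = NA,
                       dataframe = "rows")
  invisible(c(paste0(stem, ".tsv"), paste0(stem, ".json")))
}

load_audit_dbs <- function(cfg) {
  superset <- build_db(read_bed(cfg$superset_bed), "superset")
  subset <- suppressWarnings(
    enforce_nesting(build_db(read_bed(cfg$subset_bed), "subset"), superset))
  list(superset = superset, subset = subset)
}

#' Audit stage: annotation representation
#'
#' Computes the per-gene and pooled representation of the superset
#' database in the subset database and writes
#' `<out_dir>/representation.tsv` (+ JSON twin).
#'
#' @param cfg an [audit_config()].
#' @return the representation `data.frame`, invisibly-written to disk.
#' @export
run_represent <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  dbs <- load_audit_dbs(cfg)
  tab <- representation_table(dbs$subset, dbs$superset)
  write_representation_tsv(tab, file.path(cfg$out_dir, "representation.tsv"))
  jsonlite::write_json(tab, file.path(cfg$out_dir, "representation.json"),
                       digits = NA, dataframe = "rows")
  tab
}

# view of a depth matrix restricted to the bases of a region
restrict_matrix <- function(m, region) {
  pos_dt <- interval_positions(region)
  keep <- !is.na(m$positions[pos_dt, which = TRUE, on = c("chrom", "pos")])
  idx <- m$positions[pos_dt[keep], which = TRUE, on = c("chrom", "pos")]
  structure(list(positions = m$positions[idx],
                 samples = m$samples,
                 depths = m$depths[idx, , drop = FALSE]),
            class = "sample_depth_matrix")
}

#' Audit stage: coverage statistics per kit
#'
#' For every capture kit in the manifest: builds the per-base x per-sample
#' depth matrix over the superset universe, averages it into a mean-depth
#' track, and computes (a) cumulative coverage curves against both
#' databases, (b) capture fractions at the configured thresholds, (c) the
#' observed mean depth over the subset region, (d) per-gene coverage
#' summaries against the subset database, and (e) the inter-sample
#' variability profile over captured subset bases. All tables are written
#' under `out_dir` with JSON twins.
#'
#' @param cfg an [audit_config()].
#' @return a list with per-kit results (`curves`, `capture`, `summaries`,
#'   `variability`, `observed_depth`, `flags`) and the loaded databases.
#' @export
run_coverage <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  dbs <- load_audit_dbs(cfg)
  manifest <- read_manifest(cfg$manifest)
  sup_union <- db_union(dbs$superset)
  sub_union <- db_union(dbs$subset)
  kits <- unique(manifest$kit)
  res <- list()
  for (kit_name in kits) {
    m <- kit_depth_matrix(manifest, kit_name, sup_union)
    track <- mean_track(m)
    curves <- list(subset = coverage_curve(track, sub_union, cfg$max_depth),
                   superset = coverage_curve(track, sup_union, cfg$max_depth))
    for (dbn in names(curves))
      write_table(curves[[dbn]],
                  file.path(cfg$out_dir, sprintf("curve_%s_%s", kit_name, dbn)))
    capture <- data.frame(
      database = rep(c("subset", "superset"), each = 2),
      threshold = rep(c(cfg$min_depth, cfg$optimal_depth), 2),
      fraction = c(capture_fraction(track, sub_union, cfg$min_depth),
                   capture_fraction(track, sub_union, cfg$optimal_depth),
                   capture_fraction(track, sup_union, cfg$min_depth),
                   capture_fraction(track, sup_union, cfg$optimal_depth)))
    summaries <- gene_summaries(track, dbs$subset,
                                optimal_depth = cfg$optimal_depth)
    write_table(summaries,
                file.path(cfg$out_dir, sprintf("gene_summary_%s", kit_name)))
    vm <- restrict_matrix(m, sub_union)
    vp <- if (ncol(m$depths) >= 2L)
      intersample_variability(vm, bounds = cfg$ci_bounds) else NULL
    if (!is.null(vp)) {
      hist_dt <- data.frame(
        bound = cfg$ci_bounds,
        fraction_within = unname(vp$fraction_within))
      write_table(hist_dt,
                  file.path(cfg$out_dir, sprintf("variability_%s", kit_name)))
    }
    res[[kit_name]] <- list(
      curves = curves, capture = capture, summaries = summaries,
      variability = vp,
      observed_depth = overall_mean_depth(track, sub_union),
      flags = count_flags(summaries))
  }
  list(kits = res, dbs = dbs, manifest = manifest)
}

#' Audit stage: GC and size drivers of coverage
#'
#' Builds the per-gene feature table (size, GC over subset regions, median
#' coverage from the kit with the highest observed mean depth), fits the
#' two simple regressions of median coverage on GC and on size, and runs
#' the best-vs-worst-covered GC comparison. Writes `gene_features` and
#' `regressions` tables under `out_dir`.
#'
#' @param cfg an [audit_config()].
#' @param coverage output of [run_coverage()]; recomputed when `NULL`.
#' @return list with `features`, `fit_gc`, `fit_size`, `extremes`,
#'   `focal_kit`.
#' @export
run_gc <- function(cfg, coverage = NULL) {
  if (is.null(coverage)) coverage <- run_coverage(cfg)
  depths <- vapply(coverage$kits, `[[`, numeric(1), "observed_depth")
  focal <- names(depths)[which.max(depths)]
  features <- gene_features(coverage$dbs$subset, cfg$fasta,
                            coverage$kits[[focal]]$summaries)
  write_table(features, file.path(cfg$out_dir, "gene_features"))
  fit_gc <- fit_ols(features$gc_fraction, features$median_coverage)
  fit_size <- fit_ols(features$size_bases, features$median_coverage)
  extremes <- extremes_gc_test(features, k = cfg$extremes_k)
  reg <- data.frame(
    model = c("median_coverage ~ gc_fraction", "median_coverage ~ size_bases"),
    slope = c(fit_gc$slope, fit_size$slope),
    intercept = c(fit_gc$intercept, fit_size$intercept),
    r_squared = c(fit_gc$r_squared, fit_size$r_squared),
    p_value = c(fit_gc$p_value, fit_size$p_value),
    n = c(fit_gc$n, fit_size$n))
  write_table(reg, file.path(cfg$out_dir, "regressions"))
  list(features = features, fit_gc = fit_gc, fit_size = fit_size,
       extremes = extremes, focal_kit = focal)
}

#' Run the complete audit and write the combined report
#'
#' Orchestrates [run_represent()], [run_coverage()] and [run_gc()] and
#' writes `report.json`: the pooled representation, per-kit capture
#' fractions at both thresholds, observed mean depths, uniformity flag
#' counts, inter-sample variability, the two regressions, and the
#' best-vs-worst GC comparison, together with an inventory of every table
#' the stages emitted. Re-running on the same inputs reproduces the same
#' bytes.
#'
#' @param cfg an [audit_config()].
#' @return the report, a nested list (also serialized to
#'   `<out_dir>/report.json`).
#' @export
run_report <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  rep_tab <- run_represent(cfg)
  coverage <- run_coverage(cfg)
  gc <- run_gc(cfg, coverage)
  kits <- names(coverage$kits)
  per_kit <- lapply(kits, function(k) {
    r <- coverage$kits[[k]]
    list(kit = k,
         n_samples = sum(coverage$manifest$kit == k),
         observed_mean_depth = r$observed_depth,
         capture = r$capture,
         n_genes_median_below_optimal = unname(r$flags["n_median_below"]),
         n_genes_iqr_above_optimal = unname(r$flags["n_iqr_above"]),
         fraction_within = if (!is.null(r$variability))
           as.list(r$variability$fraction_within) else NULL)
  })
  names(per_kit) <- kits
  overall <- rep_tab[rep_tab$gene == "ALL", ]
  report <- list(
    thresholds = list(min_depth = cfg$min_depth,
                      optimal_depth = cfg$optimal_depth),
    representation = list(
      overall_fraction = overall$fraction,
      subset_bases = overall$subset_bases,
      superset_bases = overall$superset_bases,
      per_gene_range = range(rep_tab$fraction[rep_tab$gene != "ALL"])),
    kits = per_kit,
    gc_analysis = list(
      focal_kit = gc$focal_kit,
      fit_gc = unclass(gc$fit_gc),
      fit_size = unclass(gc$fit_size),
      extremes = gc$extremes[c("mean_top", "mean_bottom", "t", "df",
                               "p_value")]),
    tables = sort(setdiff(list.files(cfg$out_dir, pattern = "\\.(tsv|json)$"),
                          "report.json")))
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(report)
}
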