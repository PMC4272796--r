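#' GC fraction of a region set from a genome FASTA
#'
#' Counts A/C/G/T case-insensitively over all bases of `regions` and
#' returns (G + C) / (A + C + G + T). Ambiguity codes (N and friends) are
#' excluded from both numerator and denominator — the statistic is the GC
#' share among *unambiguous* bases. Soft-masked lowercase counts like
#' uppercase.
#'
#' @param fasta path to a FASTA file, or a [Biostrings::DNAStringSet].
#'   FASTA headers are truncated at the first whitespace to get sequence
#'   names.
#' @param regions a `GRanges`; merged to unique locations before counting
#'   so no base is counted twice. Every region must lie within its
#'   sequence's bounds.
#' @return a fraction in `[0, 1]`; errors if the region set contains no
#'   unambiguous base.
#' @export
gc_content <- function(fasta, regions) {
  counts <- nuc_counts(fasta, regions)
  acgt <- sum(counts)
  if (acgt == 0)
    stop("gc_content: no unambiguous (A/C/G/T) bases in regions")
  unname((counts["C"] + counts["G"]) / acgt)
}

#' @rdname gc_content
#' @return `nuc_counts()`: named vector of A/C/G/T counts over the regions.
#' @export
nuc_counts <- function(fasta, regions) {
  nuc_counts_core(load_fasta(fasta), merge_core(ivl_df(allow_empty(regions))))
}

# x: canonical coordinate core (0-based half-open)
nuc_counts_core <- function(seqs, x) {
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  if (length(x$chrom) == 0L) return(counts)
  missing <- setdiff(unique(x$chrom), names(seqs))
  if (length(missing))
    stop(sprintf("gc_content: sequence(s) not in FASTA: %s",
                 paste(missing, collapse = ", ")))
  for (ch in unique(x$chrom)) {
    sel <- x$chrom == ch
    s <- x$start[sel] + 1L
    e <- x$end[sel]
    if (any(e > length(seqs[[ch]])))
      stop(sprintf("gc_content: region beyond end of sequence '%s'", ch))
    v <- Biostrings::Views(seqs[[ch]], start = s, end = e)
    counts <- counts + colSums(Biostrings::letterFrequency(
      v, letters = c("A", "C", "G", "T")))
  }
  counts
}

gc_of_counts <- function(counts) {
  acgt <- sum(counts)
  if (acgt == 0) return(NA_real_)
  unname((counts["C"] + counts["G"]) / acgt)
}

load_fasta <- function(fasta) {
  if (methods::is(fasta, "DNAStringSet")) {
    seqs <- fasta
  } else {
    if (!file.exists(fasta)) stop(sprintf("FASTA not found: %s", fasta))
    seqs <- Biostrings::readDNAStringSet(fasta)
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Per-gene size, GC and coverage feature table
#'
#' Joins each gene model's unique-base size and GC fraction with its
#' median coverage from [gene_summaries()]. Genes whose regions contain no
#' unambiguous base, or whose model has no base in the depth track's
#' universe, are excluded with a warning — they cannot enter a regression.
#'
#' @param db an `annotation_db` (the conservative/subset database, over
#'   which coverage and GC are defined).
#' @param fasta genome FASTA path or `DNAStringSet`.
#' @param summaries output of [gene_summaries()] for the same `db`.
#' @return a `data.frame` with columns `gene`, `size_bases`,
#'   `gc_fraction`, `median_coverage`.
#' @export
gene_features <- function(db, fasta, summaries) {
  seqs <- load_fasta(fasta)
  genes <- db_genes(db)
  rows <- lapply(genes, function(g) {
    gc <- gc_of_counts(nuc_counts_core(seqs, db$models[[g]]))
    data.frame(gene = g, size_bases = core_width(db$models[[g]]),
               gc_fraction = gc, stringsAsFactors = FALSE)
  })
  feat <- do.call(rbind, rows)
  feat <- merge(feat,
                summaries[, c("gene", "median", "n_bases_in_track")],
                by = "gene", sort = TRUE)
  names(feat)[names(feat) == "median"] <- "median_coverage"
  drop_gc <- is.na(feat$gc_fraction)
  drop_track <- feat$n_bases_in_track == 0
  if (any(drop_gc))
    warning(sprintf("gene_features: excluding gene(s) with undefined GC: %s",
                    paste(feat$gene[drop_gc], collapse = ", ")))
  if (any(drop_track & !drop_gc))
    warning(sprintf("gene_features: excluding gene(s) absent from depth track: %s",
                    paste(feat$gene[drop_track & !drop_gc], collapse = ", ")))
  feat <- feat[!drop_gc & !drop_track,
               c("gene", "size_bases", "gc_fraction", "median_coverage")]
  rownames(feat) <- NULL
  feat
}

#' Simple linear regression with slope test
#'
#' Ordinary least squares of `y` on a single predictor `x`, reporting the
#' slope, intercept, coefficient of determination, and the two-sided
#' p-value of the slope's t-test on n - 2 degrees of freedom (equivalent
#' to the regression F-test). Used for the coverage-vs-GC and
#' coverage-vs-size associations; predictors enter untransformed.
#'
#' @param x numeric predictor (e.g. GC fraction or gene size in bases).
#' @param y numeric response (e.g. per-gene median coverage).
#' @return an `ols_fit`: list with `slope`, `intercept`, `r_squared`,
#'   `p_value`, `se_slope`, `n`.
#' @export
fit_ols <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("fit_ols: need at least 3 observations")
  if (stats::var(x) == 0) stop("fit_ols: constant predictor (degenerate)")
  fit <- stats::lm(y ~ x)
  # a perfect fit triggers a harmless "essentially perfect fit" warning
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  structure(list(slope = unname(co["x", "Estimate"]),
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 r_squared = sm$r.squared,
                 p_value = unname(co["x", "Pr(>|t|)"]),
                 se_slope = unname(co["x", "Std. Error"]),
                 n = n),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d): y = %.4g + %.4g x;  r^2 = %.4g,  p = %.3g\n",
              x$n, x$intercept, x$slope, x$r_squared, x$p_value))
  invisible(x)
}

#' Compare GC content of the best- and worst-covered genes
#'
#' Ranks genes by median coverage and compares the GC fractions of the
#' top-k against the bottom-k by a two-sided two-sample t-test (Welch by
#' default; pooled variance available). Ties in coverage are broken by
#' gene symbol so the grouping is deterministic. If both groups are
#' constant the test is degenerate: equal means return p = 1, unequal
#' means return p = 0 with a warning.
#'
#' @param features output of [gene_features()].
#' @param k group size (default 5).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return list with `mean_top`, `mean_bottom` (mean GC fractions),
#'   `t`, `df`, `p_value`, `top_genes`, `bottom_genes`.
#' @export
extremes_gc_test <- function(features, k = 5L, var_equal = FALSE) {
  if (nrow(features) < 2L * k)
    stop(sprintf("extremes_gc_test: need at least %d genes, have %d",
                 2L * k, nrow(features)))
  ord <- order(-features$median_coverage, features$gene)
  top <- features[ord[seq_len(k)], ]
  bottom <- features[rev(ord)[seq_len(k)], ]
  gt <- top$gc_fraction; gb <- bottom$gc_fraction
  if (stats::var(gt) == 0 && stats::var(gb) == 0) {
    if (mean(gt) == mean(gb)) {
      res <- list(t = 0, df = 2 * (k - 1), p_value = 1)
    } else {
      warning("extremes_gc_test: zero variance in both groups; p -> 0")
      res <- list(t = sign(mean(gt) - mean(gb)) * Inf,
                  df = 2 * (k - 1), p_value = 0)
    }
  } else {
    tt <- stats::t.test(gt, gb, var.equal = var_equal)
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value)
  }
  c(list(mean_top = mean(gt), mean_bottom = mean(gb)), res,
    list(top_genes = top$gene, bottom_genes = bottom$gene))
}
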