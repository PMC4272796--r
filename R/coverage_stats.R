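#' Cumulative coverage curve over a target region
#'
#' For each integer depth threshold `1..max_depth`, the fraction of target
#' bases whose cross-sample mean depth is at least the threshold.
#' Denominators are `total_bases(targets)`, so bases missing from capture
#' count as depth 0 and the curve honestly reflects uncaptured territory.
#' The curve is non-increasing in the threshold by construction.
#'
#' @param track mean-depth `data.table` from [mean_track()].
#' @param targets canonical, non-empty `GRanges`.
#' @param max_depth largest threshold to evaluate (default 200).
#' @return a `data.frame` with columns `threshold` and `fraction`.
#' @export
coverage_curve <- function(track, targets, max_depth = 200L) {
  v <- region_depths(track, targets)
  if (length(v) == 0L) stop("coverage_curve: empty target set")
  sv <- sort(v)
  thresholds <- seq_len(max_depth)
  # count(depth >= d) = n - count(depth <= d - eps); mean depths are
  # multiples of 1/n_samples, so eps = 1e-9 cannot straddle a value
  below <- findInterval(thresholds - 1e-9, sv)
  data.frame(threshold = thresholds,
             fraction = (length(sv) - below) / length(sv))
}

#' Capture fraction at a single depth threshold
#'
#' Share of target bases with mean depth >= `d`; the single-point reading
#' of [coverage_curve()]. `d = 0` is 1 by definition.
#'
#' @inheritParams coverage_curve
#' @param d depth threshold (e.g. 3 for minimum callable, 30 for a
#'   confident genotype).
#' @return a fraction in `[0, 1]`.
#' @export
capture_fraction <- function(track, targets, d) {
  v <- region_depths(track, targets)
  if (length(v) == 0L) stop("capture_fraction: empty target set")
  if (d <= 0) return(1)
  mean(v >= d)
}

#' Per-gene coverage summaries (median, quartiles, uniformity flags)
#'
#' For every gene model, computes quartiles of the per-base mean depths
#' over the gene's regions (zero-filled to the full model), and two
#' uniformity flags: `median_below_optimal` (median strictly below the
#' optimal depth) and `iqr_above_optimal` (first quartile at or above it —
#' the box of the gene's box-plot sits entirely at or above the optimal
#' depth). Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7); the convention is configurable because
#' different environments disagree at small n.
#'
#' @param track mean-depth `data.table` from [mean_track()].
#' @param db an `annotation_db` of gene models.
#' @param optimal_depth flag threshold in reads (default 30).
#' @param quantile_type passed to [stats::quantile()] (default 7).
#' @param iqr_rule `"q1"` flags genes whose first quartile reaches the
#'   optimal depth; `"width"` instead flags `q3 - q1 >= optimal_depth`.
#' @return a `data.frame` with columns `gene`, `n_bases`,
#'   `n_bases_in_track`, `q1`, `median`, `q3`, `median_below_optimal`,
#'   `iqr_above_optimal`, ordered by gene symbol.
#' @export
gene_summaries <- function(track, db, optimal_depth = 30,
                           quantile_type = 7L,
                           iqr_rule = c("q1", "width")) {
  iqr_rule <- match.arg(iqr_rule)
  if (length(db$models) == 0L) stop("gene_summaries: empty annotation db")
  rows <- lapply(db_genes(db), function(g) {
    pos_dt <- positions_core(db$models[[g]])
    v <- track[pos_dt, mean_depth, on = c("chrom", "pos")]
    in_track <- sum(!is.na(v))
    v[is.na(v)] <- 0
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = quantile_type,
                         names = FALSE)
    data.frame(gene = g, n_bases = length(v), n_bases_in_track = in_track,
               q1 = q[1], median = q[2], q3 = q[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$median_below_optimal <- out$median < optimal_depth
  out$iqr_above_optimal <- if (iqr_rule == "q1") out$q1 >= optimal_depth
                           else (out$q3 - out$q1) >= optimal_depth
  out
}

#' Tally the uniformity flags across a gene panel
#'
#' @param summaries output of [gene_summaries()].
#' @return named integer vector: `n_median_below` (genes whose median is
#'   below the optimal depth) and `n_iqr_above` (genes whose quartile box
#'   clears it).
#' @export
count_flags <- function(summaries) {
  c(n_median_below = sum(summaries$median_below_optimal),
    n_iqr_above = sum(summaries$iqr_above_optimal))
}

#' Inter-sample variability of per-base depth
#'
#' For every target base, the half-width of the normal-approximation 95%
#' confidence interval of depth across samples, `1.96 * sd / sqrt(n)`
#' (sample standard deviation, n - 1 denominator). The profile's
#' `fraction_within(k)` is the share of bases whose half-width is at most
#' `k` reads — the "bases within +/- k reads" statistic.
#'
#' @param m a `sample_depth_matrix` with at least 2 samples.
#' @param bounds half-width bounds (reads) at which to pre-tabulate
#'   `fraction_within`; default `c(5, 10)`.
#' @return a `variability_profile`: list with `half_widths` (a
#'   `data.table` of `chrom`, `pos`, `half_width`), `n_samples`, and
#'   `fraction_within` (named vector over `bounds`).
#' @export
intersample_variability <- function(m, bounds = c(5, 10)) {
  stopifnot(inherits(m, "sample_depth_matrix"))
  n <- ncol(m$depths)
  if (n < 2L)
    stop("intersample_variability: need >= 2 samples (SD undefined)")
  mu <- rowMeans(m$depths)
  sd_row <- sqrt(rowSums((m$depths - mu)^2) / (n - 1))
  hw <- 1.96 * sd_row / sqrt(n)
  dt <- data.table::copy(m$positions)
  dt[, half_width := hw]
  fw <- vapply(bounds, function(k) mean(hw <= k), numeric(1))
  structure(list(half_widths = dt[], n_samples = n,
                 fraction_within = stats::setNames(fw, paste0("k", bounds))),
            class = "variability_profile")
}

#' @export
print.variability_profile <- function(x, ...) {
  cat(sprintf("variability_profile: %d bases, %d samples\n",
              nrow(x$half_widths), x$n_samples))
  for (i in seq_along(x$fraction_within))
    cat(sprintf("  fraction within +/-%s reads: %.3f\n",
                sub("^k", "", names(x$fraction_within)[i]),
                x$fraction_within[i]))
  invisible(x)
}

#' Fraction of bases within a CI half-width bound
#'
#' @param profile a `variability_profile`.
#' @param k half-width bound in reads.
#' @return share of bases with CI half-width <= `k`.
#' @export
fraction_within <- function(profile, k) {
  stopifnot(inherits(profile, "variability_profile"))
  mean(profile$half_widths$half_width <= k)
}
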