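# Brute-force oracles: every interval statistic recomputed on explicit
# per-base sets, independent of the interval algebra under test.

# an interval data.frame (chrom, start, end; 0-based half-open) -> the
# character set of its bases, "chrom:pos"
oracle_bases <- function(df) {
  if (nrow(df) == 0) return(character())
  unique(unlist(lapply(seq_len(nrow(df)), function(i)
    paste0(df$chrom[i], ":", seq.int(df$start[i], df$end[i] - 1L)))))
}

gr_bases <- function(gr) {
  p <- interval_positions(gr)
  if (nrow(p) == 0) return(character())
  paste0(p$chrom, ":", p$pos)
}

gr_from_df <- function(df) gintervals(df$chrom, df$start, df$end)

df_from_gr <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# a set is canonical iff sorted by (chrom, start) with a gap >= 1 base
# between same-chromosome neighbours
expect_canonical <- function(gr) {
  df <- df_from_gr(gr)
  ord <- order(df$chrom, df$start)
  expect_identical(ord, seq_len(nrow(df)))
  if (nrow(df) > 1) {
    same <- df$chrom[-1] == df$chrom[-nrow(df)]
    expect_true(all(df$start[-1][same] > df$end[-nrow(df)][same]))
  }
}

random_raw_intervals <- function(n_max = 200, max_coord = 10000,
                                 n_chroms = 5, max_len = 50) {
  n <- sample.int(n_max, 1)
  start <- sample.int(max_coord - max_len, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = paste0("chr", sample.int(n_chroms, n, replace = TRUE)),
             start = start, end = start + len, stringsAsFactors = FALSE)
}

# independent quantile oracle: sort, then linearly interpolate between
# order statistics at h = (n - 1) p + 1 (the type-7 rule, by hand)
oracle_quartiles <- function(v) {
  s <- sort(v)
  n <- length(s)
  one <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  c(q1 = one(0.25), median = one(0.5), q3 = one(0.75))
}

# closed-form simple OLS via explicit normal equations
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  se <- sqrt(ss_res / (n - 2) / sxx)
  tval <- slope / se
  list(slope = slope, intercept = intercept,
       r_squared = 1 - ss_res / ss_tot,
       p_value = 2 * stats::pt(-abs(tval), df = n - 2))
}

# a small simulation config sized for unit tests
test_sim_config <- function(seed, n_genes = 12, kits = NULL, ...) {
  if (is.null(kits))
    kits <- data.frame(name = "K1", footprint_fraction = 0.95,
                       n_samples = 3L, mean_depth = 60)
  sim_config(seed = seed, n_genes = n_genes, exons_per_gene = 2L,
             exon_length = c(60L, 120L), inter_exon_gap = 40L,
             intergenic_gap = 80L, kits = kits, ...)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}
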