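make_track <- function(depths, chrom = "chr1", start = 0L) {
  data.table::data.table(chrom = chrom,
                         pos = seq.int(start, start + length(depths) - 1L),
                         mean_depth = as.double(depths))
}

test_that("coverage curves are step functions of the per-base depths", {
  targets <- gintervals("chr1", 0, 100)
  cc <- coverage_curve(make_track(rep(10, 100)), targets, max_depth = 20)
  expect_identical(cc$fraction, c(rep(1, 10), rep(0, 10)))

  # 92 of 100 target bases at depth >= 3
  cc2 <- coverage_curve(make_track(c(rep(5, 92), rep(1, 8))), targets, 10)
  expect_identical(cc2$fraction[cc2$threshold == 3], 0.92)

  zero <- coverage_curve(make_track(rep(0, 100)), targets, 10)
  expect_true(all(zero$fraction == 0))
  expect_error(coverage_curve(make_track(1), GenomicRanges::GRanges()), "empty")
})

test_that("curves are monotone non-increasing and agree with capture_fraction", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(50:300, 1)
    depths <- round(stats::rexp(n, 1 / 40), 2)
    targets <- gintervals("chr1", 0, n)
    cc <- coverage_curve(make_track(depths), targets, max_depth = 120)
    expect_true(all(diff(cc$fraction) <= 0))
    expect_true(all(cc$fraction >= 0 & cc$fraction <= 1))
    for (d in c(1, 3, 30, 120))
      expect_identical(capture_fraction(make_track(depths), targets, d),
                       cc$fraction[cc$threshold == d])
    # direct counting oracle at the audit thresholds
    expect_identical(capture_fraction(make_track(depths), targets, 3),
                     sum(depths >= 3) / n)
  }
})

test_that("capture fraction handles the trivial thresholds", {
  targets <- gintervals("chr1", 0, 100)
  tr <- make_track(c(rep(5, 55), rep(1, 45)))
  expect_identical(capture_fraction(tr, targets, 0), 1)
  expect_identical(capture_fraction(tr, targets, 3), 0.55)
  expect_identical(capture_fraction(tr, targets, 1000), 0)
})

test_that("uncaptured target bases count as depth zero in the curve denominator", {
  # track covers only half the target: fractions can never exceed 0.5
  targets <- gintervals("chr1", 0, 100)
  tr <- make_track(rep(50, 50))
  cc <- coverage_curve(tr, targets, 60)
  expect_identical(cc$fraction[cc$threshold == 1], 0.5)
  expect_identical(cc$fraction[cc$threshold == 50], 0.5)
  expect_identical(cc$fraction[cc$threshold == 51], 0)
})

test_that("gene summaries report interpolated quartiles and threshold flags", {
  db <- build_db(gintervals("chr1", 0, 5, name = "A"), "t")
  s <- gene_summaries(make_track(c(10, 20, 30, 40, 50)), db)
  expect_identical(s$q1, 20)
  expect_identical(s$median, 30)
  expect_identical(s$q3, 40)
  expect_identical(s$n_bases, 5L)

  flat35 <- gene_summaries(make_track(rep(35, 5)), db)
  expect_false(flat35$median_below_optimal)
  expect_true(flat35$iqr_above_optimal)

  # strict < at the boundary: 29 is below optimal, 30 is not
  flat29 <- gene_summaries(make_track(rep(29, 5)), db)
  expect_true(flat29$median_below_optimal)
  expect_false(flat29$iqr_above_optimal)
  flat30 <- gene_summaries(make_track(rep(30, 5)), db)
  expect_false(flat30$median_below_optimal)
  expect_true(flat30$iqr_above_optimal)

  # alternative IQR-width rule behind the flag
  spread <- gene_summaries(make_track(c(0, 0, 50, 100, 100)), db,
                           iqr_rule = "width")
  expect_true(spread$iqr_above_optimal)
})

test_that("gene quartiles match the sort-based interpolation oracle", {
  set.seed(32)
  for (rep in 1:100) {
    n <- sample(4:60, 1)
    depths <- round(stats::runif(n, 0, 120), 3)
    db <- build_db(gintervals("chr1", 0, n, name = "G"), "t")
    s <- gene_summaries(make_track(depths), db)
    o <- oracle_quartiles(depths)
    expect_equal(c(q1 = s$q1, median = s$median, q3 = s$q3), o)
  }
})

test_that("flag tallies count the two uniformity flags", {
  db <- build_db(gintervals(rep("chr1", 3), c(0, 5, 10), c(5, 10, 15),
                            name = c("A", "B", "C")), "t")
  tr <- make_track(c(rep(100, 5), rep(100, 5), rep(100, 5)))
  expect_identical(count_flags(gene_summaries(tr, db)),
                   c(n_median_below = 0L, n_iqr_above = 3L))
  tr2 <- make_track(c(rep(5, 5), rep(100, 5), rep(100, 5)))
  expect_identical(count_flags(gene_summaries(tr2, db)),
                   c(n_median_below = 1L, n_iqr_above = 2L))
  empty <- gene_summaries(tr, db)[0, ]
  expect_identical(count_flags(empty), c(n_median_below = 0L, n_iqr_above = 0L))
})

test_that("well-separated depth regimes recover the constructed flag counts", {
  set.seed(33)
  n_genes <- 20; n_low <- 7; gene_len <- 40
  mu <- c(rep(8, n_low), rep(90, n_genes - n_low))
  depths <- unlist(lapply(mu, function(m)
    stats::rpois(gene_len, m)))
  starts <- (seq_len(n_genes) - 1) * gene_len
  db <- build_db(gintervals(rep("chr1", n_genes), starts, starts + gene_len,
                            name = sprintf("G%02d", seq_len(n_genes))), "t")
  flags <- count_flags(gene_summaries(make_track(depths), db))
  expect_identical(unname(flags["n_median_below"]), as.integer(n_low))
})

test_that("inter-sample CI half-widths follow the closed form", {
  targets <- gintervals("chr1", 0, 1)
  m <- build_depth_matrix(list(
    data.table::data.table(chrom = "chr1", pos = 0L, depth = 10L),
    data.table::data.table(chrom = "chr1", pos = 0L, depth = 20L)),
    targets, c("a", "b"))
  vp <- intersample_variability(m)
  # sd = 10/sqrt(2), half-width = 1.96 * (10/sqrt(2)) / sqrt(2) = 9.8
  expect_equal(vp$half_widths$half_width, 9.8)
  expect_identical(fraction_within(vp, 5), 0)
  expect_identical(fraction_within(vp, 10), 1)

  # identical samples: all half-widths zero
  rec <- data.table::data.table(chrom = "chr1", pos = 0:9,
                                depth = sample.int(100L, 10))
  mi <- build_depth_matrix(list(rec, rec, rec), gintervals("chr1", 0, 10),
                           c("a", "b", "c"))
  vpi <- intersample_variability(mi)
  expect_true(all(vpi$half_widths$half_width == 0))
  expect_identical(fraction_within(vpi, 0.001), 1)

  expect_error(intersample_variability(
    build_depth_matrix(list(rec), gintervals("chr1", 0, 10), "a")),
    ">= 2 samples")
})
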