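test_that("the same seed reproduces every emitted file byte for byte", {
  cfg <- test_sim_config(seed = 5, n_genes = 6)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  simulate_panel(cfg, d1)
  simulate_panel(cfg, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  # a different seed changes the data
  simulate_panel(test_sim_config(seed = 6, n_genes = 6), d2)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "genome.fa"))),
                         unname(tools::md5sum(file.path(d2, "genome.fa")))))
})

test_that("exonic base composition hits the per-gene GC targets", {
  # one long exon concentrates the binomial: realized GC within 0.02
  cfg <- sim_config(seed = 9, n_chroms = 1, n_genes = 2, exons_per_gene = 1,
                    exon_length = c(10000L, 10000L), gc_range = c(0.5, 0.5),
                    subset_fraction = c(1, 1),
                    kits = data.frame(name = "K", footprint_fraction = 1,
                                      n_samples = 1L, mean_depth = 10))
  g <- simulate_genome(cfg)
  sup <- build_db(simulate_annotations(cfg, g)$superset, "sup")
  for (gene in db_genes(sup))
    expect_equal(gc_content(g$seqs, gene_model(sup, gene)), 0.5, tolerance = 0.02)

  # target GC 1 -> all-G/C exons
  cfg2 <- sim_config(seed = 9, n_chroms = 1, n_genes = 2, exons_per_gene = 1,
                     exon_length = c(500L, 500L), gc_range = c(1, 1),
                     subset_fraction = c(1, 1), kits = cfg$kits)
  g2 <- simulate_genome(cfg2)
  sup2 <- build_db(simulate_annotations(cfg2, g2)$superset, "sup")
  for (gene in db_genes(sup2))
    expect_identical(gc_content(g2$seqs, gene_model(sup2, gene)), 1)
})

test_that("subset databases are strictly nested with the requested per-gene fractions", {
  cfg <- test_sim_config(seed = 21, n_genes = 10)
  g <- simulate_genome(cfg)
  ann <- simulate_annotations(cfg, g)
  sup <- build_db(ann$superset, "sup")
  sub <- build_db(ann$subset, "sub")
  genes <- db_genes(sup)
  expect_identical(db_genes(sub), genes)
  for (i in seq_along(genes)) {
    s_sup <- gene_model(sup, genes[i])
    s_sub <- gene_model(sub, genes[i])
    # strict nesting: no subset base outside the superset
    expect_identical(total_bases(subtract_sets(s_sub, s_sup)), 0)
    # quota met exactly (integer rounding of f * size)
    expect_identical(total_bases(s_sub),
                     round(cfg$subset_fraction[i] * total_bases(s_sup)))
  }
  # f = 1 makes the two databases base-identical
  cfg1 <- test_sim_config(seed = 22, n_genes = 4,
                          subset_fraction = rep(1, 4))
  g1 <- simulate_genome(cfg1)
  ann1 <- simulate_annotations(cfg1, g1)
  expect_identical(total_bases(subtract_sets(
    db_union(build_db(ann1$superset, "a")),
    db_union(build_db(ann1$subset, "b")))), 0)
})

test_that("a vanishing subset fraction is promoted to one base with a warning", {
  cfg <- test_sim_config(seed = 23, n_genes = 3,
                         subset_fraction = c(0.001, 0.5, 0.9))
  g <- simulate_genome(cfg)
  expect_warning(ann <- simulate_annotations(cfg, g), "rounds to 0")
  sub <- build_db(ann$subset, "sub")
  expect_identical(unname(gene_sizes(sub)["GENE001"]), 1)
})

test_that("kit footprints cover the requested fraction of subset bases", {
  cfg <- test_sim_config(seed = 24, n_genes = 15,
                         kits = data.frame(name = c("A", "B"),
                                           footprint_fraction = c(0.90, 0.99),
                                           n_samples = c(2L, 2L),
                                           mean_depth = c(40, 40)))
  out <- tempfile()
  sim <- simulate_panel(cfg, out)
  sub_total <- total_bases(db_union(build_db(sim$annotations$subset, "s")))
  for (k in c("A", "B")) {
    fp <- sim$depths$footprints[[k]]
    phi <- cfg$kits$footprint_fraction[cfg$kits$name == k]
    expect_equal(total_bases(fp), round(phi * sub_total))
    # footprint is carved out of the subset
    expect_identical(total_bases(subtract_sets(fp, db_union(build_db(sim$annotations$subset, "s")))), 0)
  }
})

test_that("simulated depth files are valid pipeline inputs and truth is recomputable", {
  cfg <- test_sim_config(seed = 25, n_genes = 8)
  out <- tempfile()
  sim <- simulate_panel(cfg, out)
  mf <- read_manifest(sim$paths$manifest)
  expect_identical(nrow(mf), sum(cfg$kits$n_samples))
  sub_union <- db_union(build_db(read_bed(sim$paths$subset_bed), "s"))
  m <- kit_depth_matrix(mf, "K1", sub_union)
  expect_identical(nrow(m$depths), as.integer(total_bases(sub_union)))

  # truth round-trip from the emitted files alone
  truth <- jsonlite::read_json(sim$paths$truth, simplifyVector = TRUE)
  sup_db <- build_db(read_bed(sim$paths$superset_bed), "sup")
  sub_db <- build_db(read_bed(sim$paths$subset_bed), "sub")
  expect_equal(unname(gene_sizes(sup_db)[truth$genes$gene]),
               truth$genes$size_superset)
  expect_equal(unname(gene_sizes(sub_db)[truth$genes$gene] /
                        gene_sizes(sup_db)[truth$genes$gene]),
               truth$genes$f_realized)
  gc_re <- vapply(truth$genes$gene, function(g)
    gc_content(sim$paths$fasta, gene_model(sub_db, g)), numeric(1))
  expect_equal(unname(gc_re), truth$genes$gc_realized)
})

test_that("the Poisson limit with no GC effect recovers the target mean depth", {
  cfg <- test_sim_config(seed = 26, n_genes = 10,
                         kits = data.frame(name = "K", footprint_fraction = 1,
                                           n_samples = 4L, mean_depth = 30),
                         gc_slope = 0, dispersion = Inf, sample_log_sd = 0)
  out <- tempfile()
  sim <- simulate_panel(cfg, out)
  sub_union <- db_union(build_db(read_bed(sim$paths$subset_bed), "s"))
  m <- kit_depth_matrix(read_manifest(sim$paths$manifest), "K", sub_union)
  # law of large numbers over ~ thousands of Poisson(30) draws
  expect_equal(overall_mean_depth(mean_track(m), sub_union), 30,
               tolerance = 0.02)
})
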