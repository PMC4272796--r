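#' Configuration for the panel-coverage simulator
#'
#' Bundles every knob of the synthetic study: genome and annotation shape,
#' the per-gene fraction of each gene retained by the conservative
#' (subset) database, the capture kits as footprint fractions of the
#' subset, per-kit sample counts and target mean depths, and the depth
#' model. Depth at a captured base of gene g in sample s is drawn
#' negative-binomially with mean `exp(alpha_kit + gc_slope * GC_g + eps_s)`
#' and dispersion `dispersion` (`Inf` gives the Poisson limit);
#' `eps_s ~ Normal(0, sample_log_sd^2)` is a per-sample multiplicative
#' effect on depth. `alpha_kit` is set so that the kit's realized mean
#' depth matches `mean_depth` at the footprint's base-weighted mean GC.
#'
#' The defaults describe a 50-gene clinical panel audited with four
#' capture-kit generations of increasing footprint (92/97/98/99% of the
#' subset) sequenced in cohorts of 20/94/93/6 samples at observed depths
#' near 30.5/80/48/63x, with subset representation spanning 10-97% per
#' gene, gene GC spread over 0.35-0.65, and a log-linear GC penalty on
#' depth.
#'
#' @param seed master seed; every random draw in the simulator flows from
#'   it through fixed substreams, so the same seed reproduces every file
#'   byte for byte.
#' @param n_chroms,n_genes genome/panel shape.
#' @param exons_per_gene exons per gene model.
#' @param exon_length length-2 integer range; exon lengths are drawn
#'   uniformly from it.
#' @param inter_exon_gap,intergenic_gap spacer lengths (bases) between
#'   exons and between genes.
#' @param gc_range length-2 range of per-gene target GC; targets are
#'   evenly spaced over it and assigned to genes in shuffled order.
#' @param subset_fraction per-gene fraction of superset bases kept in the
#'   subset database; default evenly spaced over `[0.10, 0.97]`.
#' @param kits `data.frame` with columns `name`, `footprint_fraction`,
#'   `n_samples`, `mean_depth`.
#' @param gc_slope slope of GC on log mean depth (expected negative).
#' @param dispersion negative-binomial size parameter; `Inf` = Poisson.
#' @param sample_log_sd SD of the per-sample effect on log mean depth.
#' @param background_gc GC of intergenic/intronic filler sequence.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       n_genes = 50L,
                       exons_per_gene = 4L,
                       exon_length = c(120L, 300L),
                       inter_exon_gap = 150L,
                       intergenic_gap = 400L,
                       gc_range = c(0.35, 0.65),
                       subset_fraction = NULL,
                       kits = default_kits(),
                       gc_slope = -2,
                       dispersion = 40,
                       sample_log_sd = 0.05,
                       background_gc = 0.5) {
  if (is.null(subset_fraction))
    subset_fraction <- seq(0.10, 0.97, length.out = n_genes)
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length = as.integer(exon_length),
              inter_exon_gap = as.integer(inter_exon_gap),
              intergenic_gap = as.integer(intergenic_gap),
              gc_range = gc_range, subset_fraction = subset_fraction,
              kits = kits, gc_slope = gc_slope, dispersion = dispersion,
              sample_log_sd = sample_log_sd, background_gc = background_gc)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_kits <- function() {
  data.frame(name = c("V2", "V3", "V4", "V5"),
             footprint_fraction = c(0.92, 0.97, 0.98, 0.99),
             n_samples = c(20L, 94L, 93L, 6L),
             mean_depth = c(30.5, 80, 48, 63),
             stringsAsFactors = FALSE)
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$subset_fraction) == cfg$n_genes)
  if (any(cfg$subset_fraction < 0 | cfg$subset_fraction > 1))
    stop("sim_config: subset_fraction must lie in [0, 1]")
  if (any(cfg$gc_range < 0 | cfg$gc_range > 1) ||
      cfg$background_gc < 0 || cfg$background_gc > 1)
    stop("sim_config: GC levels must lie in [0, 1]")
  k <- cfg$kits
  need <- c("name", "footprint_fraction", "n_samples", "mean_depth")
  if (!all(need %in% names(k)))
    stop(sprintf("sim_config: kits needs columns %s",
                 paste(need, collapse = ", ")))
  if (any(k$footprint_fraction <= 0 | k$footprint_fraction > 1))
    stop("sim_config: footprint_fraction must lie in (0, 1]")
  if (any(k$n_samples < 1) || any(k$mean_depth <= 0))
    stop("sim_config: kits need n_samples >= 1 and mean_depth > 0")
  if (cfg$exon_length[1] < 1L || cfg$exon_length[2] < cfg$exon_length[1])
    stop("sim_config: bad exon_length range")
  if (cfg$inter_exon_gap < 1L || cfg$intergenic_gap < 1L)
    stop("sim_config: gaps must be >= 1 so exons never abut")
  if (cfg$dispersion <= 0) stop("sim_config: dispersion must be > 0 (or Inf)")
  invisible(cfg)
}

# fixed substream derivation: every stage of the simulator seeds R's RNG
# from (master seed, stage index) so stages are independently reproducible
substream <- function(seed, i) {
  as.integer(((as.double(seed) %% 2147483563) * 69069 + i * 101) %% 2147483563)
}

#' Generate the synthetic genome and gene layout
#'
#' Lays genes out sequentially across chromosomes (round-robin), separated
#' by intergenic filler, with exons separated by short gaps. Exonic
#' sequence is drawn i.i.d. with per-gene base composition hitting the
#' gene's target GC in expectation; filler is drawn at `background_gc`.
#'
#' @param cfg a [sim_config()].
#' @return list with `seqs` (a `DNAStringSet`), `layout` (a `data.table`
#'   of `gene`, `chrom`, `start`, `end` per exon, 0-based half-open), and
#'   `gc_target` (named per-gene vector).
#' @export
simulate_genome <- function(cfg) {
  set.seed(substream(cfg$seed, 1L))
  genes <- sprintf("GENE%03d", seq_len(cfg$n_genes))
  gc_levels <- seq(cfg$gc_range[1], cfg$gc_range[2],
                   length.out = cfg$n_genes)
  gc_target <- stats::setNames(gc_levels[sample.int(cfg$n_genes)], genes)
  exon_len <- matrix(
    sample(seq(cfg$exon_length[1], cfg$exon_length[2]),
           cfg$n_genes * cfg$exons_per_gene, replace = TRUE),
    nrow = cfg$n_genes)
  chrom_of <- rep_len(seq_len(cfg$n_chroms), cfg$n_genes)
  layout <- vector("list", cfg$n_genes)
  cursor <- rep(cfg$intergenic_gap, cfg$n_chroms)
  for (i in seq_len(cfg$n_genes)) {
    ch <- chrom_of[i]
    starts <- integer(cfg$exons_per_gene)
    for (e in seq_len(cfg$exons_per_gene)) {
      starts[e] <- cursor[ch]
      cursor[ch] <- cursor[ch] + exon_len[i, e] + cfg$inter_exon_gap
    }
    cursor[ch] <- cursor[ch] - cfg$inter_exon_gap + cfg$intergenic_gap
    layout[[i]] <- data.table::data.table(
      gene = genes[i], chrom = sprintf("chr%d", ch),
      start = starts, end = starts + exon_len[i, ])
  }
  layout <- data.table::rbindlist(layout)
  chrom_len <- cursor
  seqs <- lapply(seq_len(cfg$n_chroms), function(ch) {
    base_probs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2,
                                 G = gc / 2, T = (1 - gc) / 2)
    s <- sample(c("A", "C", "G", "T"), chrom_len[ch], replace = TRUE,
                prob = base_probs(cfg$background_gc))
    ex <- layout[chrom == sprintf("chr%d", ch)]
    for (r in seq_len(nrow(ex))) {
      idx <- (ex$start[r] + 1L):ex$end[r]
      s[idx] <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE,
                       prob = base_probs(gc_target[ex$gene[r]]))
    }
    paste(s, collapse = "")
  })
  seqs <- Biostrings::DNAStringSet(
    stats::setNames(unlist(seqs), sprintf("chr%d", seq_len(cfg$n_chroms))))
  list(seqs = seqs, layout = layout, gc_target = gc_target)
}

#' Generate the nested annotation databases
#'
#' The superset database is every gene's full exon set; the subset keeps,
#' per gene, a prefix of the gene's bases (in genomic order, splitting an
#' exon where the quota falls inside it) totalling
#' `round(f_g * superset_bases)`. The subset is strictly nested by
#' construction. A fraction that rounds to 0 bases is promoted to a single
#' base with a warning, so every gene exists in both databases.
#'
#' @param cfg a [sim_config()].
#' @param genome output of [simulate_genome()].
#' @return list of `GRanges` `superset` and `subset`, both labeled with
#'   gene symbols in their `name` column.
#' @export
simulate_annotations <- function(cfg, genome) {
  lay <- genome$layout
  genes <- sprintf("GENE%03d", seq_len(cfg$n_genes))
  f <- stats::setNames(cfg$subset_fraction, genes)
  sub_rows <- vector("list", cfg$n_genes)
  for (i in seq_along(genes)) {
    ex <- lay[gene == genes[i]][order(chrom, start)]
    size <- sum(ex$end - ex$start)
    quota <- round(f[genes[i]] * size)
    if (quota == 0) {
      warning(sprintf("simulate_annotations: subset fraction for %s rounds to 0 bases; emitting 1 base",
                      genes[i]))
      quota <- 1
    }
    taken <- vector("list", nrow(ex))
    for (r in seq_len(nrow(ex))) {
      if (quota <= 0) break
      len <- min(ex$end[r] - ex$start[r], quota)
      taken[[r]] <- data.table::data.table(
        gene = genes[i], chrom = ex$chrom[r],
        start = ex$start[r], end = ex$start[r] + len)
      quota <- quota - len
    }
    sub_rows[[i]] <- data.table::rbindlist(taken)
  }
  sub <- data.table::rbindlist(sub_rows)
  list(superset = gintervals(lay$chrom, lay$start, lay$end, lay$gene),
       subset = gintervals(sub$chrom, sub$start, sub$end, sub$gene))
}

# pick a kit footprint: phi of the subset's bases, dropping the remainder
# from interval tails in shuffled interval order so dropout looks exon-like
kit_footprint <- function(subset_gr, phi, seed) {
  set.seed(seed)
  dt <- data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(subset_gr)),
    start = BiocGenerics::start(subset_gr) - 1L,
    end = BiocGenerics::end(subset_gr))
  total <- sum(dt$end - dt$start)
  drop <- total - round(phi * total)
  ord <- sample.int(nrow(dt))
  for (r in ord) {
    if (drop <= 0) break
    cut <- min(dt$end[r] - dt$start[r], drop)
    dt[r, end := end - cut]
    drop <- drop - cut
  }
  dt <- dt[end > start]
  merge_intervals(gintervals(dt$chrom, dt$start, dt$end))
}

#' Simulate per-sample depth files for every kit
#'
#' For each kit, selects a captured footprint covering
#' `footprint_fraction` of the subset database's bases, then draws an
#' integer depth for every captured base and sample from the negative
#' binomial model of [sim_config()]. Uncaptured bases are simply absent
#' from the files (the reader zero-fills them). Files are written as
#' 1-based `chrom<TAB>pos<TAB>depth` text, one per sample, plus a manifest.
#'
#' @param cfg a [sim_config()].
#' @param genome output of [simulate_genome()].
#' @param annotations output of [simulate_annotations()].
#' @param out_dir output directory (created if needed).
#' @return list with `manifest` (a `data.table` of `sample_id`, `file`,
#'   `kit`), `footprints` (named list of `GRanges`), `gc_realized`
#'   (per-gene GC over subset regions), and `alpha` (per-kit intercepts on
#'   log depth).
#' @export
simulate_depths <- function(cfg, genome, annotations, out_dir) {
  dir.create(file.path(out_dir, "depths"), recursive = TRUE,
             showWarnings = FALSE)
  subset_db <- build_db(annotations$subset, "subset")
  gc_real <- vapply(subset_db$models, function(m)
    gc_of_counts(nuc_counts_core(genome$seqs, m)), numeric(1))
  # map every subset base to its gene (genes never overlap by layout)
  gene_pos <- data.table::rbindlist(lapply(db_genes(subset_db), function(g) {
    p <- positions_core(subset_db$models[[g]])
    p[, gene := g]
    p
  }))
  data.table::setkey(gene_pos, chrom, pos)
  manifest <- list(); footprints <- list(); alpha <- numeric(0)
  for (k in seq_len(nrow(cfg$kits))) {
    kit <- cfg$kits$name[k]
    fp <- kit_footprint(annotations$subset, cfg$kits$footprint_fraction[k],
                        substream(cfg$seed, 10L + k))
    footprints[[kit]] <- fp
    pos <- interval_positions(fp)
    base_gene <- gene_pos[pos, gene, on = c("chrom", "pos")]
    gc_base <- gc_real[base_gene]
    a <- log(cfg$kits$mean_depth[k]) - cfg$gc_slope * mean(gc_base)
    alpha[kit] <- a
    set.seed(substream(cfg$seed, 100L + k))
    eps <- stats::rnorm(cfg$kits$n_samples[k], 0, cfg$sample_log_sd)
    rows <- vector("list", cfg$kits$n_samples[k])
    for (s in seq_len(cfg$kits$n_samples[k])) {
      mu <- exp(a + cfg$gc_slope * gc_base + eps[s])
      d <- if (is.infinite(cfg$dispersion)) stats::rpois(length(mu), mu)
           else stats::rnbinom(length(mu), size = cfg$dispersion, mu = mu)
      sid <- sprintf("%s_s%03d", kit, s)
      f <- file.path(out_dir, "depths", paste0(sid, ".tsv"))
      data.table::fwrite(
        data.table::data.table(pos$chrom, pos$pos + 1L, d), f,
        sep = "\t", col.names = FALSE, quote = FALSE)
      rows[[s]] <- data.table::data.table(
        sample_id = sid, file = file.path("depths", paste0(sid, ".tsv")),
        kit = kit)
    }
    manifest[[kit]] <- data.table::rbindlist(rows)
  }
  manifest <- data.table::rbindlist(manifest)
  data.table::fwrite(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE)
  list(manifest = manifest, footprints = footprints,
       gc_realized = gc_real, alpha = alpha)
}

#' Run the full simulator and write a self-contained fixture directory
#'
#' Emits a genome FASTA, superset/subset BED, per-kit footprint BED,
#' per-sample depth TSVs, a manifest, and a `truth.json` recording every
#' recoverable ground-truth parameter (per-gene realized subset fractions
#' and GC, per-kit footprints and expected per-gene mean depths
#' `mu_gk = exp(alpha_k + gc_slope * GC_g)`).
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with the config, file paths, and the in-memory
#'   genome/annotations/depth objects.
#' @export
simulate_panel <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- simulate_genome(cfg)
  ann <- simulate_annotations(cfg, genome)
  fasta <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(genome$seqs, fasta, width = 70L)
  superset_bed <- file.path(out_dir, "superset.bed")
  subset_bed <- file.path(out_dir, "subset.bed")
  write_bed(ann$superset, superset_bed)
  write_bed(ann$subset, subset_bed)
  dp <- simulate_depths(cfg, genome, ann, out_dir)
  kit_dir <- file.path(out_dir, "kits")
  dir.create(kit_dir, showWarnings = FALSE)
  for (kit in names(dp$footprints))
    write_bed(dp$footprints[[kit]], file.path(kit_dir, paste0(kit, ".bed")))
  sup_db <- build_db(ann$superset, "superset")
  sub_db <- build_db(ann$subset, "subset")
  genes <- db_genes(sup_db)
  sup_sz <- gene_sizes(sup_db); sub_sz <- gene_sizes(sub_db)
  mu <- outer(dp$gc_realized[genes], dp$alpha,
              function(gc, a) exp(a + cfg$gc_slope * gc))
  truth <- list(
    seed = cfg$seed,
    gc_slope = cfg$gc_slope,
    dispersion = cfg$dispersion,
    sample_log_sd = cfg$sample_log_sd,
    genes = data.frame(
      gene = genes,
      f_target = cfg$subset_fraction,
      f_realized = unname(sub_sz[genes] / sup_sz[genes]),
      gc_target = unname(genome$gc_target[genes]),
      gc_realized = unname(dp$gc_realized[genes]),
      size_superset = unname(sup_sz[genes]),
      size_subset = unname(sub_sz[genes])),
    kits = data.frame(
      name = cfg$kits$name,
      n_samples = cfg$kits$n_samples,
      footprint_fraction_target = cfg$kits$footprint_fraction,
      footprint_bases = vapply(dp$footprints[cfg$kits$name], total_bases,
                               numeric(1)),
      footprint_fraction_realized =
        vapply(dp$footprints[cfg$kits$name], total_bases, numeric(1)) /
          total_bases(db_union(sub_db)),
      mean_depth_target = cfg$kits$mean_depth,
      alpha = unname(dp$alpha[cfg$kits$name])),
    expected_mean_depth = as.data.frame(mu))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(list(
    config = cfg,
    paths = list(out_dir = out_dir, fasta = fasta,
                 superset_bed = superset_bed, subset_bed = subset_bed,
                 manifest = file.path(out_dir, "manifest.tsv"),
                 truth = file.path(out_dir, "truth.json")),
    genome = genome, annotations = ann, depths = dp, truth = truth))
}
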