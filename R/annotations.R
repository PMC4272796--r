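#' Build a per-gene annotation database from labeled intervals
#'
#' Groups labeled intervals (e.g. coding exons of every transcript) by gene
#' symbol and collapses each gene's intervals to unique locations, yielding
#' one gene model per symbol. Gene symbols are matched exactly and
#' case-sensitively; duplicate records are harmless (set semantics).
#'
#' Gene models are held internally as plain coordinate tables for speed;
#' use [gene_model()] to obtain any gene's regions as a `GRanges`.
#'
#' @param gr a `GRanges` whose `name` metadata column carries the gene
#'   symbol of every record; an unlabeled record is an error.
#' @param name database label, e.g. `"CCDS-like"` or `"KnownGene-like"`.
#' @return an `annotation_db`: a list with elements `name` and `models`
#'   (one canonical region table per gene, names sorted).
#' @export
build_db <- function(gr, name) {
  assert_valid_intervals(gr)
  labels <- S4Vectors::mcols(gr)$name
  if (length(gr) > 0L && (is.null(labels) || anyNA(labels) || any(!nzchar(labels)))) {
    bad <- if (is.null(labels)) 1L else which(is.na(labels) | !nzchar(labels))[1]
    stop(sprintf("build_db: record %d has no gene label", bad))
  }
  core <- ivl_df(gr)
  idx <- split(seq_along(core$chrom), labels)
  models <- lapply(idx, function(i)
    merge_core(list(chrom = core$chrom[i], start = core$start[i],
                    end = core$end[i])))
  models <- models[order(names(models))]
  structure(list(name = name, models = models), class = "annotation_db")
}

core_width <- function(x) sum(as.double(x$end - x$start))

#' @export
print.annotation_db <- function(x, ...) {
  sizes <- gene_sizes(x)
  cat(sprintf("annotation_db '%s': %d genes, %s unique bases\n",
              x$name, length(x$models),
              format(sum(sizes), big.mark = ",")))
  invisible(x)
}

#' Extract one gene's regions as a GRanges
#'
#' @param db an `annotation_db` from [build_db()].
#' @param gene gene symbol.
#' @return a canonical `GRanges` of the gene's unique-base regions.
#' @export
gene_model <- function(db, gene) {
  m <- db$models[[gene]]
  if (is.null(m))
    stop(sprintf("gene '%s' not in database '%s'", gene, db$name))
  ivl_to_gr(m)
}

#' Gene symbols and unique-base sizes of a database
#'
#' @param db an `annotation_db` from [build_db()].
#' @return `gene_sizes()`: named numeric vector of unique-base counts per
#'   gene; `db_genes()`: character vector of gene symbols.
#' @export
gene_sizes <- function(db) {
  vapply(db$models, core_width, numeric(1))
}

#' @rdname gene_sizes
#' @export
db_genes <- function(db) names(db$models)

#' Union of all gene models in a database
#'
#' Pools every gene's regions into one canonical set of unique bases, so
#' shared exons between overlapping genes count once.
#'
#' @param db an `annotation_db`.
#' @return a canonical `GRanges`.
#' @export
db_union <- function(db) {
  ivl_to_gr(db_union_core(db))
}

db_union_core <- function(db) {
  if (length(db$models) == 0L)
    return(list(chrom = character(), start = integer(), end = integer()))
  merge_core(list(
    chrom = unlist(lapply(db$models, `[[`, "chrom"), use.names = FALSE),
    start = unlist(lapply(db$models, `[[`, "start"), use.names = FALSE),
    end = unlist(lapply(db$models, `[[`, "end"), use.names = FALSE)))
}

#' Force a subset database inside a superset database
#'
#' Replaces each subset gene's regions by their intersection with the same
#' gene's superset regions, so that subset coordinates are strictly nested
#' (the audit's precondition for representation fractions). Genes present
#' only in the subset are dropped with a warning.
#'
#' @param subset_db,superset_db `annotation_db` objects sharing gene
#'   symbols.
#' @return a nested copy of `subset_db`.
#' @export
enforce_nesting <- function(subset_db, superset_db) {
  genes <- db_genes(subset_db)
  missing <- setdiff(genes, db_genes(superset_db))
  if (length(missing))
    warning(sprintf("enforce_nesting: dropping %d gene(s) absent from '%s': %s",
                    length(missing), superset_db$name,
                    paste(missing, collapse = ", ")))
  keep <- setdiff(genes, missing)
  models <- lapply(stats::setNames(keep, keep), function(g)
    sweep_core(subset_db$models[[g]], superset_db$models[[g]], "intersect"))
  structure(list(name = subset_db$name, models = models),
            class = "annotation_db")
}

#' Per-gene representation of a superset database in a subset database
#'
#' For every superset gene, counts how many of its unique bases also occur
#' in the subset database (after [enforce_nesting()], applied internally),
#' and appends an `ALL` row whose fraction is computed on pooled unique
#' bases — the union over genes is taken *before* counting, so a base
#' shared by two gene models is counted once. This pooled rule makes the
#' headline fraction a true base-level containment, not a mean of per-gene
#' percentages.
#'
#' @param subset_db,superset_db `annotation_db` objects.
#' @return a `data.frame` with columns `gene`, `subset_bases`,
#'   `superset_bases`, `fraction`, ordered by gene symbol, with a final
#'   row `gene == "ALL"` carrying the pooled totals.
#' @export
representation_table <- function(subset_db, superset_db) {
  subset_db <- suppressWarnings(enforce_nesting(subset_db, superset_db))
  genes <- db_genes(superset_db)
  sup_sizes <- gene_sizes(superset_db)
  zero <- genes[sup_sizes == 0]
  if (length(zero)) {
    warning(sprintf("representation_table: excluding zero-base gene(s): %s",
                    paste(zero, collapse = ", ")))
    genes <- setdiff(genes, zero)
  }
  sub_bases <- vapply(genes, function(g) {
    m <- subset_db$models[[g]]
    if (is.null(m)) 0 else core_width(m)
  }, numeric(1))
  per_gene <- data.frame(
    gene = genes,
    subset_bases = sub_bases,
    superset_bases = sup_sizes[genes],
    fraction = sub_bases / sup_sizes[genes],
    row.names = NULL, stringsAsFactors = FALSE)
  sup_union <- db_union_core(superset_db)
  sub_union <- sweep_core(db_union_core(subset_db), sup_union, "intersect")
  pooled <- data.frame(
    gene = "ALL",
    subset_bases = core_width(sub_union),
    superset_bases = core_width(sup_union),
    fraction = core_width(sub_union) / core_width(sup_union),
    stringsAsFactors = FALSE)
  rbind(per_gene, pooled)
}

#' Write a representation table as TSV
#'
#' Columns `gene`, `subset_bases`, `superset_bases`, `percent` (2 decimal
#' places), with the pooled `ALL` row last.
#'
#' @param tab output of [representation_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_representation_tsv <- function(tab, path) {
  out <- data.table::data.table(
    gene = tab$gene,
    subset_bases = format_int(tab$subset_bases),
    superset_bases = format_int(tab$superset_bases),
    percent = sprintf("%.2f", 100 * tab$fraction))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

format_int <- function(x) format(x, scientific = FALSE, trim = TRUE)
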