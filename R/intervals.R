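#' Construct genomic intervals from 0-based half-open coordinates
#'
#' Builds a \link[GenomicRanges]{GRanges} from BED-style coordinates:
#' 0-based inclusive start, exclusive end. Empty or negative intervals are
#' rejected rather than stored. The returned object uses the usual 1-based
#' closed convention internally; all file I/O in this package converts back
#' at the boundary, so users thinking in BED coordinates never see the shift.
#'
#' @param chrom character vector of sequence names (compared verbatim;
#'   `"chr1"` and `"1"` are different sequences unless you normalize, see
#'   [normalize_chroms()]).
#' @param start integer vector, 0-based inclusive starts (>= 0).
#' @param end integer vector, exclusive ends (> start).
#' @param name optional character vector of labels (gene or transcript
#'   symbols), stored in the `name` metadata column.
#' @return a `GRanges`, unstranded, one range per input record.
#' @examples
#' gintervals("chr1", c(100, 150), c(200, 250))
#' @export
gintervals <- function(chrom, start, end, name = NULL) {
  n <- length(chrom)
  if (length(start) != n || length(end) != n)
    stop("chrom, start and end must have equal length")
  if (n == 0L)
    return(GenomicRanges::GRanges())
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad))
    stop(sprintf(
      "invalid interval at record %d: %s:%s-%s (need 0 <= start < end)",
      bad[1], chrom[bad[1]], format(start[bad[1]]), format(end[bad[1]])))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges   = IRanges::IRanges(start = as.integer(start) + 1L,
                                end   = as.integer(end)))
  if (!is.null(name))
    S4Vectors::mcols(gr)$name <- as.character(name)
  gr
}

# shared validity check: every range is a usable genomic interval
assert_valid_intervals <- function(gr, what = "interval") {
  if (!methods::is(gr, "GRanges"))
    stop(sprintf("expected a GRanges, got %s", class(gr)[1]))
  bad <- which(BiocGenerics::width(gr) < 1L | BiocGenerics::start(gr) < 1L)
  if (length(bad))
    stop(sprintf("invalid %s at record %d: %s:%d-%d (empty or negative)",
                 what, bad[1],
                 as.character(GenomeInfoDb::seqnames(gr))[bad[1]],
                 BiocGenerics::start(gr)[bad[1]] - 1L,
                 BiocGenerics::end(gr)[bad[1]]))
  invisible(gr)
}

# --- vectorized integer core -------------------------------------------------
# The algebra below runs on plain (chrom, start, end) tables in 0-based
# half-open coordinates. GRanges is the user-facing currency, but method
# dispatch on S4 containers costs milliseconds per call, which the
# audit's inner loops (and its property tests over thousands of random
# instances) cannot afford; the arithmetic here is exact integer
# sort/cumsum work and is cross-checked against both a per-base oracle
# and GenomicRanges in the test suite.

ivl_df <- function(gr) {
  list(chrom = as.character(GenomeInfoDb::seqnames(gr)),
       start = BiocGenerics::start(gr) - 1L,
       end   = BiocGenerics::end(gr))
}

ivl_to_gr <- function(x) {
  if (length(x$chrom) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = unique(x$chrom)),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end))
}

# collapse a raw table to canonical form: sorted by (chrom, start),
# overlapping or abutting runs fused
merge_core <- function(x) {
  n <- length(x$chrom)
  if (n == 0L) return(x)
  o <- order(x$chrom, x$start, x$end, method = "radix")
  ch <- x$chrom[o]; s <- x$start[o]; e <- x$end[o]
  new_chrom <- c(TRUE, ch[-1] != ch[-n])
  cm <- e                                    # running max end within chrom
  run_first <- which(new_chrom)
  run_last <- c(run_first[-1] - 1L, n)
  for (k in seq_along(run_first)) {
    idx <- run_first[k]:run_last[k]
    cm[idx] <- cummax(e[idx])
  }
  new_grp <- new_chrom | c(FALSE, s[-1] > cm[-n])
  first <- which(new_grp)
  last <- c(first[-1] - 1L, n)
  list(chrom = ch[first], start = s[first], end = cm[last])
}

# one sweep over the pooled breakpoints of two canonical tables; keeps
# the segments where the chosen predicate on (in a, in b) holds. Within
# each chromosome every opened interval closes again, so a single cumsum
# across chromosome boundaries stays exact.
sweep_core <- function(A, B, mode = c("intersect", "subtract")) {
  mode <- match.arg(mode)
  na <- length(A$chrom); nb <- length(B$chrom)
  ch <- c(A$chrom, A$chrom, B$chrom, B$chrom)
  pos <- c(A$start, A$end, B$start, B$end)
  da <- c(rep(1L, na), rep(-1L, na), integer(2L * nb))
  db <- c(integer(2L * na), rep(1L, nb), rep(-1L, nb))
  o <- order(ch, pos, method = "radix")
  ch <- ch[o]; pos <- pos[o]
  ca <- cumsum(da[o]); cb <- cumsum(db[o])
  n <- length(pos)
  if (n == 0L) return(list(chrom = character(), start = integer(),
                           end = integer()))
  is_last <- c(ch[-1] != ch[-n] | pos[-1] != pos[-n], TRUE)
  li <- which(is_last)
  pch <- ch[li]; ppos <- pos[li]; pca <- ca[li]; pcb <- cb[li]
  m <- length(li)
  if (m < 2L) return(list(chrom = character(), start = integer(),
                          end = integer()))
  same <- pch[-1] == pch[-m]
  keep <- if (mode == "intersect") pca[-m] > 0L & pcb[-m] > 0L
          else pca[-m] > 0L & pcb[-m] == 0L
  keep <- keep & same
  merge_core(list(chrom = pch[-m][keep], start = ppos[-m][keep],
                  end = ppos[-1][keep]))
}

#' Collapse intervals to unique locations
#'
#' Merges a raw interval collection into its canonical disjoint form: the
#' union of covered bases, with overlapping *and abutting* inputs collapsed
#' into single runs, sorted by (chrom, start). This is the "unique
#' locations" operation that every base-counting statistic in the audit is
#' built on, so that no base is ever counted twice.
#'
#' @param gr a `GRanges` of raw (possibly overlapping, unsorted) intervals.
#' @return a canonical `GRanges`: pairwise disjoint, non-abutting, sorted.
#'   Metadata columns are dropped (merged runs have no single label).
#' @seealso [total_bases()], [intersect_sets()], [subtract_sets()]
#' @export
merge_intervals <- function(gr) {
  assert_valid_intervals(gr)
  ivl_to_gr(merge_core(ivl_df(gr)))
}

#' Set algebra on canonical interval sets
#'
#' `intersect_sets()` returns the bases present in both sets,
#' `subtract_sets()` the bases of `a` not in `b`. Both accept canonical
#' sets (see [merge_intervals()]) and return canonical sets; together they
#' satisfy the partition identity
#' `total_bases(a) == total_bases(intersect_sets(a, b)) +
#' total_bases(subtract_sets(a, b))` exactly.
#'
#' @param a,b canonical `GRanges` interval sets.
#' @return a canonical `GRanges`.
#' @export
intersect_sets <- function(a, b) {
  assert_valid_intervals(a); assert_valid_intervals(b)
  ivl_to_gr(sweep_core(merge_core(ivl_df(a)), merge_core(ivl_df(b)),
                       "intersect"))
}

#' @rdname intersect_sets
#' @export
subtract_sets <- function(a, b) {
  assert_valid_intervals(a); assert_valid_intervals(b)
  ivl_to_gr(sweep_core(merge_core(ivl_df(a)), merge_core(ivl_df(b)),
                       "subtract"))
}

# merge_intervals on an empty GRanges with no seqlevels is fine, but the
# set operations are routinely handed empty operands; normalize here
allow_empty <- function(gr) {
  if (length(gr) == 0L) GenomicRanges::GRanges() else gr
}

#' Total number of bases in an interval set
#'
#' @param gr a canonical `GRanges` (see [merge_intervals()]); for a
#'   canonical set this equals the cardinality of the underlying per-base
#'   set.
#' @return a single non-negative number.
#' @export
total_bases <- function(gr) {
  if (length(gr) == 0L) return(0)
  assert_valid_intervals(gr)
  sum(as.double(BiocGenerics::width(gr)))
}

#' Fraction of a superset's bases contained in a subset
#'
#' The representation measure of the audit: what share of the reference
#' (superset) bases also appear in the candidate (subset) set. Computed on
#' unique bases, `total_bases(intersect) / total_bases(superset)`.
#'
#' @param subset,superset canonical `GRanges` interval sets; the superset
#'   must be non-empty.
#' @return a fraction in `[0, 1]`.
#' @export
contained_fraction <- function(subset, superset) {
  assert_valid_intervals(subset); assert_valid_intervals(superset)
  dsup <- merge_core(ivl_df(superset))
  denom <- sum(as.double(dsup$end - dsup$start))
  if (denom == 0)
    stop("contained_fraction: superset is empty (undefined denominator)")
  inter <- sweep_core(merge_core(ivl_df(subset)), dsup, "intersect")
  sum(as.double(inter$end - inter$start)) / denom
}

#' Normalize chromosome naming style
#'
#' Chromosome names are compared verbatim throughout the package
#' (`"chr1" != "1"`). When two inputs use different styles, normalize one
#' of them explicitly with this helper.
#'
#' @param gr a `GRanges`.
#' @param style `"strip"` removes a leading `"chr"`, `"add"` prepends it
#'   where missing, `"asis"` is the identity.
#' @return the `GRanges` with renamed seqlevels.
#' @export
normalize_chroms <- function(gr, style = c("asis", "strip", "add")) {
  style <- match.arg(style)
  if (style == "asis") return(gr)
  lv <- GenomeInfoDb::seqlevels(gr)
  new <- switch(style,
    strip = sub("^chr", "", lv),
    add   = ifelse(grepl("^chr", lv), lv, paste0("chr", lv)))
  if (anyDuplicated(new))
    stop("chromosome style normalization would collide two sequence names")
  GenomeInfoDb::seqlevels(gr) <- stats::setNames(new, lv)[lv]
  gr
}

#' Expand an interval set to its per-base positions
#'
#' Returns one row per covered base, 0-based, ordered by
#' (chrom, position) with chromosomes in name-sorted order. This ordering
#' is total and deterministic, and is the row order used by every per-base
#' depth structure in the package.
#'
#' @param gr a canonical `GRanges`.
#' @return a `data.table` with columns `chrom` (character) and `pos`
#'   (integer, 0-based).
#' @export
interval_positions <- function(gr) {
  positions_core(merge_core(ivl_df(allow_empty(gr))))
}

positions_core <- function(x) {
  if (length(x$chrom) == 0L)
    return(data.table::data.table(chrom = character(), pos = integer()))
  len <- x$end - x$start
  data.table::data.table(chrom = rep(x$chrom, len),
                         pos = sequence(len, from = x$start))
}
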