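#' Read a BED file of target or annotation intervals
#'
#' Parses 3- or 4-column tab-separated BED. Coordinates are taken verbatim
#' as 0-based half-open; an optional 4th column is kept as the record label
#' (gene or transcript symbol). `track`, `browser`, comment (`#`) and blank
#' lines are skipped. Columns beyond the 4th (score, strand, ...) are
#' ignored. Malformed records — non-integer coordinates, negative start, or
#' start >= end — raise an error naming the offending line.
#'
#' @param path path to a BED file.
#' @param chrom_style passed to [normalize_chroms()]; default leaves
#'   chromosome names untouched.
#' @return a `GRanges` with a `name` metadata column (`NA` for 3-column
#'   input). Records are returned in file order, *not* merged; pass the
#'   result through [merge_intervals()] or [build_db()] as appropriate.
#' @export
read_bed <- function(path, chrom_style = c("asis", "strip", "add")) {
  chrom_style <- match.arg(chrom_style)
  if (!file.exists(path)) stop(sprintf("BED file not found: %s", path))
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (length(lines) == 0L)
    return(gintervals(character(), integer(), integer(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("%s line %d: fewer than 3 tab-separated columns",
                 path, lineno[which(nf < 3L)[1]]))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end   <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("%s line %d: non-integer coordinates", path, lineno[bad[1]]))
  bad <- which(start < 0L | start >= end)
  if (length(bad))
    stop(sprintf("%s line %d: invalid range %d-%d (need 0 <= start < end)",
                 path, lineno[bad[1]], start[bad[1]], end[bad[1]]))
  name <- ifelse(nf >= 4L,
                 vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_, ""),
                 NA_character_)
  normalize_chroms(gintervals(chrom, start, end, name), chrom_style)
}

#' Write intervals to a BED file
#'
#' Emits tab-separated BED (0-based half-open). A 4th `name` column is
#' written when any record carries a non-`NA` label; otherwise 3 columns.
#' Round-trips with [read_bed()]: reading back reproduces the records.
#'
#' @param gr a `GRanges`, optionally with a `name` metadata column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  name <- S4Vectors::mcols(gr)$name
  dt <- data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end   = BiocGenerics::end(gr))
  if (!is.null(name) && any(!is.na(name))) dt$name <- name
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
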