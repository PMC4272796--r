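#' Read a per-sample per-base depth table
#'
#' Parses the 3-column text that `samtools depth` / `mpileup`-style tools
#' emit: chromosome, 1-based position, integer read depth, tab-separated,
#' no header. Positions are converted to the package's internal 0-based
#' convention here, at the parser boundary, and nowhere else. Depth files
#' are treated as ground truth: any upstream mapping- or base-quality
#' filtering changes the numbers and is out of this package's hands.
#'
#' @param path path to the depth TSV.
#' @return a `data.table` with columns `chrom` (character), `pos`
#'   (integer, 0-based) and `depth` (non-negative integer), in file order.
#' @export
read_depth_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("depth file not found: %s", path))
  if (file.size(path) == 0L)
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  depth = integer()))
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1:3),
                          showProgress = FALSE)
  if (nrow(dt) == 0L)
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  depth = integer()))
  if (ncol(dt) < 3L)
    stop(sprintf("%s: expected 3 tab-separated columns, found %d",
                 path, ncol(dt)))
  pos1 <- suppressWarnings(as.integer(dt[[2L]]))
  depth <- suppressWarnings(as.integer(dt[[3L]]))
  bad <- which(is.na(pos1) | pos1 < 1L)
  if (length(bad))
    stop(sprintf("%s line %d: position must be a positive integer (1-based)",
                 path, bad[1]))
  bad <- which(is.na(depth) | depth < 0L)
  if (length(bad))
    stop(sprintf("%s line %d: depth must be a non-negative integer",
                 path, bad[1]))
  data.table::data.table(chrom = dt[[1L]], pos = pos1 - 1L, depth = depth)
}

#' Assemble a per-base x per-sample depth matrix over target regions
#'
#' Rows are exactly the bases of `targets` in canonical (chrom, pos) order;
#' one column per sample. Target bases absent from a sample's depth file
#' are *zero-filled*: they are uncaptured, not missing data. This
#' convention is what makes "proportion of the target not captured"
#' computable from depth files alone — denominators are always the full
#' target. Records outside the target are ignored.
#'
#' @param per_sample_records list of depth `data.table`s (from
#'   [read_depth_table()]), one per sample.
#' @param targets canonical `GRanges` target region.
#' @param sample_ids character vector parallel to `per_sample_records`.
#' @return a `sample_depth_matrix`: list with `positions` (a `data.table`
#'   of `chrom`, `pos`), `samples`, and `depths` (integer matrix, one row
#'   per target base).
#' @export
build_depth_matrix <- function(per_sample_records, targets, sample_ids) {
  if (length(per_sample_records) < 1L)
    stop("build_depth_matrix: need at least one sample")
  if (length(sample_ids) != length(per_sample_records))
    stop("sample_ids must parallel per_sample_records")
  pos_dt <- interval_positions(targets)
  if (nrow(pos_dt) == 0L) stop("build_depth_matrix: empty target set")
  pos_dt[, row := .I]
  data.table::setkey(pos_dt, chrom, pos)
  depths <- matrix(0L, nrow = nrow(pos_dt), ncol = length(sample_ids),
                   dimnames = list(NULL, sample_ids))
  for (j in seq_along(per_sample_records)) {
    rec <- per_sample_records[[j]]
    idx <- pos_dt[rec, row, on = c("chrom", "pos")]
    inside <- !is.na(idx)
    if (anyDuplicated(idx[inside]))
      stop(sprintf("sample '%s': duplicate (chrom, pos) records in depth file",
                   sample_ids[j]))
    depths[idx[inside], j] <- rec$depth[inside]
  }
  pos_dt[, row := NULL]
  data.table::setkey(pos_dt, NULL)
  structure(list(positions = pos_dt[order(chrom, pos)],
                 samples = sample_ids, depths = depths),
            class = "sample_depth_matrix")
}

#' @export
print.sample_depth_matrix <- function(x, ...) {
  cat(sprintf("sample_depth_matrix: %d bases x %d samples\n",
              nrow(x$depths), ncol(x$depths)))
  invisible(x)
}

#' Average a depth matrix across samples into a mean-depth track
#'
#' Produces the per-coordinate cross-sample mean depth that all downstream
#' coverage statistics operate on (a base is "captured" at threshold d
#' when its *mean* depth is at least d).
#'
#' @param m a `sample_depth_matrix`.
#' @return a `data.table` with columns `chrom`, `pos` (0-based) and
#'   `mean_depth`, in canonical position order.
#' @export
mean_track <- function(m) {
  stopifnot(inherits(m, "sample_depth_matrix"))
  out <- data.table::copy(m$positions)
  out[, mean_depth := rowMeans(m$depths)]
  out[]
}

# zero-filled per-base mean depths of a track over a region, in canonical
# order; the workhorse behind coverage curves and gene summaries
region_depths <- function(track, region) {
  pos_dt <- interval_positions(region)
  if (nrow(pos_dt) == 0L) return(numeric(0))
  v <- track[pos_dt, mean_depth, on = c("chrom", "pos")]
  v[is.na(v)] <- 0
  v
}

#' Mean depth of a track over a region
#'
#' Arithmetic mean of the per-base mean depths across all bases of
#' `region`, zero-filling bases the track does not cover. This is the
#' per-kit "observed average read depth" statistic.
#'
#' @param track a mean-depth `data.table` from [mean_track()].
#' @param region a canonical, non-empty `GRanges`.
#' @return a non-negative number.
#' @export
overall_mean_depth <- function(track, region) {
  v <- region_depths(track, region)
  if (length(v) == 0L)
    stop("overall_mean_depth: empty region (undefined mean)")
  mean(v)
}

#' Read a sample manifest
#'
#' Tab-separated with header columns `sample_id`, `file`, `kit`; `file`
#' paths are resolved relative to the manifest's directory unless absolute.
#'
#' @param path manifest path.
#' @return a `data.table` with columns `sample_id`, `file` (absolute-ized),
#'   `kit`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", showProgress = FALSE)
  need <- c("sample_id", "file", "kit")
  if (!all(need %in% names(dt)))
    stop(sprintf("manifest %s: need columns %s", path,
                 paste(need, collapse = ", ")))
  if (anyDuplicated(dt$sample_id))
    stop(sprintf("manifest %s: duplicate sample_id", path))
  base <- dirname(normalizePath(path))
  dt[, file := ifelse(grepl("^(/|[A-Za-z]:)", file), file,
                      file.path(base, file))]
  dt[, .(sample_id, file, kit)]
}

#' Load the depth matrix for one capture kit from a manifest
#'
#' Convenience wrapper: reads every depth file of the given kit and builds
#' the per-base x per-sample matrix over `targets`.
#'
#' @param manifest a `data.table` from [read_manifest()].
#' @param kit_name kit label to select.
#' @param targets canonical `GRanges`.
#' @return a `sample_depth_matrix`.
#' @export
kit_depth_matrix <- function(manifest, kit_name, targets) {
  rows <- manifest[kit == kit_name]
  if (nrow(rows) == 0L)
    stop(sprintf("no samples for kit '%s' in manifest", kit_name))
  recs <- lapply(rows$file, read_depth_table)
  build_depth_matrix(recs, targets, rows$sample_id)
}
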