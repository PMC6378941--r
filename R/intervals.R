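#' Genomic interval tables
#'
#' Intervals are plain tibbles with columns `chrom`, `start`, `end`, using
#' 1-based fully-closed coordinates (the convention of the SAM spec and of
#' `GRanges`): a deletion printed as chr1:209945655-209947210 spans
#' `end - start + 1 = 1556` bp.  BED files, which are 0-based half-open,
#' are converted on read and write so a round-trip is lossless.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 1-based inclusive, `end >= start >= 1`.
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @examples
#' md_intervals("chr1", 209945655, 209947210) |> md_interval_size()
#' @export
md_intervals <- function(chrom, start, end) {
  x <- tibble::tibble(chrom = as.character(chrom),
                      start = as.integer(start),
                      end   = as.integer(end))
  validate_intervals(x)
  x
}

validate_intervals <- function(x) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (any(x$start < 1L)) stop("interval start must be >= 1 (1-based coordinates)")
  if (any(x$end < x$start)) stop("interval end must be >= start")
  invisible(x)
}

#' @rdname md_intervals
#' @param x An interval tibble.
#' @export
md_interval_size <- function(x) {
  validate_intervals(x)
  x$end - x$start + 1L
}

# interval tibble <-> GRanges (both are 1-based closed, so no shifting)
as_granges <- function(x) {
  validate_intervals(x)
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end))
}

granges_to_tbl <- function(gr) {
  tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr),
                 end   = GenomicRanges::end(gr))
}

#' Read and write BED interval files
#'
#' Thin wrappers around [rtracklayer::import.bed()]/[rtracklayer::export.bed()]
#' converting between the package's 1-based closed tibbles and BED's 0-based
#' half-open coordinates.
#'
#' @param path File path.
#' @return `md_read_bed()` returns an interval tibble (plus a `name` column
#'   when the BED file has one).
#' @export
md_read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- granges_to_tbl(gr)
  nm <- gr$name
  if (!is.null(nm)) out$name <- nm
  out
}

#' @rdname md_read_bed
#' @param x Interval tibble; an optional `name` column is carried through.
#' @export
md_write_bed <- function(x, path) {
  gr <- as_granges(x)
  if ("name" %in% names(x)) gr$name <- x$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a bedGraph track into an interval-value tibble
#'
#' @param path bedGraph file path.
#' @return Tibble with `chrom`, `start`, `end`, `value` (1-based closed).
#' @export
md_read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- granges_to_tbl(gr)
  out$value <- gr$score
  out
}
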