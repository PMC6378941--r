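#' Per-base coverage of a region
#'
#' Computes the per-base read depth of a read table over a region.  Depth at
#' a base is the number of retained reads whose aligned span covers it, so
#' the depth vector sums to the total aligned bases falling inside the
#' region.
#'
#' @param reads Read table (`chrom`, `start`, `end`), e.g. from
#'   [md_read_alignments()] or [md_simulate_trio_reads()].
#' @param region Single-row interval tibble.
#' @return Tibble with `chrom`, `pos`, `depth` (one row per base of the
#'   region; all-zero when no reads overlap).
#' @export
md_coverage <- function(reads, region) {
  validate_reads(reads)
  validate_intervals(region)
  stopifnot(nrow(region) == 1)
  r <- dplyr::filter(reads, .data$chrom == region$chrom,
                     .data$start <= region$end, .data$end >= region$start)
  width <- region$end - region$start + 1L
  depth <- integer(width)
  if (nrow(r) > 0) {
    ir <- IRanges::IRanges(pmax(r$start, region$start) - region$start + 1L,
                           pmin(r$end, region$end) - region$start + 1L)
    depth <- as.integer(IRanges::coverage(ir, width = width))
  }
  tibble::tibble(chrom = region$chrom,
                 pos = seq(region$start, region$end),
                 depth = depth)
}

# coverage as an Rle per chromosome over 1..max(end); used by binning
coverage_rle <- function(reads, chrom, width) {
  r <- reads[reads$chrom == chrom, , drop = FALSE]
  if (nrow(r) == 0) return(S4Vectors::Rle(0L, width))
  IRanges::coverage(IRanges::IRanges(r$start, pmin(r$end, width)),
                    width = width)
}

#' Count reads overlapping each bin
#'
#' For every bin, counts the retained reads whose aligned span overlaps the
#' bin by at least one base (so a read spanning a bin boundary contributes
#' to both bins); mates of a pair are counted independently.  An alternative
#' `"midpoint"` mode assigns each read to the single bin containing its
#' midpoint.
#'
#' @param reads Read table with a `sample_id` column, or a named list of
#'   per-sample read tables.
#' @param bins Bin tibble (`chrom`, `start`, `end`, optionally `bin_id`);
#'   bins must be sorted and non-overlapping within each chromosome.
#' @param mode `"overlap"` (default) or `"midpoint"`.
#' @return The bin tibble with one integer count column appended per sample.
#' @examples
#' bins <- md_intervals("c", c(1, 101), c(100, 200))
#' reads <- tibble::tibble(sample_id = "s1", chrom = "c",
#'                         start = c(95, 10), end = c(120, 60))
#' md_bin_counts(reads, bins)  # boundary-spanning read counts in both bins
#' @export
md_bin_counts <- function(reads, bins, mode = c("overlap", "midpoint")) {
  mode <- match.arg(mode)
  validate_bins(bins)
  reads_by_sample <- as_reads_list(reads)
  out <- bins
  for (sid in names(reads_by_sample)) {
    out[[sid]] <- count_one_sample(reads_by_sample[[sid]], bins, mode)
  }
  out
}

as_reads_list <- function(reads) {
  if (is.data.frame(reads)) {
    validate_reads(reads)
    if (!"sample_id" %in% names(reads)) {
      stop("read table must have a sample_id column (or pass a named list)")
    }
    split(reads, reads$sample_id)
  } else {
    stopifnot(is.list(reads), !is.null(names(reads)))
    lapply(reads, validate_reads)
    reads
  }
}

validate_bins <- function(bins) {
  validate_intervals(bins)
  by_chr <- split(bins, bins$chrom)
  for (b in by_chr) {
    if (is.unsorted(b$start)) stop("bins must be sorted by start within chromosome")
    if (nrow(b) > 1 && any(b$start[-1] <= b$end[-nrow(b)])) {
      stop("bins overlap; counting requires a non-overlapping partition")
    }
  }
  invisible(bins)
}

# A bin [s, e] is overlapped by reads with start <= e and end >= s; on
# sorted start/end vectors both counts are findInterval lookups.
count_one_sample <- function(reads, bins, mode = "overlap") {
  counts <- integer(nrow(bins))
  for (chr in unique(bins$chrom)) {
    idx <- which(bins$chrom == chr)
    r <- reads[reads$chrom == chr, , drop = FALSE]
    if (nrow(r) == 0) next
    if (mode == "overlap") {
      ss <- sort(r$start)
      se <- sort(r$end)
      n_start_le <- findInterval(bins$end[idx], ss)
      n_end_before <- findInterval(bins$start[idx] - 1L, se)
      counts[idx] <- n_start_le - n_end_before
    } else {
      mid <- sort((r$start + r$end) %/% 2L)
      counts[idx] <- findInterval(bins$end[idx], mid) -
        findInterval(bins$start[idx] - 1L, mid)
    }
  }
  counts
}

#' GC content of intervals
#'
#' Fraction (#G + #C) / (#non-N bases) of each interval.  Intervals of all
#' N get `NA` and subsequently fail bin QC.
#'
#' @param bins Interval tibble.
#' @param reference A FASTA path, [Rsamtools::FaFile], or named
#'   [Biostrings::DNAStringSet].
#' @return `bins` with a `gc` column appended.
#' @export
md_gc_content <- function(bins, reference) {
  validate_intervals(bins)
  seqs <- extract_sequences(bins, reference)
  freq <- Biostrings::letterFrequency(seqs, letters = c("G", "C", "A", "T"))
  non_n <- rowSums(freq)
  gc <- ifelse(non_n == 0, NA_real_, (freq[, "G"] + freq[, "C"]) / non_n)
  bins$gc <- as.numeric(gc)
  bins
}

extract_sequences <- function(bins, reference) {
  if (methods::is(reference, "DNAStringSet")) {
    missing_chrom <- setdiff(unique(bins$chrom), names(reference))
    if (length(missing_chrom) > 0) {
      stop("chromosome(s) absent from reference: ",
           paste(missing_chrom, collapse = ", "))
    }
    lens <- Biostrings::width(reference)[match(bins$chrom, names(reference))]
    if (any(bins$end > lens)) stop("interval extends past reference end")
    return(Biostrings::DNAStringSet(Map(
      function(chr, s, e) Biostrings::subseq(reference[[chr]], s, e),
      bins$chrom, bins$start, bins$end)))
  }
  fa <- if (methods::is(reference, "FaFile")) reference else {
    if (!file.exists(paste0(path_of(reference), ".fai"))) {
      Rsamtools::indexFa(reference)
    }
    Rsamtools::FaFile(reference)
  }
  idx <- Rsamtools::scanFaIndex(fa)
  missing_chrom <- setdiff(unique(bins$chrom),
                           as.character(GenomicRanges::seqnames(idx)))
  if (length(missing_chrom) > 0) {
    stop("chromosome(s) absent from reference: ",
         paste(missing_chrom, collapse = ", "))
  }
  Rsamtools::scanFa(fa, as_granges(bins))
}

path_of <- function(x) if (methods::is(x, "FaFile")) Rsamtools::path(x) else x

#' Mean mappability of intervals
#'
#' Length-weighted mean of an interval-value mappability track over each
#' bin; bases not covered by the track contribute 0.  With `track = NULL`
#' (no track available) a constant 1.0 is used so the pipeline runs without
#' an external download.
#'
#' @param bins Interval tibble.
#' @param track Tibble `chrom`, `start`, `end`, `value` (e.g. from
#'   [md_read_bedgraph()]), values in \[0, 1\]; or `NULL`.
#' @return `bins` with a `mappability` column appended.
#' @export
md_mappability <- function(bins, track = NULL) {
  validate_intervals(bins)
  if (is.null(track)) {
    bins$mappability <- 1.0
    return(bins)
  }
  validate_intervals(track)
  stopifnot(all(track$value >= 0 & track$value <= 1))
  bgr <- as_granges(track)
  hits <- GenomicRanges::findOverlaps(as_granges(bins), bgr)
  ov <- IRanges::pintersect(
    as_granges(bins)[S4Vectors::queryHits(hits)],
    bgr[S4Vectors::subjectHits(hits)])
  contrib <- GenomicRanges::width(ov) * track$value[S4Vectors::subjectHits(hits)]
  total <- rep(0, nrow(bins))
  agg <- tapply(contrib, S4Vectors::queryHits(hits), sum)
  total[as.integer(names(agg))] <- agg
  bins$mappability <- total / (bins$end - bins$start + 1)
  bins
}
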