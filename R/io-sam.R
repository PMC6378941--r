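#' Write a read table to an indexed BAM file
#'
#' Serializes simulated (or otherwise in-memory) reads as coordinate-sorted
#' SAM and converts to an indexed BAM via [Rsamtools::asBam()].  When the
#' pair columns produced by [md_simulate_trio_reads()] (`pair_id`, `mate`,
#' `mate_start`, `fragment`) are present, records are written as proper
#' pairs with template lengths, so read-pair evidence can be inspected on
#' the output; otherwise they are single-end.
#'
#' @param reads Read table for one sample.
#' @param path Output path ending in `.bam`.
#' @param chrom_lengths Named integer vector of chromosome lengths for the
#'   header (defaults to `max(end)` per chromosome).
#' @return The BAM path, invisibly.
#' @export
md_write_bam <- function(reads, path, chrom_lengths = NULL) {
  validate_reads(reads)
  stopifnot(grepl("\\.bam$", path))
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(reads$end, reads$chrom, max)
  }
  reads <- reads[order(match(reads$chrom, names(chrom_lengths)),
                       reads$start), , drop = FALSE]
  paired <- all(c("pair_id", "mate", "mate_start", "fragment") %in%
                  names(reads))
  width <- reads$end - reads$start + 1L
  if (paired) {
    # mate 1 = leftmost (forward), mate 2 = rightmost (reverse)
    flag <- ifelse(reads$mate == 1L,
                   1L + 2L + 32L + 64L,    # paired, proper, mate rev, first
                   1L + 2L + 16L + 128L)   # paired, proper, rev, second
    qname <- paste0("p", reads$pair_id)
    pnext <- reads$mate_start
    tlen <- ifelse(reads$mate == 1L, reads$fragment, -reads$fragment)
    rnext <- "="
  } else {
    flag <- 0L
    qname <- sprintf("read_%06d", seq_len(nrow(reads)))
    pnext <- 0L
    tlen <- 0L
    rnext <- "*"
  }
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                      as.integer(chrom_lengths)))
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t%s\t%d\t%d\t*\t*",
                  qname, flag, reads$chrom, reads$start, width,
                  rnext, pnext, tlen)
  sam <- sub("\\.bam$", ".sam", path)
  writeLines(c(header, body), sam)
  out <- Rsamtools::asBam(sam, sub("\\.bam$", "", path), overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  invisible(out)
}
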