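#' Read-filter configuration
#'
#' Filters applied when importing alignments for read-depth analysis:
#' secondary, supplementary and (optionally) duplicate-flagged records are
#' excluded and a MAPQ floor is applied.  These are the standard read-depth
#' conventions; all are configurable.
#'
#' @param min_mapq Minimum mapping quality retained (default 1, i.e. drop
#'   MAPQ 0 multi-mappers).
#' @param exclude_duplicates Drop records with the PCR/optical duplicate flag.
#' @param exclude_secondary Drop secondary and supplementary alignments.
#' @return A list of class `md_read_filters`.
#' @export
md_read_filters <- function(min_mapq = 1L, exclude_duplicates = TRUE,
                            exclude_secondary = TRUE) {
  structure(list(min_mapq = as.integer(min_mapq),
                 exclude_duplicates = exclude_duplicates,
                 exclude_secondary = exclude_secondary),
            class = "md_read_filters")
}

bam_index_path <- function(path) {
  for (cand in c(paste0(path, ".bai"), sub("\\.bam$", ".bai", path))) {
    if (file.exists(cand)) return(cand)
  }
  NULL
}

#' Import alignments from an indexed BAM file as a read table
#'
#' Returns one row per retained alignment record with its aligned reference
#' span (1-based closed).  Mates of a pair are independent rows.  The file
#' must be coordinate-sorted and indexed; a missing index is a hard error.
#'
#' @param path BAM file path (`.bai` index required).
#' @param region Optional single-row interval tibble restricting the import.
#' @param filters A [md_read_filters()] configuration.
#' @param sample_id Optional sample label stored in a `sample_id` column.
#' @return Tibble with columns `chrom`, `start`, `end`, `mapq`, `strand`
#'   (and `sample_id` if given).
#' @export
md_read_alignments <- function(path, region = NULL,
                               filters = md_read_filters(),
                               sample_id = NULL) {
  if (is.null(bam_index_path(path))) {
    stop("BAM file is not indexed: ", path,
         " (coordinate-sort and index it first)")
  }
  flag <- Rsamtools::scanBamFlag(
    isSecondaryAlignment = if (filters$exclude_secondary) FALSE else NA,
    isSupplementaryAlignment = if (filters$exclude_secondary) FALSE else NA,
    isDuplicate = if (filters$exclude_duplicates) FALSE else NA,
    isUnmappedQuery = FALSE
  )
  param_args <- list(flag = flag, mapqFilter = filters$min_mapq)
  if (!is.null(region)) {
    validate_intervals(region)
    hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets
    missing_chrom <- setdiff(unique(region$chrom), names(hdr))
    if (length(missing_chrom) > 0) {
      warning("chromosome(s) absent from BAM header: ",
              paste(missing_chrom, collapse = ", "))
      region <- dplyr::filter(region, !.data$chrom %in% missing_chrom)
      if (nrow(region) == 0) {
        return(empty_reads(sample_id))
      }
    }
    param_args$which <- as_granges(region)
  }
  param <- do.call(Rsamtools::ScanBamParam,
                   c(param_args, list(what = "mapq")))
  ga2 <- GenomicAlignments::readGAlignments(path, param = param,
                                            use.names = FALSE)
  out <- tibble::tibble(
    chrom  = as.character(GenomicAlignments::seqnames(ga2)),
    start  = GenomicAlignments::start(ga2),
    end    = GenomicAlignments::end(ga2),
    mapq   = S4Vectors::mcols(ga2)$mapq,
    strand = as.character(GenomicAlignments::strand(ga2))
  )
  if (!is.null(sample_id)) out$sample_id <- sample_id
  dplyr::distinct(out)  # overlapping query regions can duplicate records
}

empty_reads <- function(sample_id = NULL) {
  out <- tibble::tibble(chrom = character(), start = integer(),
                        end = integer(), mapq = integer(),
                        strand = character())
  if (!is.null(sample_id)) out$sample_id <- character()
  out
}

validate_reads <- function(reads) {
  stopifnot(all(c("chrom", "start", "end") %in% names(reads)))
  invisible(reads)
}
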