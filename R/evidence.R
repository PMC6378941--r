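#' Read-pair evidence for a candidate deletion
#'
#' A true deletion leaves a "Z-shaped" signature in a read-pair plot:
#' properly oriented pairs whose inferred fragment is far longer than the
#' sample's fragment-length distribution, flanking (spanning) the deleted
#' segment.  This inspector counts, per trio member, the pairs near a call
#' whose inferred fragment length exceeds `mean + k * sd` of the member's
#' own fragment distribution and whose fragment span contains the call.
#' Read depth made the call; this is lightweight corroborating evidence
#' only.
#'
#' @param bam_paths Named character vector of BAM paths (names are the
#'   member labels, e.g. offspring/father/mother).
#' @param call One-row tibble with `chrom`, `start`, `end` (e.g. a row of
#'   [md_call_de_novo()] output).
#' @param flank Bases added on each side of the call when fetching pairs
#'   (default 5000).
#' @param k Discordance threshold in fragment-SD units (default 5).
#' @param n_est Proper pairs used to estimate the fragment distribution
#'   (default 10000).
#' @return Tibble per member: `member`, `available`, `n_pairs`,
#'   `n_discordant`, `fragment_mean`, `fragment_sd`; the per-pair table
#'   (sorted by mate-1 start, ready for plotting) is attached as attribute
#'   `"pairs"`.
#' @export
md_read_pair_evidence <- function(bam_paths, call, flank = 5000L, k = 5,
                                  n_est = 10000L) {
  stopifnot(!is.null(names(bam_paths)))
  window <- md_intervals(call$chrom, max(1L, call$start - flank),
                         call$end + flank)
  pair_tables <- list()
  rows <- purrr::map_dfr(names(bam_paths), function(member) {
    path <- bam_paths[[member]]
    if (!file.exists(path) || is.null(bam_index_path(path))) {
      return(tibble::tibble(member = member, available = FALSE,
                            n_pairs = 0L, n_discordant = 0L,
                            fragment_mean = NA_real_, fragment_sd = NA_real_))
    }
    fr <- fragment_distribution(path, n_est)
    prm <- Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isPaired = TRUE, isUnmappedQuery = FALSE,
                                    hasUnmappedMate = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE,
                                    isDuplicate = FALSE),
      what = c("pos", "isize", "strand"),
      which = as_granges(window))
    b <- Rsamtools::scanBam(path, param = prm)[[1]]
    keep <- !is.na(b$isize) & b$isize > 0  # leftmost mate once per pair
    pairs <- tibble::tibble(
      member = member,
      start = b$pos[keep],
      end = b$pos[keep] + b$isize[keep] - 1L,
      fragment = b$isize[keep]) |>
      dplyr::arrange(.data$start)
    cut <- if (is.na(fr$sd) || fr$sd == 0) Inf else fr$mean + k * fr$sd
    pairs$discordant <- pairs$fragment > cut &
      pairs$start <= call$start & pairs$end >= call$end
    pair_tables[[member]] <<- pairs
    tibble::tibble(member = member, available = TRUE,
                   n_pairs = nrow(pairs),
                   n_discordant = sum(pairs$discordant),
                   fragment_mean = fr$mean, fragment_sd = fr$sd)
  })
  attr(rows, "pairs") <- dplyr::bind_rows(pair_tables)
  rows
}

# fragment-length mean/sd from the first n proper pairs in the file
fragment_distribution <- function(path, n = 10000L) {
  prm <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isProperPair = TRUE,
                                  isUnmappedQuery = FALSE),
    what = "isize")
  isize <- Rsamtools::scanBam(path, param = prm)[[1]]$isize
  isize <- isize[!is.na(isize) & isize > 0]
  isize <- head(isize, n)
  if (length(isize) < 2) return(list(mean = NA_real_, sd = NA_real_))
  list(mean = mean(isize), sd = stats::sd(isize))
}
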