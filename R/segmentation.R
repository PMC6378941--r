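#' Circular binary segmentation configuration
#'
#' @param alpha Minimum permutation significance to accept a change point
#'   (default 0.001).
#' @param min_width Minimum bins in any segment (default 3).
#' @param undo_sd Merge adjacent segments whose mean difference is below
#'   this many (robust) SDs (default 4).
#' @param n_permutations Permutations per tested split (default 10000; must
#'   be at least `1/alpha`).
#' @param seed RNG seed used for the permutations (default 137 so repeated
#'   runs are reproducible; `NULL` = use current RNG state).
#' @return A list of class `md_cbs_config`.
#' @export
md_cbs_config <- function(alpha = 0.001, min_width = 3L, undo_sd = 4,
                          n_permutations = 10000L, seed = 137L) {
  stopifnot(alpha > 0, alpha < 1, min_width >= 2, undo_sd >= 0,
            n_permutations >= 1 / alpha)
  structure(list(alpha = alpha, min_width = as.integer(min_width),
                 undo_sd = undo_sd,
                 n_permutations = as.integer(n_permutations), seed = seed),
            class = "md_cbs_config")
}

#' Maximal circular two-sample t statistic
#'
#' Scans all circular arc boundaries `0 <= b0 < b1 <= n` such that every
#' resulting piece has at least `min_width` observations, and returns the
#' pair maximizing the absolute t statistic comparing the arc mean to the
#' complement mean (scaled by the segment SD).  Ties resolve to the
#' leftmost `b0`, then smallest `b1`.  A zero-variance input has statistic
#' 0 and no candidate.
#'
#' @param x Numeric sequence (length at least `2 * min_width`).
#' @param min_width Minimum piece width.
#' @return List with `b0`, `b1` (0-based boundaries; the arc covers
#'   elements `(b0+1):b1`) and `t`.
#' @export
cbs_max_statistic <- function(x, min_width = 3L) {
  stopifnot(length(x) >= 2 * min_width)
  cbs_scan_cpp(as.numeric(x), as.integer(min_width))
}

#' Segment a sequence by circular binary segmentation
#'
#' Recursively splits the sequence at the maximal circular t statistic
#' whenever its permutation p-value (shuffles of the current segment) is at
#' most `alpha`, then prunes change points by SD-undo: adjacent segments
#' whose mean difference is less than `undo_sd` robust SDs are merged,
#' smallest ratio first.  The noise SD is estimated as
#' `mad(diff(x)) / sqrt(2)`, which is robust to the change points being
#' tested.
#'
#' @param x Numeric sequence.
#' @param config A [md_cbs_config()].
#' @return Tibble with `start`, `end` (1-based element indices, inclusive),
#'   `n_bins`, `mean` — segments tiling `seq_along(x)`.
#' @export
cbs_segment <- function(x, config = md_cbs_config()) {
  x <- as.numeric(x)
  run <- function() {
    bounds <- cbs_recurse(x, 1L, length(x), config)
    segs <- tibble::tibble(start = c(1L, head(bounds, -1) + 1L),
                           end = bounds)
    sd_undo(segs, x, config$undo_sd)
  }
  segs <- if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
  segs$n_bins <- segs$end - segs$start + 1L
  segs$mean <- vapply(seq_len(nrow(segs)),
                      function(i) mean(x[segs$start[i]:segs$end[i]]),
                      numeric(1))
  segs[, c("start", "end", "n_bins", "mean")]
}

# returns sorted right boundaries including the final one (hi - lo + 1 frame
# converted to absolute indices)
cbs_recurse <- function(x, lo, hi, config) {
  n <- hi - lo + 1L
  if (n < 2L * config$min_width) return(hi)
  res <- cbs_perm_cpp(x[lo:hi], config$min_width,
                      config$n_permutations, config$alpha)
  if (res$p > config$alpha || res$b0 < 0) return(hi)
  cuts <- c(res$b0, res$b1)
  cuts <- cuts[cuts > 0 & cuts < n]
  if (length(cuts) == 0) return(hi)
  pieces_hi <- lo - 1L + c(cuts, n)
  pieces_lo <- c(lo, head(pieces_hi, -1) + 1L)
  unlist(Map(function(l, h) cbs_recurse(x, l, h, config),
             pieces_lo, pieces_hi))
}

#' SD-undo pruning of change points
#'
#' Iteratively merges the adjacent segment pair with the smallest
#' mean-difference-to-SD ratio while that ratio is below `undo_sd`.
#'
#' @param segments Tibble with `start`, `end` tiling `x`.
#' @param x The segmented sequence.
#' @param undo_sd Threshold in SD units.
#' @param sd_est Noise SD; default `mad(diff(x)) / sqrt(2)`.
#' @return Pruned segment tibble with `start`, `end`, `mean`.
#' @export
sd_undo <- function(segments, x, undo_sd = 4, sd_est = NULL) {
  if (is.null(sd_est)) sd_est <- mad(diff(x)) / sqrt(2)
  if (!is.finite(sd_est) || sd_est <= 0) sd_est <- 1e-12
  segs <- segments[order(segments$start), c("start", "end")]
  segs$mean <- vapply(seq_len(nrow(segs)),
                      function(i) mean(x[segs$start[i]:segs$end[i]]),
                      numeric(1))
  while (nrow(segs) > 1) {
    ratio <- abs(diff(segs$mean)) / sd_est
    i <- which.min(ratio)
    if (ratio[i] >= undo_sd) break
    segs$end[i] <- segs$end[i + 1]
    segs$mean[i] <- mean(x[segs$start[i]:segs$end[i]])
    segs <- segs[-(i + 1), ]
  }
  segs
}

#' Segment the minimum-distance tracks of all trios
#'
#' Runs [cbs_segment()] on each trio's minimum distances, independently
#' within each targeted region (segments never cross region gaps).
#'
#' @param md_track Output of [md_minimum_distance()]; must carry
#'   `region_id`.
#' @param config A [md_cbs_config()].
#' @return Segment tibble: `family_id`, `region_id`, `chrom`, `start`,
#'   `end` (genomic coordinates spanning first to last bin), `n_bins`,
#'   `mean_d`, and a `bin_ids` list-column of member bins.
#' @export
md_segment <- function(md_track, config = md_cbs_config()) {
  if (!"region_id" %in% names(md_track)) {
    stop("minimum-distance track needs a region_id column ",
         "(build bins with targets or let proto-regions define regions)")
  }
  md_track |>
    dplyr::arrange(.data$family_id, .data$chrom, .data$start) |>
    dplyr::group_by(.data$family_id, .data$region_id) |>
    dplyr::group_modify(function(g, key) {
      segs <- cbs_segment(g$d, config)
      tibble::tibble(
        chrom = g$chrom[segs$start],
        start = g$start[segs$start],
        end = g$end[segs$end],
        n_bins = segs$n_bins,
        mean_d = segs$mean,
        bin_ids = lapply(seq_len(nrow(segs)),
                         function(i) g$bin_id[segs$start[i]:segs$end[i]]))
    }) |>
    dplyr::ungroup()
}
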