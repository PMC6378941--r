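#' Candidate-call configuration
#'
#' @param target_md Theoretical segment mean of a de novo heterozygous
#'   deletion on the M-score scale (-1).
#' @param md_tolerance Candidate window half-width around `target_md`
#'   (default 0.3, i.e. the closed interval \[-1.3, -0.7\]).
#' @param variability_sample_fraction A bin is flagged as highly variable
#'   when strictly more than this fraction of samples fall outside
#'   `variability_m_bounds` (default 0.05).
#' @param variability_m_bounds Closed M-score interval regarded as
#'   copy-neutral for the variability flag (default `c(-0.5, 0.5)`).
#' @param min_unflagged_fraction A candidate is reported only when strictly
#'   more than this fraction of its bins are unflagged (default 0.5).
#' @return A list of class `md_calling_config`.
#' @export
md_calling_config <- function(target_md = -1, md_tolerance = 0.3,
                              variability_sample_fraction = 0.05,
                              variability_m_bounds = c(-0.5, 0.5),
                              min_unflagged_fraction = 0.5) {
  stopifnot(md_tolerance > 0, variability_sample_fraction > 0,
            variability_sample_fraction < 1)
  structure(list(target_md = target_md, md_tolerance = md_tolerance,
                 variability_sample_fraction = variability_sample_fraction,
                 variability_m_bounds = variability_m_bounds,
                 min_unflagged_fraction = min_unflagged_fraction),
            class = "md_calling_config")
}

#' Flag bins of high population variability
#'
#' Copy-number polymorphisms and normalization failures make many samples'
#' M scores deviate from 0 at the same bins; de novo calls over such bins
#' are untrustworthy.  A bin is flagged when strictly more than
#' `variability_sample_fraction` of samples have M scores outside the
#' closed interval `variability_m_bounds`.
#'
#' @param mscores M-score table.
#' @param config A [md_calling_config()].
#' @return Tibble `bin_id`, `n_outside`, `variability_flag`.
#' @export
md_flag_variable_bins <- function(mscores, config = md_calling_config()) {
  cols <- md_sample_cols(mscores)
  if (length(cols) < 20) {
    warning("fewer than 20 samples; the ", config$variability_sample_fraction,
            " variability fraction is a poor estimate")
  }
  m <- as.matrix(mscores[, cols])
  lo <- config$variability_m_bounds[1]
  hi <- config$variability_m_bounds[2]
  n_outside <- rowSums(m < lo | m > hi)
  tibble::tibble(
    bin_id = mscores$bin_id,
    n_outside = as.integer(n_outside),
    variability_flag =
      n_outside / length(cols) > config$variability_sample_fraction)
}

#' Call candidate de novo deletions from segments
#'
#' A segment becomes a candidate when its mean minimum distance lies within
#' `md_tolerance` of the theoretical single-copy-deletion value -1 (closed
#' interval).  A candidate is `reported` when strictly more than half of
#' its bins are free of the variability flag, and `suppressed` otherwise
#' (suppressed candidates are kept in the output for auditability).
#'
#' @param segments Output of [md_segment()].
#' @param flags Output of [md_flag_variable_bins()].
#' @param config A [md_calling_config()].
#' @return Call tibble: `family_id`, `chrom`, `start`, `end`, `size`,
#'   `n_bins`, `mean_md`, `n_flagged`, `status` plus the `bin_ids`
#'   list-column.
#' @export
md_call_de_novo <- function(segments, flags, config = md_calling_config()) {
  lo <- config$target_md - config$md_tolerance
  hi <- config$target_md + config$md_tolerance
  cand <- dplyr::filter(segments, .data$mean_d >= lo, .data$mean_d <= hi)
  if (nrow(cand) == 0) {
    return(tibble::tibble(family_id = character(), region_id = character(),
                          chrom = character(), start = integer(),
                          end = integer(), size = integer(),
                          n_bins = integer(), mean_md = numeric(),
                          n_flagged = integer(), status = character(),
                          bin_ids = list()))
  }
  flag_of <- setNames(flags$variability_flag, flags$bin_id)
  cand$n_flagged <- vapply(cand$bin_ids, function(ids) {
    sum(flag_of[ids], na.rm = TRUE)
  }, integer(1))
  cand$size <- cand$end - cand$start + 1L
  unflagged_frac <- (cand$n_bins - cand$n_flagged) / cand$n_bins
  cand$status <- ifelse(unflagged_frac > config$min_unflagged_fraction,
                        "reported", "suppressed")
  cand$mean_md <- cand$mean_d
  dplyr::select(cand, "family_id", "region_id", "chrom", "start", "end",
                "size", "n_bins", "mean_md", "n_flagged", "status",
                "bin_ids")
}
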