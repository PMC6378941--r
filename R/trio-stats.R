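#' Read a pedigree table
#'
#' Tab-separated file with header columns `family_id`, `offspring_id`,
#' `father_id`, `mother_id` (one trio per row).
#'
#' @param path TSV path.
#' @return Pedigree tibble.
#' @export
md_read_pedigree <- function(path) {
  ped <- tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                             colClasses = "character"))
  validate_pedigree(ped)
  ped
}

validate_pedigree <- function(ped) {
  need <- c("family_id", "offspring_id", "father_id", "mother_id")
  if (!all(need %in% names(ped))) {
    stop("pedigree needs columns: ", paste(need, collapse = ", "))
  }
  bad <- ped$offspring_id == ped$father_id |
    ped$offspring_id == ped$mother_id | ped$father_id == ped$mother_id
  if (any(bad)) stop("trio members must be three distinct samples")
  invisible(ped)
}

#' Minimum distance of a trio at one bin
#'
#' With offspring/father/mother M scores \eqn{M_O, M_F, M_M}, forms
#' \eqn{\delta_F = M_O - M_F} and \eqn{\delta_M = M_O - M_M} and returns the
#' one of smaller absolute value (the father term on exact ties).  Inherited
#' copy-number events — where the offspring matches one parent — therefore
#' cancel to about 0, while a de novo heterozygous deletion gives about -1.
#'
#' @param m_offspring,m_father,m_mother Numeric vectors of M scores.
#' @return The per-bin minimum distance `d`.
#' @examples
#' md_minimum_distance_stat(-1, -1, 0)  # inherited from father -> 0
#' md_minimum_distance_stat(-1, 0, 0)   # de novo -> -1
#' @export
md_minimum_distance_stat <- function(m_offspring, m_father, m_mother) {
  delta_f <- m_offspring - m_father
  delta_m <- m_offspring - m_mother
  ifelse(abs(delta_f) <= abs(delta_m), delta_f, delta_m)
}

#' Per-trio minimum-distance tracks
#'
#' Computes `delta_f`, `delta_m` and the minimum distance `d` at every bin
#' for every trio in the pedigree.  Bins where any family member has a
#' non-finite M score are masked (dropped from that trio's track).
#'
#' @param mscores M-score table from [md_m_scores()].
#' @param pedigree Pedigree tibble (`family_id`, `offspring_id`,
#'   `father_id`, `mother_id`); all member IDs must be sample columns of
#'   `mscores`.
#' @return Tibble with one row per family x bin: bin metadata plus
#'   `family_id`, `delta_f`, `delta_m`, `d`, in genomic order within family.
#' @export
md_minimum_distance <- function(mscores, pedigree) {
  validate_pedigree(pedigree)
  samples <- md_sample_cols(mscores)
  missing_samples <- setdiff(unlist(pedigree[, c("offspring_id", "father_id",
                                                 "mother_id")]), samples)
  if (length(missing_samples) > 0) {
    stop("pedigree samples absent from M-score table: ",
         paste(missing_samples, collapse = ", "))
  }
  meta <- intersect(c("bin_id", "region_id", "chrom", "start", "end"),
                    names(mscores))
  purrr::map_dfr(seq_len(nrow(pedigree)), function(i) {
    tr <- pedigree[i, ]
    mo <- mscores[[tr$offspring_id]]
    mf <- mscores[[tr$father_id]]
    mm <- mscores[[tr$mother_id]]
    out <- mscores[, meta]
    out$family_id <- tr$family_id
    out$delta_f <- mo - mf
    out$delta_m <- mo - mm
    out$d <- md_minimum_distance_stat(mo, mf, mm)
    # mask bins where any member is non-finite
    out[is.finite(mo) & is.finite(mf) & is.finite(mm), ]
  })
}

# biased sample autocorrelation at a given lag; 0 for constant series
acf_at_lag <- function(x, lag = 10L) {
  n <- length(x)
  if (n <= lag) return(NA_real_)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) return(0)
  sum(xc[1:(n - lag)] * xc[(lag + 1):n]) / denom
}

#' Family-level quality control on the minimum-distance track
#'
#' Families whose minimum distances are too noisy or too strongly
#' autocorrelated produce unreliable segmentations and are excluded: a
#' family fails when the lag-10 autocorrelation of `d` exceeds 0.4 and/or
#' the variance of `d` exceeds 0.05.  Statistics are computed over the full
#' track in genomic order (regions concatenated).  Tracks with fewer than
#' 11 bins cannot support the lag-10 estimate and fail with an explicit
#' reason.
#'
#' @param md_track Output of [md_minimum_distance()].
#' @param max_lag10_acf,max_variance Exclusion thresholds (defaults 0.4 and
#'   0.05).
#' @return Tibble per family: `family_id`, `n_bins`,
#'   `lag10_autocorrelation`, `variance`, `pass`, `reason`.
#' @export
md_family_qc <- function(md_track, max_lag10_acf = 0.4,
                         max_variance = 0.05) {
  md_track |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(
      n_bins = dplyr::n(),
      lag10_autocorrelation = acf_at_lag(.data$d, 10L),
      variance = if (dplyr::n() > 1) var(.data$d) else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(
      pass = !is.na(.data$lag10_autocorrelation) &
        !is.na(.data$variance) &
        .data$lag10_autocorrelation <= max_lag10_acf &
        .data$variance <= max_variance,
      reason = dplyr::case_when(
        is.na(.data$lag10_autocorrelation) ~ "too_few_bins",
        .data$lag10_autocorrelation > max_lag10_acf &
          .data$variance > max_variance ~ "autocorrelation+variance",
        .data$lag10_autocorrelation > max_lag10_acf ~ "autocorrelation",
        .data$variance > max_variance ~ "variance",
        TRUE ~ NA_character_))
}
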