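#' log2(count + 1) transformation
#'
#' @param counts Count table from [md_bin_counts()] (bin metadata plus one
#'   column per sample).  Negative counts are an error.
#' @return Same shape with sample columns replaced by `log2(count + 1)`.
#' @export
md_log2_counts <- function(counts) {
  cols <- md_sample_cols(counts)
  for (s in cols) {
    if (any(counts[[s]] < 0)) stop("negative count in sample ", s)
    counts[[s]] <- log2(counts[[s]] + 1)
  }
  counts
}

#' Median centering by sample then by bin
#'
#' Subtracts each sample column's median, then each bin row's median — one
#' pass each, in that order (not an iterated median polish).
#'
#' @param x Table of log-scale scores (bin metadata + sample columns).
#' @return Centered table.
#' @export
md_median_center <- function(x) {
  cols <- md_sample_cols(x)
  m <- as.matrix(x[, cols])
  m <- sweep(m, 2, apply(m, 2, median), "-")
  m <- sweep(m, 1, apply(m, 1, median), "-")
  x[, cols] <- m
  x
}

#' Loess adjustment for GC content and mappability
#'
#' For each sample, fits a loess of the centered score against bin GC and
#' subtracts the fit, then does the same against bin mappability.  A
#' covariate with (near-)constant values across bins carries no trend and
#' is skipped; with fewer than 10 bins the whole adjustment is skipped with
#' a warning (the fit is unstable).
#'
#' @param x Centered score table; bins must carry `gc` and `mappability`.
#' @param span Loess span (default 0.75).
#' @return Adjusted table (the M scores).
#' @export
md_adjust_covariates <- function(x, span = 0.75) {
  stopifnot(all(c("gc", "mappability") %in% names(x)))
  cols <- md_sample_cols(x)
  if (nrow(x) < 10) {
    warning("fewer than 10 bins; covariate adjustment skipped")
    return(x)
  }
  for (covar in c("gc", "mappability")) {
    v <- x[[covar]]
    if (length(unique(round(v, 10))) < 4 || stats::sd(v) < 1e-8) next
    for (s in cols) {
      fit <- lowess_safe(x[[s]], v, span)
      if (!is.null(fit)) x[[s]] <- x[[s]] - fit
    }
  }
  x
}

# loess fit returning fitted values, NULL if the fit fails
lowess_safe <- function(y, v, span) {
  tryCatch({
    fit <- loess(y ~ v, span = span, degree = 2, family = "gaussian")
    fitted(fit)
  }, error = function(e) NULL)
}

#' Normalize raw counts to M scores
#'
#' Runs the normalization chain: `log2(count + 1)`, centering by sample
#' then bin medians, and loess adjustment for GC and mappability.  The
#' resulting M score is a relative copy-number measure with expectation
#' about 0 for copy-neutral bins and about -1 for a single-copy (i.e.
#' heterozygous) deletion.
#'
#' QC-failing bins (`qc_pass == FALSE`) are dropped before normalization so
#' they cannot distort the medians.
#'
#' @param counts Count table from [md_bin_counts()]; bin metadata must
#'   include `gc` and `mappability` (and `qc_pass` if QC was run).
#' @param span Loess span (default 0.75).
#' @return M-score table (same shape as `counts`, QC-passing bins only).
#' @export
md_m_scores <- function(counts, span = 0.75) {
  if ("qc_pass" %in% names(counts)) {
    counts <- dplyr::filter(counts, .data$qc_pass)
  }
  counts |>
    md_log2_counts() |>
    md_median_center() |>
    md_adjust_covariates(span = span)
}
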