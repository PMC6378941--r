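#' Score calls against a spiked truth set
#'
#' A truth deletion counts as called when the fraction of its length
#' covered by the union of reported calls in the same family reaches the
#' overlap threshold (`threshold = 0` means any overlap).  Each reported
#' call is classified as matching a de novo truth, matching an inherited
#' truth (an inherited event mistaken for de novo), or an additional false
#' positive, by the same fraction-of-truth-covered rule.
#'
#' @param calls Call tibble from [md_call_de_novo()]; only rows with
#'   `status == "reported"` are scored.
#' @param truth Truth tibble from [md_spike_plan()].
#' @param threshold Overlap fraction in \{0, 0.25, 0.5\} (or any value in
#'   \[0, 1\]).
#' @return List with `detection` (truth rows plus `covered_frac`,
#'   `detected`), `summary` (per kind x size detection rates) and
#'   `false_positives` (unmatched reported calls with their widths).
#' @export
md_score_calls <- function(calls, truth, threshold = 0.25) {
  reported <- dplyr::filter(calls, .data$status == "reported")
  truth$covered_frac <- vapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    cc <- dplyr::filter(reported, .data$family_id == tr$family_id,
                        .data$chrom == tr$chrom)
    covered_fraction(tr$start, tr$end, cc$start, cc$end)
  }, numeric(1))
  truth$detected <- if (threshold == 0) truth$covered_frac > 0 else
    truth$covered_frac >= threshold
  summary <- truth |>
    dplyr::group_by(.data$kind, .data$size) |>
    dplyr::summarise(n = dplyr::n(), n_called = sum(.data$detected),
                     rate = mean(.data$detected), .groups = "drop")

  match_kind <- rep("additional_fp", nrow(reported))
  if (nrow(reported) > 0) {
    for (i in seq_len(nrow(reported))) {
      cl <- reported[i, ]
      tt <- dplyr::filter(truth, .data$family_id == cl$family_id,
                          .data$chrom == cl$chrom)
      if (nrow(tt) == 0) next
      frac <- vapply(seq_len(nrow(tt)), function(j) {
        covered_fraction(tt$start[j], tt$end[j], cl$start, cl$end)
      }, numeric(1))
      hit <- if (threshold == 0) frac > 0 else frac >= threshold
      if (any(hit & tt$kind == "de_novo")) match_kind[i] <- "de_novo"
      else if (any(hit & tt$kind == "inherited")) match_kind[i] <- "inherited"
    }
  }
  fp <- reported
  fp$match <- match_kind
  fp <- dplyr::filter(fp, .data$match != "de_novo")
  fp$width <- fp$end - fp$start + 1L
  list(detection = truth, summary = summary,
       false_positives = dplyr::select(fp, "family_id", "chrom", "start",
                                       "end", "width", "mean_md", "match"))
}

# fraction of [ts, te] covered by the union of [cs, ce] intervals
covered_fraction <- function(ts, te, cs, ce) {
  if (length(cs) == 0) return(0)
  ov <- IRanges::intersect(IRanges::IRanges(ts, te),
                           IRanges::reduce(IRanges::IRanges(cs, ce)))
  sum(IRanges::width(ov)) / (te - ts + 1)
}

#' Run the spike-in benchmark
#'
#' Simulates replicate cohorts of trios, spikes de novo (proband-only) and
#' inherited (proband plus one parent) deletions by dropping overlapping
#' reads with probability 0.5, runs the full pipeline (binning,
#' normalization, minimum distance, family QC, segmentation, calling) on
#' each replicate, and scores reported calls against the spiked truth at
#' each overlap threshold.
#'
#' @param n_trios Trios per replicate (default 50).
#' @param n_replicates Number of replicate cohorts (default 5).
#' @param sizes Spike sizes in bp.
#' @param seed Master seed; all per-replicate seeds derive from it.
#' @param profile A [md_capture_profile()].
#' @param layout Spike layout, see [md_spike_plan()].
#' @param overlap_thresholds Overlap fractions to score at.
#' @param drop_probability Read-drop probability (default 0.5).
#' @param binning,cbs,calling Stage configurations.
#' @param span Loess span for normalization.
#' @return An object of class `md_benchmark`: `detection` (all truth rows
#'   with per-threshold detection), `summary` (rates with binomial 95%
#'   confidence intervals), `false_positives`, `calls`, and the run
#'   parameters.  See [tidy.md_benchmark()], [autoplot.md_benchmark()].
#' @export
md_run_benchmark <- function(n_trios = 50L, n_replicates = 5L,
                             sizes = c(250L, 500L, 1000L, 2000L, 4000L),
                             seed = 137L,
                             profile = md_capture_profile(),
                             layout = c("rotating", "full"),
                             overlap_thresholds = c(0, 0.25, 0.5),
                             drop_probability = 0.5,
                             binning = md_binning_config(),
                             cbs = md_cbs_config(),
                             calling = md_calling_config(),
                             span = 0.75) {
  layout <- match.arg(layout)
  reference <- md_simulate_reference(profile, seed = seed %% 2147483647L)
  detections <- list(); fps <- list(); all_calls <- list()
  for (r in seq_len(n_replicates)) {
    rep_seed <- (seed + 104729L * r) %% 2147483647L
    cohort <- md_simulate_cohort(profile, n_trios, seed = rep_seed)
    truth <- md_spike_plan(profile, cohort$pedigree, sizes, layout,
                           seed = rep_seed + 1L)
    reads <- md_apply_spikes(cohort$reads, truth, cohort$pedigree,
                             drop_probability, seed = rep_seed + 2L)
    cohort$reads <- NULL  # free the unspiked copy before the pipeline
    bconf <- binning
    bconf$seed <- rep_seed + 3L
    res <- md_run_pipeline(reads, cohort$pedigree,
                           targets = profile$regions,
                           reference = reference,
                           binning = bconf, cbs = cbs, calling = calling,
                           span = span)
    all_calls[[r]] <- dplyr::mutate(res$calls, replicate = r)
    qc_pass <- stats::setNames(res$family_qc$pass, res$family_qc$family_id)
    for (th in overlap_thresholds) {
      sc <- md_score_calls(res$calls, truth, th)
      detections[[length(detections) + 1L]] <-
        dplyr::mutate(sc$detection, replicate = r, threshold = th,
                      family_passed_qc = unname(qc_pass[.data$family_id]))
      fps[[length(fps) + 1L]] <-
        dplyr::mutate(sc$false_positives, replicate = r, threshold = th)
    }
    rm(reads, res)
    gc(FALSE)
  }
  detection <- dplyr::bind_rows(detections)
  summary <- detection |>
    dplyr::group_by(.data$threshold, .data$kind, .data$size) |>
    dplyr::summarise(n = dplyr::n(), n_called = sum(.data$detected),
                     rate = mean(.data$detected), .groups = "drop")
  ci <- t(vapply(seq_len(nrow(summary)), function(i) {
    as.numeric(binom.test(summary$n_called[i], summary$n[i])$conf.int)
  }, numeric(2)))
  summary$ci_lo <- ci[, 1]
  summary$ci_hi <- ci[, 2]
  structure(list(detection = detection, summary = summary,
                 false_positives = dplyr::bind_rows(fps),
                 calls = dplyr::bind_rows(all_calls),
                 params = list(n_trios = n_trios,
                               n_replicates = n_replicates, sizes = sizes,
                               seed = seed, layout = layout,
                               drop_probability = drop_probability,
                               overlap_thresholds = overlap_thresholds)),
            class = "md_benchmark")
}

#' @export
print.md_benchmark <- function(x, ...) {
  cat("Spike-in benchmark:", x$params$n_trios, "trios x",
      x$params$n_replicates, "replicates, drop probability",
      x$params$drop_probability, "\n\n")
  print(x$summary, n = Inf)
  invisible(x)
}

#' Tidy a benchmark result
#'
#' @param x An `md_benchmark` object.
#' @param ... Unused.
#' @return The per-threshold, per-kind, per-size detection-rate tibble with
#'   binomial 95% confidence intervals.
#' @method tidy md_benchmark
#' @export
tidy.md_benchmark <- function(x, ...) x$summary

#' One-row benchmark summary
#'
#' @param x An `md_benchmark` object.
#' @param threshold Overlap threshold to summarise at (default 0.25).
#' @param ... Unused.
#' @return Tibble with overall de novo sensitivity, the rate at which
#'   inherited spikes were called de novo, and the count of additional
#'   false positives, at the chosen threshold.
#' @method glance md_benchmark
#' @export
glance.md_benchmark <- function(x, threshold = 0.25, ...) {
  det <- dplyr::filter(x$detection, .data$threshold == !!threshold)
  fp <- dplyr::filter(x$false_positives, .data$threshold == !!threshold,
                      .data$match == "additional_fp")
  tibble::tibble(
    threshold = threshold,
    sensitivity_de_novo = mean(det$detected[det$kind == "de_novo"]),
    inherited_called_de_novo = mean(det$detected[det$kind == "inherited"]),
    n_additional_fp = nrow(fp))
}

#' Plot benchmark detection rates
#'
#' Detection rate against spike size (log scale), faceted by spike kind,
#' with exact binomial 95% confidence intervals — de novo rates are the
#' sensitivity, inherited rates are the inherited-called-de-novo error.
#'
#' @param object An `md_benchmark` object.
#' @param threshold Overlap threshold to plot (default 0.25).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot md_benchmark
#' @export
autoplot.md_benchmark <- function(object, threshold = 0.25, ...) {
  dat <- dplyr::filter(object$summary, .data$threshold == !!threshold)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$size, y = .data$rate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10(breaks = unique(dat$size)) +
    ggplot2::facet_wrap(~kind) +
    ggplot2::labs(x = "spiked deletion size (bp)", y = "fraction called",
                  title = sprintf("Spike-in detection at %.0f%% overlap",
                                  100 * threshold)) +
    ggplot2::theme_bw()
}
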