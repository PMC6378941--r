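#' Run the full de novo deletion pipeline
#'
#' Executes the stages in order: build coverage-adaptive bins, count reads
#' per bin for every sample, normalize to M scores, compute per-trio
#' minimum distances, exclude families failing minimum-distance QC,
#' segment each trio's track per region by circular binary segmentation,
#' and call candidate de novo deletions with variability-flag suppression.
#' Deterministic under the stage seeds.
#'
#' @param reads Named list of per-sample read tables, a read table with a
#'   `sample_id` column, or a named character vector of indexed BAM paths.
#' @param pedigree Pedigree tibble (`family_id`, `offspring_id`,
#'   `father_id`, `mother_id`).
#' @param targets Optional target-region interval tibble (segmentation is
#'   confined within regions).
#' @param reference Reference sequence for GC annotation (optional).
#' @param mappability Mappability track (optional; constant 1 if absent).
#' @param sample_info Optional tibble (`sample_id`, `batch`, `qc_fail`)
#'   for [md_batch_qc_filter()].
#' @param binning,cbs,calling Stage configurations.
#' @param span Loess span for normalization.
#' @param filters Read filters, used when `reads` are BAM paths.
#' @param outdir Optional directory; when given, stage outputs are written
#'   as TSV/BED next to a `manifest.tsv`.
#' @return An object of class `md_pipeline`: list with `bins`, `counts`,
#'   `mscores`, `flags`, `family_qc`, `md_track`, `segments`, `calls`,
#'   `manifest`.
#' @export
md_run_pipeline <- function(reads, pedigree, targets = NULL,
                            reference = NULL, mappability = NULL,
                            sample_info = NULL,
                            binning = md_binning_config(),
                            cbs = md_cbs_config(),
                            calling = md_calling_config(),
                            span = 0.75,
                            filters = md_read_filters(),
                            outdir = NULL) {
  if (is.character(reads)) {
    stopifnot(!is.null(names(reads)))
    reads <- lapply(stats::setNames(names(reads), names(reads)), function(s) {
      md_read_alignments(reads[[s]], filters = filters, sample_id = s)
    })
  }
  reads <- as_reads_list(reads)
  validate_pedigree(pedigree)

  families_in <- nrow(pedigree)
  batch <- md_batch_qc_filter(pedigree, sample_info)
  pedigree <- batch$pedigree

  if (nrow(pedigree) == 0) {
    manifest <- pipeline_manifest(families_in, batch$n_excluded, 0, 0,
                                  0, 0, 0, 0, 0)
    return(structure(list(bins = NULL, counts = NULL, mscores = NULL,
                          flags = NULL, family_qc = NULL, md_track = NULL,
                          segments = NULL, calls = empty_calls(),
                          manifest = manifest), class = "md_pipeline"))
  }

  bins <- md_build_bins(reads, binning, reference = reference,
                        mappability = mappability, targets = targets)
  counts <- md_bin_counts(reads, bins)
  mscores <- md_m_scores(counts, span = span)
  flags <- md_flag_variable_bins(mscores, calling)
  md_track <- md_minimum_distance(mscores, pedigree)
  fam_qc <- md_family_qc(md_track)
  keep <- fam_qc$family_id[fam_qc$pass]
  md_track_kept <- dplyr::filter(md_track, .data$family_id %in% keep)
  segments <- md_segment(md_track_kept, cbs)
  calls <- md_call_de_novo(segments, flags, calling)

  manifest <- pipeline_manifest(
    families_in, batch$n_excluded, sum(!fam_qc$pass), length(keep),
    nrow(bins), sum(bins$qc_pass), nrow(segments),
    nrow(calls), sum(calls$status == "reported"))

  out <- structure(list(bins = bins, counts = counts, mscores = mscores,
                        flags = flags, family_qc = fam_qc,
                        md_track = md_track, segments = segments,
                        calls = calls, manifest = manifest),
                   class = "md_pipeline")
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

empty_calls <- function() {
  tibble::tibble(family_id = character(), region_id = character(),
                 chrom = character(), start = integer(), end = integer(),
                 size = integer(), n_bins = integer(), mean_md = numeric(),
                 n_flagged = integer(), status = character(),
                 bin_ids = list())
}

pipeline_manifest <- function(families_in, excl_batch, excl_mdqc, analyzed,
                              bins_built, bins_qc, segments, candidates,
                              reported) {
  tibble::tibble(
    stage = c("families_in", "families_excluded_batch",
              "families_excluded_mdqc", "families_analyzed", "bins_built",
              "bins_qc_pass", "segments", "candidates", "reported_calls"),
    n = as.integer(c(families_in, excl_batch, excl_mdqc, analyzed,
                     bins_built, bins_qc, segments, candidates, reported)))
}

#' Exclude families failing batch/lab quality control
#'
#' Families whose members were run in different batches, or with any
#' member failing the reporting lab's QC, are excluded before analysis.
#' With no usable `sample_info` the filter is skipped with a warning.
#'
#' @param pedigree Pedigree tibble.
#' @param sample_info Tibble with `sample_id` plus optional `batch` and
#'   `qc_fail` columns, or `NULL`.
#' @return List with the retained `pedigree` and `n_excluded`.
#' @export
md_batch_qc_filter <- function(pedigree, sample_info = NULL) {
  if (is.null(sample_info) ||
      !any(c("batch", "qc_fail") %in% names(sample_info))) {
    if (!is.null(sample_info)) {
      warning("sample_info lacks batch/qc_fail columns; filter skipped")
    }
    return(list(pedigree = pedigree, n_excluded = 0L))
  }
  bad <- vapply(seq_len(nrow(pedigree)), function(i) {
    ids <- unlist(pedigree[i, c("offspring_id", "father_id", "mother_id")])
    info <- sample_info[match(ids, sample_info$sample_id), ]
    span_batches <- "batch" %in% names(info) &&
      length(unique(stats::na.omit(info$batch))) > 1
    failed <- "qc_fail" %in% names(info) && any(info$qc_fail %in% TRUE)
    span_batches || failed
  }, logical(1))
  list(pedigree = pedigree[!bad, ], n_excluded = sum(bad))
}

write_tsv_plain <- function(x, path) {
  x <- x[, !vapply(x, is.list, logical(1)), drop = FALSE]
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("bins", "counts", "mscores", "flags", "family_qc",
               "md_track", "segments", "calls", "manifest")) {
    if (!is.null(res[[nm]])) {
      write_tsv_plain(res[[nm]], file.path(outdir, paste0(nm, ".tsv")))
    }
  }
  reported <- dplyr::filter(res$calls, .data$status == "reported")
  if (nrow(reported) > 0) {
    md_write_bed(dplyr::mutate(reported, name = .data$family_id)[,
                   c("chrom", "start", "end", "name")],
                 file.path(outdir, "calls.bed"))
  }
  invisible(outdir)
}

#' @export
print.md_pipeline <- function(x, ...) {
  cat("de novo deletion pipeline run\n")
  print(x$manifest, n = Inf)
  if (!is.null(x$calls) && nrow(x$calls) > 0) {
    cat("\ncalls:\n")
    print(dplyr::select(x$calls, -"bin_ids"), n = 20)
  }
  invisible(x)
}

#' Tidy pipeline calls
#'
#' @param x An `md_pipeline` object.
#' @param ... Unused.
#' @return The call tibble without the list-column.
#' @method tidy md_pipeline
#' @export
tidy.md_pipeline <- function(x, ...) {
  dplyr::select(x$calls, -"bin_ids")
}

#' One-row pipeline summary
#'
#' @param x An `md_pipeline` object.
#' @param ... Unused.
#' @return Wide one-row tibble of the stage counts.
#' @method glance md_pipeline
#' @export
glance.md_pipeline <- function(x, ...) {
  tidyr::pivot_wider(x$manifest, names_from = "stage", values_from = "n")
}
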