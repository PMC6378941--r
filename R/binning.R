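#' Coverage-adaptive binning configuration
#'
#' Bins are defined empirically from the data rather than by a fixed width:
#' a subsample of study samples defines proto-regions (bases where at least
#' one sample reaches `proto_min_depth`), which are then partitioned
#' left-to-right into bins closing as soon as the median read count across
#' the subsample reaches `min_median_reads`.  The default target of 160
#' reads separates copy-neutral from single-bin heterozygous-deletion means
#' by more than 6 Poisson standard deviations (see [md_separation_sd()]).
#'
#' @param n_subsample Samples drawn to define bins (default 25).
#' @param proto_min_depth Per-base depth defining proto-regions (default 10).
#' @param min_median_reads Per-bin median read target (default 160).
#' @param min_mappability QC floor on mean bin mappability (default 0.75).
#' @param gc_range Closed interval of acceptable mean GC (default
#'   `c(0.15, 0.85)`).
#' @param seed Seed for the sample subsample (`NULL` = use current RNG state).
#' @return A list of class `md_binning_config`.
#' @export
md_binning_config <- function(n_subsample = 25L, proto_min_depth = 10L,
                              min_median_reads = 160L,
                              min_mappability = 0.75,
                              gc_range = c(0.15, 0.85), seed = NULL) {
  stopifnot(proto_min_depth >= 1, min_median_reads >= 1,
            length(gc_range) == 2, all(gc_range >= 0 & gc_range <= 1))
  structure(list(n_subsample = as.integer(n_subsample),
                 proto_min_depth = as.integer(proto_min_depth),
                 min_median_reads = as.integer(min_median_reads),
                 min_mappability = min_mappability,
                 gc_range = gc_range, seed = seed),
            class = "md_binning_config")
}

#' Poisson separation of copy states at a given read target
#'
#' With a per-bin copy-neutral mean of `c` reads, a heterozygous deletion
#' has mean `c/2`; under a Poisson model the two means are
#' `(c - c/2) / sqrt(c)` copy-neutral standard deviations apart.  At the
#' default `c = 160` this is about 6.32, i.e. more than 6 SD.
#'
#' @param min_median_reads Copy-neutral per-bin read target (positive).
#' @return Separation in copy-neutral Poisson SD units.
#' @examples
#' md_separation_sd(160)  # 6.325
#' @export
md_separation_sd <- function(min_median_reads) {
  if (any(min_median_reads <= 0)) stop("min_median_reads must be positive")
  c0 <- min_median_reads
  (c0 - c0 / 2) / sqrt(c0)
}

#' Subsample the study samples used to define bins
#'
#' Uniform draw without replacement, reproducible under `seed`.  If fewer
#' samples are available than requested, all are used with a warning.
#'
#' @param sample_ids Character vector of all sample IDs.
#' @param n Number to draw.
#' @param seed Optional integer seed.
#' @return Character vector of selected IDs.
#' @export
md_subsample <- function(sample_ids, n = 25L, seed = NULL) {
  if (length(sample_ids) < n) {
    warning("fewer samples (", length(sample_ids), ") than requested (", n,
            "); using all")
    return(sample_ids)
  }
  draw <- function() sample(sample_ids, n)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Proto-regions: bases where any subsampled sample reaches the depth floor
#'
#' Maximal runs of consecutive bases at which the maximum per-base depth
#' across the subsampled samples is at least `min_depth` (threshold
#' inclusive).
#'
#' @param reads_by_sample Named list of read tables (the subsample).
#' @param min_depth Per-base depth threshold (default 10).
#' @return Sorted, disjoint interval tibble.
#' @export
md_proto_regions <- function(reads_by_sample, min_depth = 10L) {
  reads_by_sample <- as_reads_list(reads_by_sample)
  chroms <- sort(unique(unlist(lapply(reads_by_sample, function(r) r$chrom))))
  out <- list()
  for (chr in chroms) {
    width <- max(unlist(lapply(reads_by_sample, function(r) {
      e <- r$end[r$chrom == chr]
      if (length(e)) max(e) else 0L
    })))
    if (width == 0) next
    depth_max <- integer(width)
    for (r in reads_by_sample) {
      depth_max <- pmax(depth_max,
                        as.integer(coverage_rle(r, chr, width)))
    }
    runs <- IRanges::slice(S4Vectors::Rle(depth_max), lower = min_depth,
                           rangesOnly = TRUE)
    if (length(runs) > 0) {
      out[[chr]] <- tibble::tibble(chrom = chr,
                                   start = IRanges::start(runs),
                                   end = IRanges::end(runs))
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  dplyr::bind_rows(out)
}

# lower median: for even n the smaller of the two central order statistics
median_low <- function(x) {
  n <- length(x)
  sort(x)[floor((n + 1) / 2)]
}

#' Partition one proto-region into read-depth bins
#'
#' Scans the proto-region left to right, growing the current bin base by
#' base and closing it at the first base where the median (across the
#' subsampled samples; lower median for even counts) number of reads
#' overlapping the growing bin reaches `min_median_reads`.  Trailing bases
#' that never reach the target are merged into the last closed bin; a
#' proto-region that never reaches the target becomes a single bin
#' (retained, subject to QC).
#'
#' @param region Single-row interval tibble (a proto-region).
#' @param reads_by_sample Named list of read tables (the subsample).
#' @param min_median_reads Median read target per bin.
#' @return Interval tibble of bins tiling the proto-region exactly.
#' @export
md_partition_region <- function(region, reads_by_sample,
                                min_median_reads = 160L) {
  reads_by_sample <- as_reads_list(reads_by_sample)
  partition_region_idx(region, sorted_read_index(reads_by_sample),
                       min_median_reads)
}

# per sample: chromosome-wise sorted read start/end positions (as doubles,
# so findInterval does not re-coerce on every call)
sorted_read_index <- function(reads_by_sample) {
  lapply(reads_by_sample, function(r) {
    lapply(split(r[, c("start", "end")], r$chrom), function(x) {
      list(starts = sort(as.numeric(x$start)),
           ends = sort(as.numeric(x$end)))
    })
  })
}

partition_region_idx <- function(region, index, min_median_reads = 160L) {
  validate_intervals(region)
  stopifnot(nrow(region) == 1)
  n_s <- length(index)
  rs <- region$start
  re <- region$end
  L <- re - rs + 1L
  pos <- as.numeric(seq.int(rs, re))

  # per sample, along the region: cumulative counts of read starts <= p
  # (C) and of read ends < p (E); reads overlapping the window [s, p] are
  # then C[i, p] - E[i, s], each obtained with a single findInterval pass
  # over the pre-sorted starts/ends
  C <- E <- matrix(0, nrow = n_s, ncol = L)
  for (i in seq_len(n_s)) {
    ix <- index[[i]][[region$chrom]]
    if (is.null(ix)) ix <- list(starts = numeric(), ends = numeric())
    C[i, ] <- findInterval(pos, ix$starts)
    E[i, ] <- findInterval(pos - 1, ix$ends)
  }
  # lower median across n_s samples >= t  <=>  at least (n_s - k + 1)
  # samples have count >= t, with k the lower-median order statistic
  k <- floor((n_s + 1) / 2)
  need <- n_s - k + 1L

  boundaries <- integer(0)  # closing positions (absolute coordinates)
  s <- rs
  chunk <- 256L
  while (s <= re) {
    s_idx <- s - rs + 1L
    thr <- min_median_reads + E[, s_idx]  # reads overlapping [s, p] >= target
    close_at <- NA_integer_
    p0 <- s_idx
    while (p0 <= L) {
      p1 <- min(p0 + chunk - 1L, L)
      ok <- colSums(C[, p0:p1, drop = FALSE] >= thr) >= need
      hit <- which(ok)
      if (length(hit) > 0) {
        close_at <- as.integer(pos[p0 + hit[1] - 1L])
        break
      }
      p0 <- p1 + 1L
    }
    if (is.na(close_at)) break  # remainder never reaches target
    boundaries <- c(boundaries, close_at)
    s <- close_at + 1L
  }

  if (length(boundaries) == 0) {
    return(tibble::tibble(chrom = region$chrom, start = rs, end = re))
  }
  # trailing remainder (if any) merges into the last closed bin
  boundaries[length(boundaries)] <- re
  tibble::tibble(chrom = region$chrom,
                 start = c(rs, head(boundaries, -1) + 1L),
                 end = boundaries)
}

#' Apply bin-level quality control
#'
#' A bin passes QC iff its mean mappability is at least `min_mappability`
#' and its mean GC lies inside the closed `gc_range`.  Bins with undefined
#' GC (all-N sequence) fail.
#'
#' @param bins Bin tibble with `gc` and `mappability` columns.
#' @param min_mappability,gc_range See [md_binning_config()].
#' @return `bins` with a logical `qc_pass` column.
#' @export
md_bin_qc <- function(bins, min_mappability = 0.75,
                      gc_range = c(0.15, 0.85)) {
  stopifnot(all(c("gc", "mappability") %in% names(bins)))
  bins$qc_pass <- !is.na(bins$gc) &
    bins$mappability >= min_mappability &
    bins$gc >= gc_range[1] & bins$gc <= gc_range[2]
  bins
}

#' Build the full coverage-adaptive bin set
#'
#' Runs the binning stage end to end: subsample samples, find proto-regions,
#' partition each into bins, annotate GC and mappability, and apply QC.
#' QC-failing bins are kept in the result (with `qc_pass = FALSE`) but must
#' be excluded from counting/normalization downstream.
#'
#' @param reads Read table with `sample_id` or named list of per-sample read
#'   tables (all study samples; the subsample is drawn internally).
#' @param config A [md_binning_config()].
#' @param reference Reference sequence for GC (see [md_gc_content()]), or
#'   `NULL` to skip (GC set to 0.5, passing QC).
#' @param mappability Mappability track for [md_mappability()], or `NULL`
#'   for a constant 1.
#' @param targets Optional target-region interval tibble; bins are assigned
#'   a `region_id` by overlap (bins outside all targets get `NA` and fail
#'   QC).  With `targets = NULL`, each proto-region is its own region.
#' @return Bin tibble: `bin_id`, `region_id`, `chrom`, `start`, `end`,
#'   `gc`, `mappability`, `qc_pass`.
#' @export
md_build_bins <- function(reads, config = md_binning_config(),
                          reference = NULL, mappability = NULL,
                          targets = NULL) {
  reads_by_sample <- as_reads_list(reads)
  sub_ids <- md_subsample(names(reads_by_sample), config$n_subsample,
                          config$seed)
  sub <- reads_by_sample[sub_ids]
  proto <- md_proto_regions(sub, config$proto_min_depth)
  if (nrow(proto) == 0) {
    return(tibble::tibble(bin_id = character(), region_id = character(),
                          chrom = character(), start = integer(),
                          end = integer(), gc = numeric(),
                          mappability = numeric(), qc_pass = logical()))
  }
  idx <- sorted_read_index(sub)
  bins <- purrr::map_dfr(seq_len(nrow(proto)), function(i) {
    b <- partition_region_idx(proto[i, ], idx, config$min_median_reads)
    b$proto_id <- i
    b
  })
  if (is.null(targets)) {
    bins$region_id <- sprintf("region_%03d", bins$proto_id)
  } else {
    validate_intervals(targets)
    hits <- GenomicRanges::findOverlaps(as_granges(bins), as_granges(targets),
                                        select = "first")
    bins$region_id <- ifelse(is.na(hits), NA_character_,
                             sprintf("region_%03d", hits))
  }
  bins$proto_id <- NULL
  if (is.null(reference)) bins$gc <- 0.5 else bins <- md_gc_content(bins, reference)
  bins <- md_mappability(bins, mappability)
  bins <- md_bin_qc(bins, config$min_mappability, config$gc_range)
  bins$qc_pass <- bins$qc_pass & !is.na(bins$region_id)
  bins$bin_id <- sprintf("bin_%05d", seq_len(nrow(bins)))
  dplyr::select(bins, "bin_id", "region_id", "chrom", "start", "end",
                "gc", "mappability", "qc_pass")
}
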