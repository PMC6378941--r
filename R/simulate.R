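#' Capture profile for the synthetic-data generator
#'
#' Describes a toy capture design: a set of targeted regions on one
#' synthetic chromosome, each with its own relative capture intensity
#' (log-normal across regions, emulating heterogeneous capture
#' efficiency), sequenced with 100 bp paired-end reads.  The default
#' per-base fragment rate of 0.33 gives about 66x median per-base coverage
#' — the study-like regime in which bins targeting a median of 160 reads
#' come out a few hundred bp wide.
#'
#' @param n_regions Number of targeted regions (default 13, the footprint
#'   of a typical multi-locus targeted design).
#' @param region_size Width of each region in bp (default 15000).
#' @param gap Gap between consecutive regions (default 20000).
#' @param chrom Name of the synthetic chromosome.
#' @param read_length Read length in bp (default 100).
#' @param fragment_mean,fragment_sd Fragment-length distribution (defaults
#'   400 and 60, inside a 300-500 bp size-selection window).
#' @param base_rate Expected fragments per base per unit intensity
#'   (default 0.33; coverage is about `2 * read_length * base_rate`).
#' @param region_intensity_sdlog Log-normal SD of per-region capture
#'   intensity (default 0.3).
#' @param sample_scale_sdlog Log-normal SD of per-sample depth scale
#'   (default 0.15, matching a median-coverage MAD of roughly 15 at 66x).
#' @param seed Seed for the per-region intensities.
#' @return A list of class `md_capture_profile` with a `regions` tibble
#'   (`chrom`, `start`, `end`, `intensity`, `name`) and the parameters.
#' @export
md_capture_profile <- function(n_regions = 13L, region_size = 15000L,
                               gap = 20000L, chrom = "sim1",
                               read_length = 100L, fragment_mean = 400,
                               fragment_sd = 60, base_rate = 0.33,
                               region_intensity_sdlog = 0.3,
                               sample_scale_sdlog = 0.15, seed = 1L) {
  starts <- 10000L + (seq_len(n_regions) - 1L) * (region_size + gap)
  intensity <- withr::with_seed(seed, {
    exp(rnorm(n_regions, 0, region_intensity_sdlog))
  })
  regions <- tibble::tibble(chrom = chrom, start = starts,
                            end = starts + region_size - 1L,
                            intensity = intensity,
                            name = sprintf("target_%03d", seq_len(n_regions)))
  structure(list(regions = regions, read_length = as.integer(read_length),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 base_rate = base_rate,
                 sample_scale_sdlog = sample_scale_sdlog,
                 chrom_length = max(regions$end) + 10000L, chrom = chrom),
            class = "md_capture_profile")
}

#' Synthetic reference sequence for a capture profile
#'
#' Random nucleotide sequence over the profile's chromosome with a slowly
#' varying GC propensity (sinusoidal between about 0.35 and 0.65), so that
#' bins acquire a realistic spread of GC values for the loess adjustment.
#'
#' @param profile A [md_capture_profile()].
#' @param seed Integer seed.
#' @param gc_period Period of the GC oscillation in bp (default 6000).
#' @return Named [Biostrings::DNAStringSet] of length 1.
#' @export
md_simulate_reference <- function(profile, seed = 1L, gc_period = 6000) {
  n <- profile$chrom_length
  withr::with_seed(seed, {
    gc_prob <- 0.5 + 0.15 * sin(2 * pi * seq_len(n) / gc_period)
    is_gc <- rbinom(n, 1, gc_prob) == 1
    half <- runif(n) < 0.5
    base <- ifelse(is_gc, ifelse(half, "G", "C"), ifelse(half, "A", "T"))
    ref <- Biostrings::DNAStringSet(paste(base, collapse = ""))
    names(ref) <- profile$chrom
    ref
  })
}

# paired reads for one sample; scale multiplies the fragment rate
simulate_sample_reads <- function(profile, sample_id, scale = 1,
                                  pair_info = TRUE) {
  rl <- profile$read_length
  regs <- profile$regions
  per_region <- lapply(seq_len(nrow(regs)), function(i) {
    L <- regs$end[i] - regs$start[i] + 1L
    lambda <- profile$base_rate * regs$intensity[i] * scale * L
    n_frag <- rpois(1, lambda)
    if (n_frag == 0) return(NULL)
    flen <- pmax(round(rnorm(n_frag, profile$fragment_mean,
                             profile$fragment_sd)), 2L * rl)
    fstart <- pmax(1L, regs$start[i] - flen + 1L +
                     floor(runif(n_frag) * (L + flen - 1L)))
    fend <- fstart + flen - 1L
    tibble::tibble(
      region = i,
      fstart = as.integer(fstart), fend = as.integer(fend))
  })
  frags <- dplyr::bind_rows(per_region)
  if (nrow(frags) == 0) {
    out <- tibble::tibble(sample_id = character(), chrom = character(),
                          start = integer(), end = integer())
    if (pair_info) {
      out$pair_id <- integer(); out$mate <- integer()
      out$mate_start <- integer(); out$fragment <- integer()
    }
    return(out)
  }
  out <- tibble::tibble(
    sample_id = sample_id,
    chrom = profile$chrom,
    start = c(frags$fstart, frags$fend - rl + 1L),
    end = c(frags$fstart + rl - 1L, frags$fend))
  if (pair_info) {
    out$pair_id <- rep(seq_len(nrow(frags)), 2)
    out$mate <- rep(1:2, each = nrow(frags))
    out$mate_start <- c(frags$fend - rl + 1L, frags$fstart)
    out$fragment <- rep(frags$fend - frags$fstart + 1L, 2)
  }
  dplyr::arrange(out, .data$start)
}

#' Simulate paired-end capture reads for the members of one trio
#'
#' Fragments are placed by a Poisson process with the profile's per-region
#' intensity; each sample's overall depth is scaled by an independent
#' log-normal factor to mimic inter-sample variation.  Reads are the two
#' 100 bp ends of each fragment.  Deterministic under `seed`.
#'
#' @param profile A [md_capture_profile()].
#' @param sample_ids Character vector (typically offspring, father,
#'   mother).
#' @param seed Integer seed.
#' @param pair_info Keep the mate bookkeeping columns (`pair_id`, `mate`,
#'   `mate_start`, `fragment`) needed to export proper pairs with
#'   [md_write_bam()]; drop them (`FALSE`) to halve memory when only read
#'   spans are needed.
#' @return Named list of per-sample read tables (columns `sample_id`,
#'   `chrom`, `start`, `end`, plus the pair columns when `pair_info`).
#' @export
md_simulate_trio_reads <- function(profile, sample_ids, seed = 1L,
                                   pair_info = TRUE) {
  withr::with_seed(seed, {
    scales <- exp(rnorm(length(sample_ids), 0, profile$sample_scale_sdlog))
    out <- lapply(seq_along(sample_ids), function(i) {
      simulate_sample_reads(profile, sample_ids[i], scales[i], pair_info)
    })
    names(out) <- sample_ids
    out
  })
}

#' Spike a deletion into a read table by dropping reads
#'
#' Every read whose aligned span overlaps the interval is removed
#' independently with the given probability (mates are treated
#' independently: a mate not overlapping the interval always survives).
#' With probability 0.5 this halves the expected depth over the interval —
#' a heterozygous deletion; dropping both a proband's and one parent's
#' reads emulates an inherited deletion.
#'
#' @param reads Read table.
#' @param interval Single-row interval tibble.
#' @param drop_probability Probability in \[0, 1\] (default 0.5).
#' @param seed Optional integer seed.
#' @return The read table with dropped reads removed.
#' @export
md_spike_deletion <- function(reads, interval, drop_probability = 0.5,
                              seed = NULL) {
  validate_reads(reads)
  validate_intervals(interval)
  stopifnot(drop_probability >= 0, drop_probability <= 1)
  run <- function() {
    hit <- reads$chrom == interval$chrom &
      reads$start <= interval$end & reads$end >= interval$start
    drop <- hit & runif(nrow(reads)) < drop_probability
    reads[!drop, , drop = FALSE]
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a cohort of trios
#'
#' @param profile A [md_capture_profile()].
#' @param n_trios Number of parent-offspring trios.
#' @param seed Integer seed (per-trio seeds are derived from it).
#' @param pair_info Keep mate bookkeeping columns (see
#'   [md_simulate_trio_reads()]); off by default for cohort-scale runs.
#' @return List with `reads` (named list over all samples) and `pedigree`.
#' @export
md_simulate_cohort <- function(profile, n_trios, seed = 1L,
                               pair_info = FALSE) {
  pedigree <- tibble::tibble(
    family_id = sprintf("F%03d", seq_len(n_trios)),
    offspring_id = sprintf("F%03d_o", seq_len(n_trios)),
    father_id = sprintf("F%03d_f", seq_len(n_trios)),
    mother_id = sprintf("F%03d_m", seq_len(n_trios)))
  reads <- list()
  for (i in seq_len(n_trios)) {
    ids <- c(pedigree$offspring_id[i], pedigree$father_id[i],
             pedigree$mother_id[i])
    reads <- c(reads, md_simulate_trio_reads(
      profile, ids, seed = (seed * 1000L + i) %% 2147483647L,
      pair_info = pair_info))
  }
  list(reads = reads, pedigree = pedigree)
}

#' Plan spike-in deletions for a cohort
#'
#' Two layouts are available.  `"rotating"` (the scaled default used by
#' [md_run_benchmark()]): every trio receives one de novo and one inherited
#' deletion, in two distinct randomly chosen regions, with sizes rotating
#' through `sizes` across trios so each size is represented equally.
#' `"full"`: every trio receives the complete design — the regions are
#' split into 5 de novo and 5 inherited hosts, one deletion of each size in
#' each group (requires exactly `2 * length(sizes)` regions).  Each
#' deletion is placed uniformly inside its host region; inherited
#' deletions are additionally assigned a random carrier parent.
#'
#' @param profile A [md_capture_profile()].
#' @param pedigree Cohort pedigree.
#' @param sizes Deletion sizes in bp (default 250/500/1000/2000/4000).
#' @param layout `"rotating"` or `"full"`.
#' @param seed Integer seed.
#' @return Truth tibble: `family_id`, `chrom`, `start`, `end`, `size`,
#'   `kind` (`de_novo`/`inherited`), `carrier_parent`, `region_id`.
#' @export
md_spike_plan <- function(profile, pedigree,
                          sizes = c(250L, 500L, 1000L, 2000L, 4000L),
                          layout = c("rotating", "full"), seed = 1L) {
  layout <- match.arg(layout)
  regs <- profile$regions
  n_reg <- nrow(regs)
  place <- function(region_idx, size) {
    lo <- regs$start[region_idx]
    hi <- regs$end[region_idx] - size + 1L
    stopifnot(hi >= lo)  # region too small to host the deletion
    s <- lo + floor(runif(1) * (hi - lo + 1L))
    c(s, s + size - 1L)
  }
  withr::with_seed(seed, {
    rows <- list()
    if (layout == "rotating") {
      n_sz <- length(sizes)
      for (i in seq_len(nrow(pedigree))) {
        two <- sample.int(n_reg, 2)
        sz_dn <- sizes[(i - 1L) %% n_sz + 1L]
        sz_in <- sizes[(i) %% n_sz + 1L]
        p_dn <- place(two[1], sz_dn)
        p_in <- place(two[2], sz_in)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          family_id = pedigree$family_id[i], chrom = regs$chrom[two],
          start = as.integer(c(p_dn[1], p_in[1])),
          end = as.integer(c(p_dn[2], p_in[2])),
          size = c(sz_dn, sz_in), kind = c("de_novo", "inherited"),
          carrier_parent = c("none", sample(c("father", "mother"), 1)),
          region_id = sprintf("region_%03d", two))
      }
    } else {
      stopifnot(n_reg == 2L * length(sizes))
      for (i in seq_len(nrow(pedigree))) {
        ord <- sample.int(n_reg)
        dn_reg <- ord[seq_along(sizes)]
        in_reg <- ord[length(sizes) + seq_along(sizes)]
        pos_dn <- vapply(seq_along(sizes),
                         function(j) place(dn_reg[j], sizes[j]), numeric(2))
        pos_in <- vapply(seq_along(sizes),
                         function(j) place(in_reg[j], sizes[j]), numeric(2))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          family_id = pedigree$family_id[i],
          chrom = regs$chrom[c(dn_reg, in_reg)],
          start = as.integer(c(pos_dn[1, ], pos_in[1, ])),
          end = as.integer(c(pos_dn[2, ], pos_in[2, ])),
          size = c(sizes, sizes),
          kind = rep(c("de_novo", "inherited"), each = length(sizes)),
          carrier_parent = c(rep("none", length(sizes)),
                             sample(c("father", "mother"), length(sizes),
                                    replace = TRUE)),
          region_id = sprintf("region_%03d", c(dn_reg, in_reg)))
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Apply a spike plan to cohort reads
#'
#' De novo deletions drop the proband's reads; inherited deletions drop
#' the proband's and the carrier parent's reads, both with the plan's drop
#' probability.
#'
#' @param reads Named list of per-sample read tables.
#' @param truth Spike plan from [md_spike_plan()].
#' @param pedigree Cohort pedigree.
#' @param drop_probability Default 0.5.
#' @param seed Integer seed.
#' @return Modified read list.
#' @export
md_apply_spikes <- function(reads, truth, pedigree, drop_probability = 0.5,
                            seed = 1L) {
  withr::with_seed(seed, {
    for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      ped <- pedigree[pedigree$family_id == tr$family_id, ]
      victims <- ped$offspring_id
      if (tr$kind == "inherited") {
        victims <- c(victims,
                     if (tr$carrier_parent == "father") ped$father_id
                     else ped$mother_id)
      }
      for (v in victims) {
        reads[[v]] <- md_spike_deletion(reads[[v]], tr[, c("chrom", "start", "end")],
                                        drop_probability, seed = NULL)
      }
    }
    reads
  })
}
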