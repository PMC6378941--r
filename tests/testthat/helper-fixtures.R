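# Shared fixtures, built once per test run.

# A small cohort with one heterozygous de novo spike, run through the full
# pipeline.  Sized so a 2 kb deletion stays well below the family-QC
# thresholds (~570 bins) while remaining quick.
e2e_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    profile <- md_capture_profile(n_regions = 8L, region_size = 8000L,
                                  seed = 5L)
    cohort <- md_simulate_cohort(profile, n_trios = 12L, seed = 21L)
    reference <- md_simulate_reference(profile, seed = 5L)
    spike <- tibble::tibble(family_id = "F001", chrom = "sim1",
                            start = profile$regions$start[3] + 2500L,
                            end = profile$regions$start[3] + 4499L,
                            size = 2000L, kind = "de_novo",
                            carrier_parent = "none",
                            region_id = "region_003")
    reads <- md_apply_spikes(cohort$reads, spike, cohort$pedigree,
                             drop_probability = 0.5, seed = 31L)
    run <- function() {
      md_run_pipeline(reads, cohort$pedigree, targets = profile$regions,
                      reference = reference,
                      binning = md_binning_config(n_subsample = 25L,
                                                  seed = 11L))
    }
    cache <<- list(profile = profile, cohort = cohort,
                   reference = reference, spike = spike, reads = reads,
                   run = run, result = run())
    cache
  }
})

# The spike-in benchmark at the scaled study conditions (50 trios x 5
# replicates, all spike sizes, drop probability 0.5); computed once and
# shared by the acceptance checks.
benchmark_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- md_run_benchmark(seed = 137L)
    cache
  }
})

# an indexed BAM written from a read table; returns the path
write_bam_fixture <- function(reads, name, chrom_lengths = NULL) {
  dir <- file.path(tempdir(), "bam-fixtures")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  md_write_bam(reads, file.path(dir, paste0(name, ".bam")),
               chrom_lengths = chrom_lengths)
}
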