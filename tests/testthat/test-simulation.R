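test_that("read simulation is seeded, capture-shaped, and scalable", {
  prof <- md_capture_profile(n_regions = 2L, region_size = 3000L)
  r1 <- md_simulate_trio_reads(prof, c("o", "f", "m"), seed = 4L)
  r2 <- md_simulate_trio_reads(prof, c("o", "f", "m"), seed = 4L)
  expect_identical(r1, r2)
  expect_named(r1, c("o", "f", "m"))
  # reads only fall within regions +/- one fragment length
  regs <- prof$regions
  lo <- min(regs$start) - 3 * prof$fragment_mean
  hi <- max(regs$end) + 3 * prof$fragment_mean
  expect_true(all(r1$o$start >= lo & r1$o$end <= hi))
  # zero intensity -> no reads
  prof0 <- md_capture_profile(n_regions = 2L, base_rate = 0)
  r0 <- md_simulate_trio_reads(prof0, "o", seed = 4L)
  expect_equal(nrow(r0$o), 0L)
})

test_that("bins built from simulated coverage hit the 160-read target", {
  prof <- md_capture_profile(n_regions = 2L, region_size = 6000L,
                             region_intensity_sdlog = 0)
  cohort <- md_simulate_cohort(prof, n_trios = 4L, seed = 13L)
  bins <- md_build_bins(cohort$reads,
                        md_binning_config(n_subsample = 12L, seed = 2L),
                        targets = prof$regions)
  counts <- md_bin_counts(cohort$reads, bins)
  med <- apply(as.matrix(counts[, md_sample_cols(counts)]), 1, median)
  # median per-bin count within 10% of the 160-read target
  expect_lt(abs(median(med) - 160), 16)
  expect_true(mean(med >= 144) > 0.9)
})

test_that("spiking drops overlapping reads at the requested probability", {
  reads <- make_reads(seq(1, 20000, by = 10), seq(100, 20099, by = 10))
  del <- md_intervals("c1", 5000, 14999)
  # probability 0: identity
  expect_identical(md_spike_deletion(reads, del, 0, seed = 1), reads)
  # probability 1: nothing overlapping survives
  gone <- md_spike_deletion(reads, del, 1, seed = 1)
  expect_equal(sum(gone$start <= del$end & gone$end >= del$start), 0L)
  expect_equal(nrow(gone), sum(reads$start > del$end | reads$end < del$start))
  # probability 0.5: surviving count within binomial 99% bounds
  n_in <- sum(reads$start <= del$end & reads$end >= del$start)
  kept <- md_spike_deletion(reads, del, 0.5, seed = 7)
  n_kept <- sum(kept$start <= del$end & kept$end >= del$start)
  bounds <- qbinom(c(0.005, 0.995), n_in, 0.5)
  expect_gte(n_kept, bounds[1])
  expect_lte(n_kept, bounds[2])
  # reads outside the interval are untouched
  expect_identical(kept[kept$start > del$end | kept$end < del$start, ],
                   reads[reads$start > del$end | reads$end < del$start, ])
})

test_that("spiked intervals halve the expected per-bin depth", {
  prof <- md_capture_profile(n_regions = 1L, region_size = 6000L)
  cohort <- md_simulate_cohort(prof, n_trios = 1L, seed = 3L)
  del <- md_intervals("sim1", prof$regions$start + 2000L,
                      prof$regions$start + 3999L)
  bins <- md_intervals("sim1",
                       seq(prof$regions$start + 2000L, by = 200L,
                           length.out = 10),
                       seq(prof$regions$start + 2199L, by = 200L,
                           length.out = 10))
  pre <- md_bin_counts(cohort$reads[1], bins)
  post <- md_bin_counts(list(x = md_spike_deletion(cohort$reads[[1]], del,
                                                   0.5, seed = 5)), bins)
  ratio <- sum(post$x) / sum(pre[[4]])
  expect_equal(ratio, 0.5, tolerance = 0.08)
})

test_that("spike plans respect layout, hosting regions, and disjointness", {
  prof <- md_capture_profile()
  ped <- tibble::tibble(family_id = sprintf("F%02d", 1:10),
                        offspring_id = sprintf("F%02d_o", 1:10),
                        father_id = sprintf("F%02d_f", 1:10),
                        mother_id = sprintf("F%02d_m", 1:10))
  plan <- md_spike_plan(prof, ped, seed = 5)
  expect_equal(nrow(plan), 20L)
  expect_equal(as.vector(table(plan$kind)), c(10L, 10L))
  # every spike lies inside its host region
  hosts <- prof$regions[match(plan$region_id,
                              sprintf("region_%03d",
                                      seq_len(nrow(prof$regions)))), ]
  expect_true(all(plan$start >= hosts$start & plan$end <= hosts$end))
  expect_equal(plan$end - plan$start + 1L, plan$size)
  # within a family the two spikes never overlap (distinct regions)
  per_fam <- split(plan, plan$family_id)
  expect_true(all(vapply(per_fam, function(p) {
    p$region_id[1] != p$region_id[2]
  }, logical(1))))
  # full layout: 5 de novo + 5 inherited per family, one of each size
  full <- md_spike_plan(md_capture_profile(n_regions = 10L), ped,
                        layout = "full", seed = 5)
  expect_equal(nrow(full), 100L)
  one_fam <- full[full$family_id == "F01", ]
  expect_equal(sort(one_fam$size[one_fam$kind == "de_novo"]),
               c(250L, 500L, 1000L, 2000L, 4000L))
  expect_equal(length(unique(one_fam$region_id)), 10L)
})

test_that("call scoring equals the per-base coverage-fraction oracle", {
  truth <- tibble::tibble(family_id = c("T1", "T1", "T2"), chrom = "c1",
                          start = c(1000L, 5000L, 1000L),
                          end = c(1999L, 5999L, 1999L),
                          size = 1000L,
                          kind = c("de_novo", "inherited", "de_novo"),
                          carrier_parent = c("none", "father", "none"),
                          region_id = "region_001")
  calls <- tibble::tibble(family_id = c("T1", "T1", "T2"),
                          region_id = "region_001", chrom = "c1",
                          start = c(1700L, 5900L, 3000L),
                          end = c(2399L, 6099L, 3999L),
                          size = c(700L, 200L, 1000L), n_bins = 5L,
                          mean_md = -0.95, n_flagged = 0L,
                          status = "reported", bin_ids = list(NULL))
  for (th in c(0, 0.25, 0.5)) {
    sc <- md_score_calls(calls, truth, th)
    want <- vapply(seq_len(nrow(truth)), function(i) {
      cc <- calls[calls$family_id == truth$family_id[i], ]
      oracle_covered_fraction(truth$start[i], truth$end[i], cc$start, cc$end)
    }, numeric(1))
    expect_equal(sc$detection$covered_frac, want)
    expect_equal(sc$detection$detected,
                 if (th == 0) want > 0 else want >= th)
  }
  # call covering 30% of T1's de novo: detected at 25%, missed at 50%
  expect_true(md_score_calls(calls, truth, 0.25)$detection$detected[1])
  expect_false(md_score_calls(calls, truth, 0.5)$detection$detected[1])
  # call covering 10% of the inherited truth: any-overlap only
  expect_true(md_score_calls(calls, truth, 0)$detection$detected[2])
  expect_false(md_score_calls(calls, truth, 0.25)$detection$detected[2])
  # no calls at all
  sc0 <- md_score_calls(calls[0, ], truth, 0.25)
  expect_true(all(!sc0$detection$detected))
  expect_equal(nrow(sc0$false_positives), 0L)
  # T2's call matches nothing: an additional false positive with its width
  fp <- md_score_calls(calls, truth, 0.25)$false_positives
  expect_true(any(fp$family_id == "T2" & fp$match == "additional_fp" &
                    fp$width == 1000L))
})
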