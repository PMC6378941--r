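flags_tbl <- function(flags) {
  tibble::tibble(bin_id = sprintf("b%03d", seq_along(flags)),
                 n_outside = NA_integer_, variability_flag = flags)
}

seg_tbl <- function(mean_d, bin_idx, family = "T1") {
  tibble::tibble(family_id = family, region_id = "region_001", chrom = "c1",
                 start = 1L, end = 1000L, n_bins = length(bin_idx),
                 mean_d = mean_d,
                 bin_ids = list(sprintf("b%03d", bin_idx)))
}

test_that("variability flag uses a strict 5%-of-samples rule", {
  n_bins <- 3
  m <- matrix(0, n_bins, 100)
  m[1, 1:6] <- -1   # 6% outside -> flagged
  m[2, 1:5] <- -1   # 5% outside -> boundary, not flagged
  ms <- tibble::tibble(bin_id = sprintf("b%03d", 1:n_bins), chrom = "c1",
                       start = c(1L, 101L, 201L), end = c(100L, 200L, 300L))
  for (j in 1:100) ms[[sprintf("s%03d", j)]] <- m[, j]
  fl <- md_flag_variable_bins(ms)
  expect_equal(fl$variability_flag, c(TRUE, FALSE, FALSE))
  expect_equal(fl$n_outside, c(6L, 5L, 0L))
  expect_warning(md_flag_variable_bins(ms[, 1:10]), "fewer than 20")
})

test_that("a simulated copy-number polymorphism is flagged", {
  withr::with_seed(77, {
    counts <- matrix(rpois(50 * 100, 160), 50, 100)
    carriers <- sample(100, 30)
    counts[21:25, carriers] <- rbinom(5 * 30, counts[21:25, carriers], 0.5)
    x <- tibble::tibble(bin_id = sprintf("b%03d", 1:50), chrom = "c1",
                        start = seq(1L, by = 100L, length.out = 50),
                        end = seq(100L, by = 100L, length.out = 50),
                        gc = runif(50, 0.3, 0.7), mappability = 1)
    for (j in 1:100) x[[sprintf("s%03d", j)]] <- counts[, j]
  })
  fl <- md_flag_variable_bins(md_m_scores(x))
  expect_true(all(fl$variability_flag[21:25]))
  expect_true(sum(fl$variability_flag[-(21:25)]) <= 2)
})

test_that("candidates obey the closed +/-0.3 window and majority flag rule", {
  flags <- flags_tbl(rep(FALSE, 20))
  cfg <- md_calling_config()
  # mirrors the reported real-data call at MD -0.90 across 7 bins
  out <- md_call_de_novo(seg_tbl(-0.90, 1:7), flags, cfg)
  expect_equal(out$status, "reported")
  expect_equal(out$mean_md, -0.90)
  # -0.65 is outside the tolerance: not a candidate at all
  expect_equal(nrow(md_call_de_novo(seg_tbl(-0.65, 1:7), flags, cfg)), 0L)
  # boundary values are candidates (closed interval)
  expect_equal(nrow(md_call_de_novo(seg_tbl(-0.7, 1:7), flags, cfg)), 1L)
  expect_equal(nrow(md_call_de_novo(seg_tbl(-1.3, 1:7), flags, cfg)), 1L)
  # 4 of 7 bins flagged: 3/7 unflagged <= 1/2 -> suppressed but retained
  fl2 <- flags_tbl(c(rep(TRUE, 4), rep(FALSE, 16)))
  out2 <- md_call_de_novo(seg_tbl(-0.95, 1:7), fl2, cfg)
  expect_equal(out2$status, "suppressed")
  expect_equal(out2$n_flagged, 4L)
  # 3 of 7 flagged: 4/7 > 1/2 -> reported
  fl3 <- flags_tbl(c(rep(TRUE, 3), rep(FALSE, 17)))
  expect_equal(md_call_de_novo(seg_tbl(-0.95, 1:7), fl3, cfg)$status,
               "reported")
})

test_that("tightening the tolerance never adds calls", {
  withr::with_seed(15, means <- runif(40, -1.6, -0.4))
  flags <- flags_tbl(rep(FALSE, 10))
  segs <- dplyr::bind_rows(lapply(seq_along(means), function(i) {
    seg_tbl(means[i], 1:5, family = paste0("T", i))
  }))
  for (tol in c(0.3, 0.2, 0.1)) {
    calls <- md_call_de_novo(segs, flags, md_calling_config(md_tolerance = tol))
    if (tol == 0.3) wide <- calls$family_id
    expect_true(all(calls$family_id %in% wide))
    expect_lte(nrow(calls), length(wide))
  }
})

test_that("read-pair evidence counts discordant pairs spanning the call", {
  mk_pairs <- function(fstart, flen, offset = 0L) {
    n <- length(fstart)
    tibble::tibble(
      chrom = "c1",
      start = c(fstart, fstart + flen - 100L),
      end = c(fstart + 99L, fstart + flen - 1L),
      pair_id = rep(seq_len(n) + offset, 2),
      mate = rep(1:2, each = n),
      mate_start = c(fstart + flen - 100L, fstart),
      fragment = rep(flen, length.out = 2L * n))
  }
  withr::with_seed(19, {
    bg_start <- sample(1000:8000, 1000, TRUE)
    bg_len <- as.integer(round(rnorm(1000, 300, 30)))
  })
  proper <- mk_pairs(bg_start, pmax(bg_len, 210L))
  # deletion chr c1:4000-5000 -> offspring carries long-insert pairs over it
  long <- mk_pairs(as.integer(seq(3300, 3700, length.out = 12)), 3000L,
                   offset = 10000L)
  trio_bams <- c(
    offspring = write_bam_fixture(dplyr::bind_rows(proper, long), "ev_o",
                                  chrom_lengths = c(c1 = 20000)),
    father = write_bam_fixture(proper, "ev_f", chrom_lengths = c(c1 = 20000)),
    mother = write_bam_fixture(proper, "ev_m", chrom_lengths = c(c1 = 20000)))
  call <- tibble::tibble(chrom = "c1", start = 4000L, end = 5000L)
  ev <- md_read_pair_evidence(trio_bams, call, flank = 2000L)
  expect_equal(ev$member, c("offspring", "father", "mother"))
  expect_true(ev$n_discordant[1] >= 10)
  expect_equal(ev$n_discordant[2:3], c(0L, 0L))
  expect_true(all(ev$available))
  # a window with no reads at all
  far <- tibble::tibble(chrom = "c1", start = 15000L, end = 15500L)
  ev2 <- md_read_pair_evidence(trio_bams, far, flank = 100L)
  expect_equal(ev2$n_pairs, c(0L, 0L, 0L))
  # a missing BAM is reported as unavailable, not an error
  ev3 <- md_read_pair_evidence(c(offspring = "/nonexistent.bam"), call)
  expect_false(ev3$available)
})
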