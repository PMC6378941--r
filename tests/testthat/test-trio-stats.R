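test_that("minimum distance picks the smaller parent difference", {
  # inherited from father: cancels to 0
  expect_equal(md_minimum_distance_stat(-1, -1, 0), 0)
  # de novo: both deltas agree at -1
  expect_equal(md_minimum_distance_stat(-1, 0, 0), -1)
  # printed trio averages: deltaF = -0.99, deltaM = -0.94 -> -0.94
  expect_equal(md_minimum_distance_stat(-0.93, 0.06, 0.01), -0.94)
  # exact tie returns the father term: deltaF = 0.3, deltaM = -0.3
  expect_equal(md_minimum_distance_stat(0, -0.3, 0.3), 0.3)
  # |d| = min(|dF|, |dM|) and d is one of the two deltas, under random input
  withr::with_seed(3, {
    mo <- rnorm(500); mf <- rnorm(500); mm <- rnorm(500)
  })
  d <- md_minimum_distance_stat(mo, mf, mm)
  expect_equal(abs(d), pmin(abs(mo - mf), abs(mo - mm)))
  expect_true(all(d == (mo - mf) | d == (mo - mm)))
  # swapping parents leaves |d| unchanged
  expect_equal(abs(md_minimum_distance_stat(mo, mm, mf)), abs(d))
})

make_mscore_tbl <- function(m, samples) {
  n <- nrow(m)
  out <- tibble::tibble(bin_id = sprintf("b%03d", seq_len(n)),
                        region_id = "region_001", chrom = "c1",
                        start = seq(1L, by = 100L, length.out = n),
                        end = seq(100L, by = 100L, length.out = n))
  for (j in seq_along(samples)) out[[samples[j]]] <- m[, j]
  out
}

test_that("pedigree files are read and validated", {
  ped <- md_read_pedigree(system.file("extdata", "example_pedigree.tsv",
                                      package = "mdtrio"))
  expect_equal(nrow(ped), 3L)
  expect_equal(ped$offspring_id[1], "F001_o")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("family_id	offspring_id	father_id	mother_id",
               "X	s1	s1	s2"), bad)
  expect_error(md_read_pedigree(bad), "distinct")
})

test_that("trio tracks mask non-finite bins and keep genomic order", {
  m <- cbind(o = c(0, NA, -1, 0), f = c(0, 0, 0, 0), m = c(0, 0, 0, Inf))
  ms <- make_mscore_tbl(m, c("o", "f", "m"))
  ped <- tibble::tibble(family_id = "T1", offspring_id = "o",
                        father_id = "f", mother_id = "m")
  track <- md_minimum_distance(ms, ped)
  expect_equal(track$bin_id, c("b001", "b003"))
  expect_equal(track$d, c(0, -1))
  expect_error(md_minimum_distance(ms, dplyr::mutate(ped, mother_id = "zz")),
               "absent")
})

test_that("family QC applies the lag-10 autocorrelation and variance rules", {
  mk <- function(d) tibble::tibble(family_id = "T", d = d)
  # constant track: variance 0, autocorrelation defined as 0 -> passes
  qc0 <- md_family_qc(mk(rep(0, 50)))
  expect_equal(qc0$variance, 0)
  expect_equal(qc0$lag10_autocorrelation, 0)
  expect_true(qc0$pass)
  # white noise at variance 0.06 is excluded by the variance rule
  withr::with_seed(8, noisy <- rnorm(400, 0, sqrt(0.06)))
  qc1 <- md_family_qc(mk(noisy))
  expect_gt(qc1$variance, 0.05)
  expect_false(qc1$pass)
  expect_equal(qc1$reason, "variance")
  # AR(1) with phi chosen so phi^10 ~ 0.6 is excluded by autocorrelation
  phi <- 0.6^(1 / 10)
  withr::with_seed(9, {
    innov_sd <- sqrt(0.02 * (1 - phi^2))  # keeps variance ~0.02 < 0.05
    ar <- as.numeric(stats::arima.sim(list(ar = phi), 3000, sd = innov_sd))
  })
  qc2 <- md_family_qc(mk(ar))
  expect_gt(qc2$lag10_autocorrelation, 0.4)
  expect_lt(qc2$variance, 0.05)
  expect_false(qc2$pass)
  expect_equal(qc2$reason, "autocorrelation")
  # fewer than 11 bins: explicit failure reason
  qc3 <- md_family_qc(mk(rep(0, 5)))
  expect_false(qc3$pass)
  expect_equal(qc3$reason, "too_few_bins")
})

test_that("null trios are centred and de novo signal survives cancellation", {
  withr::with_seed(31, {
    n_bins <- 120
    counts <- matrix(rpois(n_bins * 30, 160), n_bins, 30)
  })
  samples <- sprintf("s%02d", 1:30)
  # family 1 copy-neutral; family 2 offspring-only deletion (de novo);
  # family 3 offspring+father deletion (inherited)
  del <- 41:60
  counts[del, 4] <- floor(counts[del, 4] / 2)   # F2 offspring
  counts[del, 7] <- floor(counts[del, 7] / 2)   # F3 offspring
  counts[del, 8] <- floor(counts[del, 8] / 2)   # F3 father
  x <- make_mscore_tbl(log2(counts + 1), samples)
  x[, samples] <- md_median_center(x[, c("bin_id", samples)])[, samples]
  ped <- tibble::tibble(family_id = c("F1", "F2", "F3"),
                        offspring_id = c("s01", "s04", "s07"),
                        father_id = c("s02", "s05", "s08"),
                        mother_id = c("s03", "s06", "s09"))
  track <- md_minimum_distance(x, ped)
  d1 <- track$d[track$family_id == "F1"]
  expect_lt(abs(mean(d1)), 0.05)
  # sign symmetry of the null distribution
  signs <- sum(d1 > 0)
  expect_gt(stats::binom.test(signs, length(d1))$p.value, 0.01)
  # de novo: mean d over the deleted run near -1
  d2 <- track$d[track$family_id == "F2"]
  expect_equal(mean(d2[del]), -1, tolerance = 0.12)
  # inherited: the statistic cancels to near 0
  d3 <- track$d[track$family_id == "F3"]
  expect_lt(abs(mean(d3[del])), 0.12)
})
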