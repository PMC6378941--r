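test_that("intervals are 1-based closed and size arithmetic matches", {
  x <- md_intervals(c("chr1", "chr8"), c(209945655, 130113612),
                    c(209947210, 130132753))
  expect_equal(md_interval_size(x), c(1556L, 19142L))
  expect_error(md_intervals("c", 0, 10), "1-based")
  expect_error(md_intervals("c", 10, 9), ">= start")
})

test_that("BED round-trip through 0-based half-open is lossless", {
  bins <- md_intervals("c1", c(1L, 101L, 500L), c(100L, 499L, 1556L))
  path <- withr::local_tempfile(fileext = ".bed")
  md_write_bed(bins, path)
  back <- md_read_bed(path)
  expect_equal(back[, c("chrom", "start", "end")], bins)
  # on disk the first interval must start at 0 (BED convention)
  expect_equal(strsplit(readLines(path)[1], "\t")[[1]][2], "0")
})

test_that("per-base coverage matches the interval-stabbing oracle", {
  region <- md_intervals("c1", 1, 300)
  # empty
  cov0 <- md_coverage(make_reads(integer(), integer()), region)
  expect_equal(cov0$depth, rep(0L, 300))
  # one 100 bp read fully inside
  cov1 <- md_coverage(make_reads(51, 150), region)
  expect_equal(sum(cov1$depth), 100L)
  expect_equal(unique(cov1$depth[51:150]), 1L)
  expect_equal(sum(cov1$depth[-(51:150)]), 0L)
  # 7 overlapping reads vs brute force
  reads <- make_reads(c(1, 20, 90, 101, 140, 150, 290),
                      c(100, 119, 189, 200, 239, 249, 389))
  cov <- md_coverage(reads, region)
  expect_equal(cov$depth, as.integer(oracle_coverage(reads, region)))
  # depth sums to aligned bases falling inside the window
  expect_equal(sum(cov$depth),
               sum(pmin(reads$end, 300) - pmax(reads$start, 1) + 1))
})

test_that("bin counting matches the read-by-bin overlap oracle", {
  bins <- md_intervals("c1", c(1, 101, 301), c(100, 300, 400))
  # empty alignments
  c0 <- md_bin_counts(list(s1 = make_reads(integer(), integer())), bins)
  expect_equal(c0$s1, c(0L, 0L, 0L))
  # a boundary-spanning read contributes to both bins
  c1 <- md_bin_counts(list(s1 = make_reads(95, 120)), bins)
  expect_equal(c1$s1, c(1L, 1L, 0L))
  # 160 contained reads
  c2 <- md_bin_counts(list(s1 = make_reads(rep(110, 160), rep(209, 160))),
                      bins)
  expect_equal(c2$s1, c(0L, 160L, 0L))
  # random fixture vs oracle, overlap and midpoint modes
  withr::with_seed(7, {
    reads <- make_reads(sample(1:380, 500, TRUE), integer(500))
    reads$end <- reads$start + sample(20:120, 500, TRUE)
  })
  expect_equal(md_bin_counts(list(s = reads), bins)$s,
               as.integer(oracle_bin_counts(reads, bins)))
  mid <- (reads$start + reads$end) %/% 2L
  expect_equal(md_bin_counts(list(s = reads), bins, mode = "midpoint")$s,
               as.integer(oracle_bin_counts(
                 make_reads(mid, mid), bins)))
  # overlapping bins violate the partition contract
  expect_error(md_bin_counts(list(s = reads),
                             md_intervals("c1", c(1, 50), c(100, 150))),
               "overlap")
})

test_that("GC content counts G+C over non-N bases", {
  ref <- Biostrings::DNAStringSet(c(c1 = "GGCCATATACGTNNNNN"))
  expect_equal(md_gc_content(md_intervals("c1", 1, 4), ref)$gc, 1.0)
  expect_equal(md_gc_content(md_intervals("c1", 5, 8), ref)$gc, 0.0)
  expect_equal(md_gc_content(md_intervals("c1", 9, 13), ref)$gc, 0.5)
  expect_true(is.na(md_gc_content(md_intervals("c1", 14, 17), ref)$gc))
  expect_error(md_gc_content(md_intervals("c9", 1, 4), ref), "absent")
})

test_that("mappability is a length-weighted mean with absent bases as 0", {
  bin <- md_intervals("c1", 101, 200)
  expect_equal(md_mappability(bin, NULL)$mappability, 1.0)
  full <- tibble::tibble(chrom = "c1", start = 1, end = 500, value = 1)
  expect_equal(md_mappability(bin, full)$mappability, 1.0)
  half <- tibble::tibble(chrom = "c1", start = 101, end = 150, value = 1)
  expect_equal(md_mappability(bin, half)$mappability, 0.5)
  away <- tibble::tibble(chrom = "c1", start = 300, end = 400, value = 1)
  expect_equal(md_mappability(bin, away)$mappability, 0.0)
  mixed <- tibble::tibble(chrom = "c1", start = c(101, 151),
                          end = c(150, 200), value = c(0.4, 0.8))
  expect_equal(md_mappability(bin, mixed)$mappability, 0.6)
})

test_that("BAM round trip preserves read spans and filters apply", {
  reads <- make_reads(c(10, 50, 200, 500), c(109, 149, 299, 599))
  bam <- write_bam_fixture(reads, "roundtrip", chrom_lengths = c(c1 = 1000))
  back <- md_read_alignments(bam)
  expect_equal(back[, c("chrom", "start", "end")][order(back$start), ],
               reads[order(reads$start), ])
  # restricted import: reads 10-109 and 50-149 both overlap 40-60
  sub <- md_read_alignments(bam, region = md_intervals("c1", 40, 60))
  expect_equal(nrow(sub), 2L)
  # unknown chromosome warns and returns empty
  expect_warning(none <- md_read_alignments(bam,
                                            region = md_intervals("zz", 1, 5)),
                 "absent")
  expect_equal(nrow(none), 0L)
  # missing index is a hard error naming the file
  dir <- file.path(tempdir(), "bam-fixtures")
  noidx <- file.path(dir, "unindexed.bam")
  file.copy(bam, noidx)
  expect_error(md_read_alignments(noidx), "unindexed.bam")
})

test_that("bedGraph mappability tracks are read and averaged", {
  track <- md_read_bedgraph(system.file("extdata",
                                        "example_mappability.bedGraph",
                                        package = "mdtrio"))
  expect_equal(track$value, c(1, 0.8, 0.5, 1))
  expect_equal(track$start[1], 10000L)  # bedGraph is 0-based half-open
  bins <- md_intervals("sim1", 19001L, 21000L)
  expect_equal(md_mappability(bins, track)$mappability, 0.65)
})
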