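# Independent brute-force oracles used to check the optimized paths.

# per-base depth by interval stabbing over all reads
oracle_coverage <- function(reads, region) {
  vapply(seq(region$start, region$end), function(p) {
    sum(reads$chrom == region$chrom & reads$start <= p & reads$end >= p)
  }, numeric(1))
}

# read x bin overlap test, one read at a time
oracle_bin_counts <- function(reads, bins) {
  vapply(seq_len(nrow(bins)), function(b) {
    sum(reads$chrom == bins$chrom[b] &
          reads$start <= bins$end[b] & reads$end >= bins$start[b])
  }, numeric(1))
}

# exhaustive scan over all admissible circular arc boundaries (canonical
# form: b0 > 0, so a plain two-piece split appears once, as (cut, n])
oracle_cbs_scan <- function(x, min_width) {
  n <- length(x)
  s <- stats::sd(x)
  best <- list(t = 0, b0 = -1L, b1 = -1L)
  if (is.na(s) || s == 0) return(best)
  S <- c(0, cumsum(x))
  total <- S[n + 1]
  for (b0 in seq(min_width, n - min_width)) {
    for (b1 in seq(b0 + min_width, n)) {
      right <- n - b1
      if (right != 0 && right < min_width) next
      k <- b1 - b0
      m <- n - k
      arc <- S[b1 + 1] - S[b0 + 1]
      t <- abs(arc / k - (total - arc) / m) / (s * sqrt(1 / k + 1 / m))
      if (t > best$t) best <- list(t = t, b0 = b0, b1 = b1)
    }
  }
  best
}

# per-base coverage-fraction of a truth interval by a set of call intervals
oracle_covered_fraction <- function(ts, te, cs, ce) {
  if (length(cs) == 0) return(0)
  covered <- vapply(ts:te, function(p) any(cs <= p & ce >= p), logical(1))
  mean(covered)
}

# lower median (even n: the smaller central order statistic)
lower_median <- function(x) sort(x)[floor((length(x) + 1) / 2)]

# cumulative-median partition of a proto-region, one base at a time
oracle_partition <- function(region, reads_by_sample, target) {
  counts_at <- function(s, p) {
    vapply(reads_by_sample, function(r) {
      sum(r$chrom == region$chrom & r$start <= p & r$end >= s)
    }, numeric(1))
  }
  bounds <- integer(0)
  s <- region$start
  p <- region$start
  while (p <= region$end) {
    if (lower_median(counts_at(s, p)) >= target) {
      bounds <- c(bounds, p)
      s <- p + 1L
    }
    p <- p + 1L
  }
  if (length(bounds) == 0) {
    return(tibble::tibble(chrom = region$chrom, start = region$start,
                          end = region$end))
  }
  bounds[length(bounds)] <- region$end  # remainder merges into last bin
  tibble::tibble(chrom = region$chrom,
                 start = c(region$start, head(bounds, -1) + 1L),
                 end = bounds)
}

make_reads <- function(start, end, chrom = "c1", sample_id = NULL) {
  r <- tibble::tibble(chrom = chrom, start = as.integer(start),
                      end = as.integer(end))
  if (!is.null(sample_id)) r$sample_id <- sample_id
  r
}
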