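---
title: "Calling de novo deletions in trios from targeted capture sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling de novo deletions in trios from targeted capture sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mdtrio)
```

## The problem

A de novo copy-number deletion is a loss present in a child but in neither
parent.  On capture-based targeted sequencing (TS) the only broadly usable
signal is read depth, and read depth on capture platforms is shaped far
more by probe design and capture efficiency than by copy number: coverage
varies by an order of magnitude between and within targeted regions.
Calling each family member separately and intersecting the calls wastes
the key structure of the design — most technical artifacts are *shared*
within a trio, and a post-hoc comparison of three noisy call sets
multiplies their false positives instead of cancelling their noise.

`mdtrio` implements a trio-aware read-depth caller around three ideas:

1. **Coverage-adaptive bins.**  Bins are not fixed-width windows or probe
   coordinates; they are sized so that the *median read count* across a
   subsample of study samples reaches a fixed target (160 reads by
   default).  Dense capture gives narrow bins (high resolution), sparse
   capture gives wide bins (stable counts).  Under a Poisson model a
   copy-neutral bin with mean $c$ and a heterozygous deletion with mean
   $c/2$ are separated by $(c - c/2)/\sqrt{c}$ copy-neutral SDs —
   `md_separation_sd(160)` $\approx 6.3 > 6$, which is the rationale for
   the default target.

2. **M scores.**  Raw bin-by-sample counts are transformed
   $\log_2(\mathrm{count}+1)$, centred by sample (column) medians then bin
   (row) medians — one pass each, in that order — and adjusted for bin GC
   and mappability by sequential loess fits.  The resulting M score is a
   relative copy-number measure: $\approx 0$ when copy-neutral,
   $\approx -1$ for a single-copy deletion (because halving a large count
   shifts its log2 by one).

3. **The minimum distance.**  For each trio and bin, with offspring,
   father and mother scores $M_O, M_F, M_M$:
   $$\delta_F = M_O - M_F,\qquad \delta_M = M_O - M_M,\qquad
     d = \operatorname*{arg\,min}_{\delta\in\{\delta_F,\delta_M\}} |\delta|.$$
   An inherited deletion appears in the offspring *and* one parent, so one
   of the deltas is $\approx 0$ and $d$ cancels; only events private to
   the offspring push $d$ towards $-1$.  $d$ also cancels bin-level
   technical effects shared within the trio.

The $d$ track of each trio is segmented per targeted region by circular
binary segmentation (CBS) with permutation p-values; segments whose mean
is within 0.3 of $-1$ become candidates, and candidates survive only if
more than half of their bins are free of a population-variability flag
(bins where more than 5% of all samples fall outside $[-0.5, 0.5]$ —
copy-number polymorphisms and normalization failures).  A lightweight
read-pair inspector (`md_read_pair_evidence()`) can then count aberrantly
spaced pairs spanning a call — the "Z-shaped" discordant-pair signature
that corroborates a real deletion.

## Pipeline and parameters

`md_run_pipeline()` chains the stages; each has its own configuration
object with these defaults:

| stage | parameter | default | meaning |
|---|---|---|---|
| binning | `n_subsample` | 25 | samples used to define bins |
| binning | `proto_min_depth` | 10× | per-base depth defining proto-regions (bases where *any* subsampled sample reaches it) |
| binning | `min_median_reads` | 160 | per-bin median read target; controls resolution vs stability |
| binning | `min_mappability` | 0.75 | bin QC floor |
| binning | `gc_range` | [0.15, 0.85] | closed bin QC range |
| normalization | `span` | 0.75 | loess span for GC and mappability fits |
| family QC | lag-10 autocorrelation | ≤ 0.4 | excludes families with structured $d$ tracks |
| family QC | variance of $d$ | ≤ 0.05 | excludes noisy families |
| CBS | `alpha` | 0.001 | permutation significance per split |
| CBS | `min_width` | 3 bins | minimum bins per segment |
| CBS | `undo_sd` | 4 | merge adjacent segments closer than this many robust SDs |
| CBS | `n_permutations` | 10 000 | with early stopping once significance is unreachable |
| CBS | `seed` | 137 | fixed so reruns are identical |
| calling | `md_tolerance` | 0.3 | candidate window $[-1.3, -0.7]$, closed |
| calling | `variability_sample_fraction` | 0.05 | strict ">5% of samples outside $[-0.5, 0.5]$" flag |
| calling | `min_unflagged_fraction` | 0.5 | strict ">half the bins unflagged" reporting rule |

## Interpretation choices the contract left open

Several details are not pinned down by the method's published description;
the package fixes them as follows and treats them as part of its contract:

* **Read counting** ("reads overlapping the bins"): each retained read
  (MAPQ ≥ 1, primary, non-duplicate — all configurable) counts once in
  every bin it overlaps by ≥ 1 bp; mates count independently.  A
  midpoint-assignment mode exists but is not the default.
* **Coordinates** are 1-based fully closed internally (so the printed
  sizes of reported deletions equal `end - start + 1`); BED I/O converts
  to 0-based half-open and back losslessly.
* **Partition remainders**: trailing bases of a proto-region that never
  reach the read target merge into the last closed bin; a proto-region
  that never reaches it at all is kept as a single bin and left to QC.
  The median over the subsample is the *lower* median for even counts.
* **Median centering** is a single column-then-row pass, not an iterated
  Tukey polish — "in that order" reads as one pass.
* **Loess adjustment** is sequential (GC first, then mappability), degree
  2, span 0.75.  A covariate that is constant across bins (e.g. the
  default all-1 mappability track when none is supplied) carries no trend
  and is skipped.  Loess smoothing is linear but *not* a projection, so a
  second adjustment pass moves scores by a small non-zero amount; the
  tests assert near-idempotence (second pass ≪ first pass, < 0.02)
  rather than exact idempotence, which no genuine loess can satisfy.
* **Eq-style tie-breaking**: when $|\delta_F| = |\delta_M|$ exactly, $d$
  takes the father term — deterministic and role-stable.
* **Family QC** statistics are computed on the full concatenated track in
  genomic order, before any variability-flag masking; the biased sample
  autocorrelation estimator is used, with the autocorrelation of a
  constant track defined as 0.
* **CBS** is implemented natively (max circular two-sample t statistic,
  within-segment permutations, SD-undo).  Candidate splits are enumerated
  canonically with the left boundary strictly inside the segment, so a
  plain two-piece split appears exactly once; every resulting piece must
  hold at least `min_width` bins.  The permutation loop stops early as
  soon as the exceedance count makes `p <= alpha` impossible, which
  changes nothing about the accept/reject decision.  The SD for sd-undo
  is `mad(diff(x))/sqrt(2)` — robust to the change points being tested.
  No Gaussian tail approximation is used; `alpha` applies to the
  empirical permutation p-value, so numerical equality with other CBS
  implementations is not promised, only contract-level behavior.
* **Suppressed candidates** (those failing the majority-unflagged rule)
  are retained in the output with `status = "suppressed"` for audit.

## The synthetic-data generator

All testing and benchmarking run on synthetic cohorts from
`md_capture_profile()` / `md_simulate_cohort()`.  The generator emulates:

* 13 targeted regions of 15 kb on one synthetic chromosome (a 195 kb
  footprint, echoing a multi-region targeted design), with per-region
  capture intensity drawn log-normally (sdlog 0.3) — capture
  heterogeneity;
* 100 bp paired-end reads from fragments $\sim N(400, 60^2)$ bp (a
  300–500 bp size selection), placed by a Poisson process at 0.33
  fragments/base, i.e. ≈ 66× median coverage, the regime in which
  160-read bins come out ≈ 100–250 bp wide;
* per-sample depth scales drawn log-normally (sdlog 0.15), mimicking
  inter-sample library-size variation;
* a reference sequence whose GC propensity oscillates smoothly between
  ≈ 0.35 and 0.65, giving bins a realistic GC spread for the loess stage.

It does **not** emulate sequencing errors, split reads, mapping artifacts,
GC-dependent capture bias (GC varies but does not bias coverage), batch
effects, or real CNP architecture.  Passing benchmarks therefore show the
statistical machinery behaves as designed under capture-like depth
heterogeneity and Poisson counting noise — not that real-cohort
performance is reproduced.

Deletions are spiked exactly as the benchmark design prescribes: every
read overlapping the deletion interval is dropped independently with
probability 0.5 (proband only for de novo; proband plus one random parent
for inherited), which halves expected depth — a heterozygous loss.

### Scaled benchmark design

The published experiment resamples one trio at a time (1000 iterations)
against a real, unspiked cohort; that is not desk-reproducible.  The
scaled surrogate (`md_run_benchmark()`) runs 5 replicate cohorts of 50
trios.  Two scaling decisions matter:

* **Spike layout.**  If every trio carried the full 10-deletion layout,
  the 150-sample cohort would have ~10–16% of samples deleted at many
  bins, tripping the 5% variability flag — an artifact of the small
  cohort, not of the method.  The default `"rotating"` layout gives each
  trio one de novo and one inherited spike (sizes rotating so each size
  gets 10 trios per replicate, 50 events per size over the run), keeping
  per-bin carrier fractions ≈ 2%.  The full layout remains available
  (`layout = "full"`).
* **Footprint and family QC.**  On the real design (~25 000 bins) one
  deletion is invisible in a family's track-level summary statistics.  On
  a scaled footprint it is not: with ~1700 bins, a 4 kb deletion (~35
  bins at $-1$) alone pushes the carrier family's lag-10 autocorrelation
  toward the 0.4 exclusion threshold.  The 195 kb footprint was chosen so
  this censoring is negligible up to 2 kb; at 4 kb a fraction of carrier
  families still self-exclude, which *lowers the unconditional 4 kb
  sensitivity* at this scale.  The benchmark therefore records
  `family_passed_qc` per truth record; detection conditional on passing
  QC is monotone in spike size, as expected.  The QC thresholds
  themselves are part of the method and are not rescaled.

Problem sizes throughout (50 trios × 5 replicates, 195 kb footprint,
66× coverage; 12-trio end-to-end fixtures in the unit tests) were chosen
as the smallest cohorts at which the 5%-variability flag, the family QC
and binomial counting at 50 events per size remain meaningful.

## Numerical and degenerate-input behavior

* Zero-variance segments have statistic 0 and never split; `sd_undo` with
  a zero robust SD merges only exactly-equal means.
* Bins with all-N sequence have undefined GC and fail QC; chromosomes
  absent from a BAM header yield an empty, warned import rather than an
  error; missing BAM indexes are hard errors naming the file.
* Fewer than 10 bins: the loess adjustment is skipped with a warning.
  Fewer than 20 samples: the variability flag warns that 5% of samples is
  a poor estimate.  Fewer than 11 bins in a trio track: family QC fails
  with reason `too_few_bins`.
* All randomness flows through explicit seeds (subsampling, simulation,
  CBS permutations — the CBS default seed is 137); reruns are
  byte-identical, which the tests verify by hashing written outputs.

## Known limitations

* Deletions spanning ≤ 2 bins are structurally hard to call
  (`min_width = 3`); the benchmark's 250 bp sensitivity is accordingly
  low, as expected for read-depth methods.
* Only autosomal, heterozygous de novo *deletions* are in scope — no
  duplications, no sex chromosomes, no genotyping of CNPs.
* The variability flag needs a cohort; with tens of samples the 5% rule
  is coarse, and single-family use is unsupported.
* The read-pair inspector is heuristic corroboration, not a breakpoint
  refiner; split-read realignment is out of scope.
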