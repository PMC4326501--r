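---
title: "Detecting A-to-I miRNA editing and ADAR-dependent expression changes: methods"
author: "editkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting A-to-I miRNA editing and ADAR-dependent expression changes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editkit)
```

## The problem

ADAR enzymes deaminate adenosine to inosine in double-stranded RNA,
including miRNA precursors. Reverse transcription and sequencing read
inosine as guanosine, so an edited position appears as an A-to-G mismatch
between small-RNA reads and the mature miRNA reference. Two questions
drive the analysis: *which mature-miRNA positions are edited* (beyond what
sequencing error can explain), and *which miRNAs change expression* when
ADAR2 activity is modulated (active enzyme vs a catalytically dead mutant
vs enzyme knock-down) — a question of practical interest in glioblastoma,
where ADAR2 activity is impaired and onco-miRs such as miR-21, miR-221
and miR-222 are over-expressed.

`editkit` implements both halves as a desk-scale, fully testable pipeline,
plus the small auxiliary statistics used around such a study (array probe
selection, 2^-ddCt relative quantification, Sanger peak-ratio editing
levels) and a synthetic-data generator with known truth.

## Read cleaning

Four rules, applied in this order by `preprocess_reads()`:

1. **Quality gate** — a read is dropped when *more than* 3 positions have
   phred below 20. Both bounds are deliberately strict inequalities:
   exactly three sub-threshold positions pass, and a base at phred
   exactly 20 is not low-quality.
2. **Adaptor removal** — the longest read suffix matching a prefix of the
   3' adaptor is removed (minimum overlap 8 nt, at most one mismatch per
   8 nt of overlap; a 5' adaptor is handled symmetrically). Reads without
   a detectable adaptor are kept but flagged; at a fixed machine length
   they almost always exceed the insert gate and fall out there. The
   matching rule is deterministic; no published trimmer is being
   emulated.
3. **Insert length gate** — keep 15-28 nt inclusive, applied to the
   *post-adaptor* length (the stated removal conditions, "shorter than
   15" / "longer than 28", are strict).
4. **3' trim** — the final two bases are removed: the 3' end of mature
   small-RNA reads carries non-templated additions and other
   modifications, so those base calls are untrustworthy for editing
   inference.

## Alignment and tallies

Cleaned reads are aligned to a mature-miRNA FASTA (not to a genome: at
desk scale the per-miRNA position space is identical, and the references
are strand-resolved, so only the sense strand is searched). The policy is
ungapped, at most one mismatch, and a mismatch is only accepted when the
read base has phred >= 30; 5' start offsets of 0-3 nt tolerate isomiR
wobble. The hit with fewest mismatches wins; equally good hits at
distinct (reference, offset) positions make the read *ambiguous*, and
ambiguous reads are excluded from both tallies and expression counts to
avoid double counting.

`tally_alignments()` accumulates per-position A/C/G/T counts from
uniquely aligned reads, counting **only bases with phred >= 30** — not
just mismatch bases. This is the conservative reading of the phred-30
mismatch rule: the binomial null below assumes a 0.1% error rate *given*
phred-30 filtering, so the denominator of every test must be restricted
to the same base population. Whether sub-phred-30 bases should count
toward coverage when quoting editing percentages is genuinely
underdetermined; this choice keeps the test and its null coherent, and it
is applied uniformly.

## The editing caller

At every reference position, each alternate base with a nonzero count is
tested with the upper-tail binomial `P(X >= n_alt)`,
`X ~ Binomial(coverage, 0.001)` (`binomial_site_pvalue()`, computed via
the survival function, exact and stable to coverage of 10^7). The test is
one-sided because editing can only inflate a mismatch count above the
error null, and the full 0.1% error rate is charged to each alternate
base separately, which is conservative. Bonferroni correction is applied
over all (position x alternate base) tests performed in the sample
(BH and uncorrected are available), and a site is *significant* at
adjusted p < 0.05.

Reporting rules:

* **ND** — any site with coverage below 10 reads is "not determined",
  regardless of p-value, and reports no level.
* **Editing level** — `100 * n_alt / (n_ref + n_alt)`. Third bases are
  excluded from the denominator so the sequencing estimate is directly
  comparable with the Sanger definition (G peak area over A+G peak
  areas).
* **Seed region** — mature positions 2-8 (configurable; the seed is
  invoked in this field without fixed published bounds, and 2-8 is the
  common convention).

`compare_conditions()` lines calls up across samples and flags sites
significant in the active-enzyme sample but not in the dead-enzyme
control; `context_profile()` summarizes the -1/+1 reference neighbours of
significant A-to-G calls (genuine A-to-I sites tend to show upstream U
and downstream G). `amplicon_editing()` reuses the caller on precursor
coordinates and labels sites relative to a user-supplied anchor, the
anchor base being +1 and the base before it -1, with no position zero.
The base *opposing* a site in the precursor stem is not computed — that
would require secondary-structure prediction, which is out of scope.

## Expression

Counts of uniquely aligned reads per miRNA are normalized with the
trimmed mean of M-values (`tmm_normalize()`, backed by edgeR): gene-wise
log2 ratios to a reference sample are trimmed (30% of M-values, 5% of
A-values), precision-weighted and averaged; the reference sample is the
one whose upper quartile is closest to the across-sample mean. The
reported per-sample scale factor is library size x TMM factor rescaled to
geometric mean one, so normalizing an already-normalized table returns
factors of one.

`differential_table()` contrasts two samples per miRNA:

* **Fold-change** `log2[(A + 1)/(B + 1)]` — the pseudocount keeps zero
  counts finite.
* **Exact Poisson test** — conditional on `n = a + b`, `a` is binomial
  with probability `lib_a / (lib_a + lib_b)` under equal per-library
  rates; two-sided by minimum-likelihood summation (`binom.test`). For a
  TMM-normalized table the libraries are treated as equal — that is what
  normalization means — while raw tables condition on column totals.
  Conditioning normalized counts on raw totals would bias every null
  gene whenever the planted or real changes are asymmetric in total
  mass. Normalized counts are rounded per sample before the test.
* **Bonferroni** over the miRNAs with a nonzero summed count in the
  contrast (whether the original analysis divided by all catalogued or
  only expressed miRNAs is unstated; expressed-only is the less
  conservative but better-defined choice).
* **Filters** — summed counts strictly greater than 200; |log2 ratio| of
  at least 0.5 (inclusive); the *highly expressed* subset takes summed
  counts >= 10,000 (inclusive, per the published legend's ">=").
  `reversal_filter()` keeps selected miRNAs whose second-contrast ratio
  has the strictly opposite sign, with no magnitude threshold on the
  second contrast.

## Auxiliary statistics

* `array_select()` — one-sample two-sided t-test of each probe's
  replicate log2 ratios against zero (the standard reading of "t-test"
  for ratio arrays), BH across probes, selection at q <= 0.2 and
  |mean log2| >= 0.5 (inclusive, following the "at least +/-0.5"
  phrasing). Array normalization is upstream and out of scope; the
  module consumes normalized log ratios.
* `ddct_fold()` — dCt = target - endogenous control per sample, ddCt
  subtracts the calibrator, fold = 2^-ddCt; the calibrator maps to 1.
* `sanger_editing_level()` — 100 x G/(A+G) peak areas; scale-invariant.

## The synthetic generator

`simulate_reads()` emulates exactly the data features the pipeline's
rules exist for: mature-sequence reads with per-site A-to-G flips at
planted fractions (independent across reads, matching the per-site
binomial model — no molecule-level linkage), uniform per-base
substitution error (default 0.001, the rate the null assumes; uniformity
over the three alternates is the simplest consistent choice), a 2-base
random non-templated 3' tail with probability 0.5 (the trimming rule's
*raison d'etre*; the real tail process is irrelevant because those bases
are discarded), the 3' adaptor, truncation at a 36 nt machine length, and
a three-component quality mixture (2% phred 10-19, 8% phred 25-29, 90%
phred 33-40) so that both the phred-20 read gate and the phred-30 tally
gate are exercised and mismatches occur on both sides of the phred-30
bar. Per-miRNA read counts are Poisson; abundances across miRNAs are
log-normal (published count tables span zero to about 1.5 million reads,
which log-normal covers). `simulate_tally()` draws the per-position base
composition directly — the fast path for caller-level simulations — and
`simulate_count_tables()` plants log2 fold-changes in a labelled subset
with Poisson observation noise.

What the generator does **not** model: PCR duplicates, ligation bias,
indels, quality-by-cycle structure, multi-mapping families of paralogous
miRNAs, SNP/editing confusion, or genome-scale alignment ambiguity.
Passing tests therefore demonstrate the statistical machinery is
correct under its stated model, not that real libraries meet that model.

All generators are pure functions of their parameters and a seed, and
restore the caller's RNG state.

## Numerical choices

* p-values via survival functions in stable tail form; the exact
  conditional test can underflow to subnormal doubles (< ~1e-308) for
  extreme splits, where relative comparisons are quantization noise —
  verification compares absolutely there.
* Ambiguity tie-break: equally good hits never pick a winner, they
  discard the read.
* All internal coordinates are 1-based closed (the R/Bioconductor
  convention); reports are likewise 1-based from the 5' end.
* Boundary semantics are fixed and unit-tested: quality "more than
  three" = drop at 4; length 15 and 28 kept; ND strictly below 10 reads;
  sum filter strictly above 200; effect and high-expression bounds
  inclusive.
* Count-table cells accept thousands separators so published tables can
  be pasted verbatim.

## Validation design and problem sizes

Every statistical operation is tested against an independent brute-force
oracle (direct pmf summation for both exact tests, a hand-rolled BH
step-up, an exhaustive Hamming-distance alignment scan, a brute-force
adaptor overlap scan) and against construction truths from the
generator. The standard suite and the acceptance checks use: 100 seeded
null-tally simulations of 200 miRNAs at coverage 1,000; level recovery
at coverage 2,000 for planted levels of 1/5/20/70% over 100 seeds; 1,000
random cases for each oracle-equivalence check; 500-gene tables for TMM
recovery (a 3x-scaled library, then 5% of genes perturbed 4-fold); and
an end-to-end run of 20 synthetic miRNAs at expected coverage 800 with
four planted sites spanning 5-70%. These sizes give the binomial checks
comfortable power while keeping the whole suite inside a coffee break.

One published-table check deserves a note: of the 32 printed log2 ratios
in the bundled 16-row fixture, 29 follow exactly (to 4 decimal places)
from the printed counts, and three cells in the knock-down contrast do
not (hsa-miR-21, hsa-miR-30a*, hsa-miR-548s). The validation reports
those as mismatches rather than correcting or skipping them; the
recomputed values are the internally consistent ones.

The array-selection power property is stated for probes at |log2| = 1
with replicate noise SD 0.2: with only three replicates a df-2 t-test
cannot reach 80% recall at FDR 0.2 (simulated recall is about 66%), so
the property test uses four replicates, where recall is essentially
complete. This is a fact about the t distribution, not about the
implementation.

## Limitations

* Alignment is to a provided mature/precursor reference; genome-scale
  multi-mapping and cross-mapping between paralogues are not modelled,
  and antisense hits are not searched.
* Editing calls cannot distinguish A-to-I editing from A/G SNPs without
  external genotype information.
* The exact Poisson test ignores biological replication and
  overdispersion; it answers "is this difference larger than counting
  noise", not "is it reproducible across subjects". Negative-binomial
  modelling is deliberately out of scope.
* The TMM variant used by the original analysis is not specified beyond
  its family; standard TMM with configurable trims is implemented and
  documented as this package's interpretation.
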