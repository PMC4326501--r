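# editkit

Detection of A-to-I editing in mature microRNAs from small-RNA
sequencing, and of ADAR-dependent miRNA expression changes — as a
desk-scale, fully tested R pipeline.

## The problem

ADAR enzymes convert adenosine (A) to inosine (I) in double-stranded
RNA, including miRNA precursors. Inosine base-pairs like guanosine, so
an edited site surfaces in cDNA and sequencing data as an A→G mismatch
against the miRNA reference. Profiling *which* mature-miRNA positions
are edited, and *which* miRNAs change abundance when ADAR2 activity is
rescued or silenced, is central to understanding miRNA dysregulation in
glioblastoma, where ADAR2 activity is impaired and onco-miRs (miR-21,
miR-221, miR-222) run high.

`editkit` is for analysts who want that computation reproducible and
testable end to end: read cleaning, reference alignment, per-position
base tallies, a binomial editing caller, TMM-normalized exact Poisson
differential expression, the surrounding selection filters, and the
small auxiliary statistics of such a study (microarray probe selection,
2^−ΔΔCt qPCR quantification, Sanger peak-ratio editing). A
synthetic-data module generates reads, tallies and count tables with
planted truth, so every stage is verifiable without any sequencing
deposit.

## The statistics at the core

**Editing caller.** After quality filtering (drop a read when more than
3 positions have phred < 20), 3′-adaptor removal, a 15–28 nt insert
gate and trimming of the last two 3′ bases, reads are aligned to the
mature-miRNA reference allowing ≤ 1 mismatch with phred ≥ 30. For every
reference position and alternate base, with n quality-passing bases of
which k are the alternate:

    p = P(X ≥ k),  X ~ Binomial(n, 0.001)

i.e. an upper-tail test against the 0.1% sequencing-error null, with
Bonferroni correction over all (position × alternate base) tests in the
sample. Sites with coverage < 10 are reported **ND** (not determined);
the editing level is `100 · k / (n_ref + k)`, matching the Sanger
definition G/(A+G).

**Expression.** Per-miRNA counts of uniquely aligned reads are
normalized by the trimmed mean of M-values (TMM); two conditions are
contrasted per miRNA with the exact conditional test of equal Poisson
rates (given `n = a + b`, `a ~ Binomial(n, λ_a/(λ_a+λ_b))` under the
null; two-sided by minimum likelihood), Bonferroni-corrected, with
fold-changes `log2[(A+1)/(B+1)]` and the selection filters: summed
counts > 200, |log2 ratio| ≥ 0.5, a highly expressed subset at
summed counts ≥ 10,000, and an expression-trend reversal filter across
a second contrast.

## Worked example

Plant editing at known sites in a synthetic reference, sequence it,
and run the pipeline stages:

```r
library(editkit)

refs <- make_reference(10, c(20, 24), rng_seed = 100)
a_pos <- vapply(refs$sequence,
                function(s) which(strsplit(s, "")[[1]] == "A")[1],
                integer(1))
editing <- data.frame(id = refs$id[1:3], position = a_pos[1:3],
                      fraction = c(0.40, 0.25, 0.10))

reads <- simulate_reads(refs, abundance = 500, editing = editing,
                        rng_seed = 101)
pp    <- preprocess_reads(reads, DEFAULT_ADAPTOR3)
pp$stats
#>           input dropped_quality  dropped_length      no_adaptor        retained
#>            4997              25               0               0            4972

aln   <- align_reads(pp$reads, refs)
tl    <- tally_alignments(aln, pp$reads, refs)
calls <- call_sites(tl, refs)
calls
#> Editing-site calls: 80 tested (position x alt base), 3 significant, 0 ND
#> Significant A-to-G sites:
#>        ref_id position editing_level     p_adj in_seed
#>  syn-mir-0001        6          37.1  0.00e+00    TRUE
#>  syn-mir-0002        3          26.8 8.38e-231    TRUE
#>  syn-mir-0003        3          10.7  1.32e-79    TRUE
```

Of 4,997 simulated reads, 25 fail the quality gate and none fail the
length gate (every read carries its adaptor). The caller recovers
exactly the three planted sites — estimated levels 37.1%, 26.8% and
10.7% against planted fractions 40%, 25% and 10%, each within binomial
counting noise at ~500× coverage — and nothing else: the ~77 other
tested (position, alternate-base) pairs are error-driven and stay below
significance after Bonferroni.

The building blocks are ordinary functions:

```r
binomial_site_pvalue(5, 1000, 0.001)   # 0.003636878
fold_change(5296, 14463)               # -1.4492
```

`run_pipeline()` wires the stages over FASTQ inputs and writes tally,
editing, count, differential-expression and comparison TSVs plus a run
manifest; `inst/scripts/editkit.R` exposes the same stages as shell
subcommands (`simulate`, `preprocess`, `align`, `call-editing`,
`diffexpr`, `array-select`, `ddct`, `sanger`, `run`,
`validate-table2`).

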