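cfg <- pipeline_config()

two_refs <- mirna_refs(c("mirA", "mirB"),
                       c("TGAGGTAGTAGGTTGTATAGTT",
                        "ACCCGTAGATCCGAACTTGTGA"))

test_that("exact substring reads align with zero mismatches", {
  r <- make_read(substr(two_refs$sequence[1], 1, 20), 40L)
  hit <- align_read(r, two_refs, cfg)
  expect_equal(hit$status, "aligned")
  expect_equal(hit$ref_id, "mirA")
  expect_equal(hit$start, 1L)
  expect_equal(hit$n_mismatch, 0L)

  # 5' isomiR wobble: starting inside the reference still aligns
  r2 <- make_read(substr(two_refs$sequence[1], 3, 22), 40L)
  hit2 <- align_read(r2, two_refs, cfg)
  expect_equal(hit2$status, "aligned")
  expect_equal(hit2$start, 3L)
})

test_that("the one-mismatch / phred-30 policy is enforced", {
  s <- substr(two_refs$sequence[1], 1, 20)
  one_mm <- paste0("C", substr(s, 2, 20))
  expect_false(substr(s, 1, 1) == "C")

  hit <- align_read(make_read(one_mm, 30L), two_refs, cfg)
  expect_equal(hit$status, "aligned")
  expect_equal(hit$n_mismatch, 1L)

  q29 <- rep(40L, 20); q29[1] <- 29L
  expect_equal(align_read(make_read(one_mm, q29), two_refs, cfg)$status,
               "unaligned")

  two_mm <- paste0("CC", substr(s, 3, 20))
  expect_false(substr(s, 2, 2) == "C")
  expect_equal(align_read(make_read(two_mm, 40L), two_refs, cfg)$status,
               "unaligned")
})

test_that("a sequence present in two references is ambiguous", {
  shared <- "TGAGGTAGTAGGTTGTATAGTT"
  refs <- mirna_refs(c("m1", "m2"),
                     c(shared, paste0(shared, "AC")))
  hit <- align_read(make_read(shared, 40L), refs, cfg)
  expect_equal(hit$status, "ambiguous")
  expect_error(align_read(make_read(shared, 40L), refs[0, ], cfg),
               "empty reference")
})

test_that("single-read and batch aligners agree with the exhaustive oracle", {
  set.seed(101)
  refs <- make_reference(12, c(20, 30), rng_seed = 55)
  n_cases <- 1000
  reads <- random_reads(n_cases, len = 22)
  # bias half the cases toward near-matches of a reference
  for (i in seq_len(n_cases %/% 2)) {
    j <- sample(nrow(refs), 1)
    s <- substr(refs$sequence[j], 1, 22)
    if (nchar(s) < 22) s <- refs$sequence[j]
    n_mut <- sample(0:2, 1)
    for (k in seq_len(n_mut)) {
      p <- sample(nchar(s), 1)
      substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    reads$seq[i] <- s
  }
  # mixed qualities so the phred-30 rule is exercised
  reads$qual <- vapply(nchar(reads$seq), function(L)
    phred_encode(sample(c(25L, 29L, 30L, 40L), L, replace = TRUE)),
    character(1))

  batch <- align_reads(reads, refs, cfg)
  for (i in seq_len(n_cases)) {
    expected <- oracle_align(reads$seq[i], phred_decode(reads$qual[i])[[1]],
                             refs)
    expect_equal(batch$status[i], expected$status)
    if (expected$status == "aligned") {
      expect_equal(batch$ref_id[i], expected$ref_id)
      expect_equal(batch$start[i], expected$start)
      expect_equal(batch$n_mismatch[i], expected$n_mismatch)
    }
  }
  # spot-check the single-read entry point against the batch driver
  for (i in sample(n_cases, 25)) {
    single <- align_read(reads[i, ], refs, cfg)
    expect_equal(single$status, batch$status[i])
  }
})

test_that("tallies count only phred-30+ bases and match direct counts", {
  ref <- mirna_refs("m", "AAAAAAAAAAAAAAAAAAAA")
  g_read <- make_read(paste0(strrep("A", 9), "G", strrep("A", 10)), 40L)
  a_read <- make_read(strrep("A", 20), 40L)
  reads <- do.call(rbind, c(replicate(70, g_read, simplify = FALSE),
                            replicate(30, a_read, simplify = FALSE)))
  reads$id <- paste0("r", seq_len(100))
  aln <- align_reads(reads, ref, cfg)
  expect_true(all(aln$status == "aligned"))
  tl <- tally_alignments(aln, reads, ref, cfg)
  expect_equal(unname(tl$m["G", 10]), 70L)
  expect_equal(unname(tl$m["A", 10]), 30L)
  expect_equal(unname(colSums(tl$m)), rep(100L, 20))

  # a base below phred 30 contributes neither counts nor coverage
  lowq <- rep(40L, 20); lowq[10] <- 20L
  reads2 <- rbind(make_read(strrep("A", 20), 40L, id = "hi"),
                  make_read(strrep("A", 20), lowq, id = "lo"))
  tl2 <- tally_alignments(align_reads(reads2, ref, cfg), reads2, ref, cfg)
  expect_equal(unname(tl2$m["A", 10]), 1L)
  expect_equal(unname(tl2$m["A", 11]), 2L)
})

test_that("tallies are order-independent and monomorphic without errors", {
  refs <- make_reference(6, c(20, 24), rng_seed = 9)
  reads <- simulate_reads(refs, abundance = 80, error_rate = 0,
                          rng_seed = 3)
  pp <- preprocess_reads(reads, DEFAULT_ADAPTOR3)
  aln <- align_reads(pp$reads, refs, cfg)
  tl <- tally_alignments(aln, pp$reads, refs, cfg)

  set.seed(1)
  perm <- sample(nrow(aln))
  tl_perm <- tally_alignments(aln[perm, ], pp$reads[perm, ], refs, cfg)
  expect_identical(unclass(tl), unclass(tl_perm))

  # error-free, editing-free reads: every covered position is monomorphic
  for (rid in refs$id) {
    m <- tl[[rid]]
    refb <- strsplit(refs$sequence[refs$id == rid], "")[[1]]
    for (p in seq_along(refb))
      expect_equal(sum(m[rownames(m) != refb[p], p]), 0L)
  }
})

test_that("expression counts track unique alignments only", {
  refs <- two_refs
  no_aln <- align_reads(random_reads(0), refs, cfg)
  expect_equal(unname(expression_counts(no_aln, refs)), c(0L, 0L))

  reads <- rbind(make_read(substr(refs$sequence[1], 1, 20), 40L, "a"),
                 make_read(substr(refs$sequence[2], 1, 20), 40L, "b"),
                 make_read(substr(refs$sequence[1], 1, 20), 40L, "c"))
  aln <- align_reads(reads, refs, cfg)
  cts <- expression_counts(aln, refs)
  expect_equal(unname(cts), c(2L, 1L))

  # exact recovery of per-miRNA truth at error rate 0
  refs6 <- make_reference(6, c(20, 24), rng_seed = 9)
  reads6 <- simulate_reads(refs6, abundance = 60, error_rate = 0,
                           qual_mix = c(0, 0, 1), rng_seed = 13)
  truth <- attr(reads6, "truth")$n_per_ref
  pp <- preprocess_reads(reads6, DEFAULT_ADAPTOR3)
  cts6 <- expression_counts(align_reads(pp$reads, refs6, cfg), refs6)
  expect_equal(unname(cts6), unname(truth[names(cts6)]))
})

test_that("tally TSV round-trips", {
  refs <- make_reference(3, c(20, 22), rng_seed = 2)
  reads <- simulate_reads(refs, abundance = 40, rng_seed = 4)
  pp <- preprocess_reads(reads, DEFAULT_ADAPTOR3)
  aln <- align_reads(pp$reads, refs, cfg)
  tl <- tally_alignments(aln, pp$reads, refs, cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tally(tl, refs, path)
  back <- read_tally(path)
  expect_equal(lapply(unclass(back), unname),
               lapply(unclass(tl), unname))
})
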