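cfg <- pipeline_config()

test_that("binomial site p-value matches direct pmf summation", {
  expect_equal(binomial_site_pvalue(0, 1000, 0.001), 1.0)
  expect_equal(binomial_site_pvalue(0, 0, 0.001), 1.0)

  # frozen from the summation oracle: P(X >= 5), X ~ Bin(1000, 0.001)
  expect_equal(oracle_binom_upper(5, 1000, 0.001), 0.003636879,
               tolerance = 1e-6)
  expect_equal(binomial_site_pvalue(5, 1000, 0.001),
               oracle_binom_upper(5, 1000, 0.001), tolerance = 1e-12)

  p_all <- binomial_site_pvalue(50, 50, 0.001)
  expect_lt(p_all, 1e-100)
  expect_gt(p_all, 0)

  set.seed(5)
  for (i in 1:200) {
    n <- sample(1:10000, 1)
    k <- sample(0:min(n, 50), 1)
    rate <- runif(1, 1e-4, 0.01)
    expect_equal(binomial_site_pvalue(k, n, rate),
                 oracle_binom_upper(k, n, rate),
                 tolerance = 1e-9)
  }
  expect_error(binomial_site_pvalue(5, 3, 0.001), "n_alt")
  expect_error(binomial_site_pvalue(1, 10, 0), "error_rate")
})

test_that("p-values are monotone in the alternate count and error rate", {
  n <- 2000
  p_by_k <- binomial_site_pvalue(0:40, n, 0.001)
  expect_true(all(diff(p_by_k) <= 0))
  rates <- c(1e-4, 5e-4, 1e-3, 5e-3, 1e-2)
  p_by_rate <- vapply(rates, function(r) binomial_site_pvalue(8, n, r),
                      numeric(1))
  expect_true(all(diff(p_by_rate) >= 0))
})

test_that("site calling applies the ND rule, level formula and seed span", {
  ref <- mirna_refs("m", "TTAAATTTTTTTTTTTTTTT")
  m <- matrix(0L, 4, 20, dimnames = list(c("A", "C", "G", "T"), NULL))
  # positions covered at depth 100 with the reference base
  refb <- strsplit(ref$sequence, "")[[1]]
  for (p in 1:20) m[refb[p], p] <- 100L
  # position 3 (an A inside the 2-8 seed): 70 G / 30 A
  m["A", 3] <- 30L; m["G", 3] <- 70L
  # position 5: coverage 9 only, all alt
  m[, 5] <- 0L; m["A", 5] <- 0L; m["G", 5] <- 9L
  tl <- structure(list(m = m), names = "m", class = "position_tally")
  calls <- call_sites(tl, ref, cfg)

  site3 <- calls[calls$position == 3, ]
  expect_equal(site3$editing_level, 70.0)
  expect_equal(site3$status, "significant")
  expect_true(site3$in_seed)
  expect_true(site3$is_AtoG)

  site5 <- calls[calls$position == 5, ]
  expect_equal(site5$status, "ND")
  expect_equal(site5$coverage, 9)

  # coverage exactly at the bound is determined
  m[, 5] <- 0L; m["G", 5] <- 10L
  tl10 <- structure(list(m = m), names = "m", class = "position_tally")
  calls10 <- call_sites(tl10, ref, cfg)
  expect_false(calls10[calls10$position == 5, ]$status == "ND")
})

test_that("editing-level denominator excludes third bases", {
  ref <- mirna_refs("m", strrep("A", 20))
  m <- matrix(0L, 4, 20, dimnames = list(c("A", "C", "G", "T"), NULL))
  m["A", ] <- 100L
  m["A", 4] <- 60L; m["G", 4] <- 30L; m["C", 4] <- 10L
  tl <- structure(list(m = m), names = "m", class = "position_tally")
  calls <- call_sites(tl, ref, cfg)
  g4 <- calls[calls$position == 4 & calls$alt_base == "G", ]
  # 30 / (60 + 30), not 30 / 100
  expect_equal(g4$editing_level, 100 * 30 / 90)
  expect_equal(g4$coverage, 100)
})

test_that("null tallies yield no significant calls under Bonferroni", {
  refs <- make_reference(50, c(20, 24), rng_seed = 21)
  tl <- simulate_tally(refs, coverage = 1000, error_rate = 0.001,
                       rng_seed = 22)
  calls <- call_sites(tl, refs, cfg)
  expect_equal(sum(calls$status == "significant"), 0L)
  # without correction the same tallies produce spurious calls at times;
  # the corrected caller must be strictly more conservative
  raw <- call_sites(tl, refs, cfg, correction = "none")
  expect_gte(sum(raw$p_value < cfg$editing_alpha),
             sum(calls$status == "significant"))
})

test_that("condition comparison flags enzyme-specific sites", {
  refs <- make_reference(8, c(20, 24), rng_seed = 31)
  a_pos <- vapply(refs$sequence, function(s)
    which(strsplit(s, "")[[1]] == "A")[1], integer(1))
  editing <- data.frame(id = refs$id[1:4], position = a_pos[1:4],
                        fraction = c(0.3, 0.2, 0.4, 0.25))
  tl_active <- simulate_tally(refs, 2000, editing, rng_seed = 32)
  tl_dead <- simulate_tally(refs, 2000, NULL, rng_seed = 33)
  calls <- list(active = call_sites(tl_active, refs, cfg),
                dead = call_sites(tl_dead, refs, cfg))
  cmp <- compare_conditions(calls, active = "active", control = "dead")
  planted <- paste(editing$id, editing$position)
  flagged <- paste(cmp$ref_id, cmp$position)[cmp$enzyme_specific]
  expect_setequal(flagged, planted)

  # identical samples give identical per-sample columns
  cmp2 <- compare_conditions(list(x = calls$active, y = calls$active))
  expect_equal(cmp2$level_x, cmp2$level_y)
  expect_error(compare_conditions(calls, active = "nope", control = "dead"),
               "not present")
})

test_that("context profile summarizes flanking bases", {
  ref <- mirna_refs("m", "TTAGTTTTTTTTTTTTTTTT")
  calls <- data.frame(ref_id = "m", position = 3, ref_base = "A",
                      alt_base = "G", status = "significant",
                      is_AtoG = TRUE, editing_level = 50,
                      stringsAsFactors = FALSE)
  prof <- context_profile(calls, ref)
  expect_equal(unname(prof$upstream["T"]), 1)
  expect_equal(unname(prof$downstream["G"]), 1)
  expect_equal(sum(prof$upstream), 1)
  expect_error(context_profile(calls[0, ], ref), "no sites")

  # uniformly planted sites in random sequence: near-uniform profile
  set.seed(77)
  refs <- make_reference(300, c(22, 22), rng_seed = 78)
  pos <- vapply(refs$sequence, function(s) {
    a <- which(strsplit(s, "")[[1]] == "A")
    a <- a[a > 1 & a < 22]
    if (length(a)) sample(rep(a, 2), 1) else NA_integer_
  }, integer(1))
  keep <- !is.na(pos)
  fake <- data.frame(ref_id = refs$id[keep], position = pos[keep],
                     ref_base = "A", alt_base = "G",
                     status = "significant", is_AtoG = TRUE,
                     editing_level = 50, stringsAsFactors = FALSE)
  prof2 <- context_profile(fake, refs)
  expect_true(all(abs(prof2$upstream - 0.25) < 0.12))
  expect_true(all(abs(prof2$downstream - 0.25) < 0.12))
})

test_that("amplicon mode labels sites relative to the anchor", {
  pre <- mirna_refs("pre-mir-x", paste0(strrep("C", 30), "A",
                                        strrep("C", 29), "A",
                                        strrep("C", 19)),
                    kind = "precursor")
  editing <- data.frame(id = "pre-mir-x", position = c(31, 61),
                        fraction = c(0.2, 0.1))
  tl <- simulate_tally(pre, 5000, editing, rng_seed = 41)
  res <- amplicon_editing(tl, pre, anchor = c("pre-mir-x" = 31L))
  sig <- res[res$status == "significant", ]
  expect_equal(sort(sig$anchor_label), sort(c("+1", "+31")))
  # planted 20% site recovered within 2 binomial SD at coverage 5000
  lev <- sig$editing_level[sig$position == 31] / 100
  expect_lt(abs(lev - 0.2), 2 * sqrt(0.2 * 0.8 / 5000))
  # base before the anchor would be -1
  res2 <- amplicon_editing(tl, pre, anchor = c("pre-mir-x" = 62L))
  expect_true("-1" %in% res2$anchor_label[res2$position == 61])
  expect_error(amplicon_editing(tl, pre, anchor = c("pre-mir-x" = 999L)),
               "anchor")
})
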