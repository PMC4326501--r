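# Independent brute-force oracles. These deliberately re-derive each
# quantity by direct enumeration / summation, separate from the package's
# code paths.

# Upper-tail binomial probability by direct pmf summation.
oracle_binom_upper <- function(n_alt, n_total, rate) {
  if (n_alt == 0) return(1)
  sum(dbinom(n_alt:n_total, n_total, rate))
}

# Two-sided equal-rates Poisson p-value by exhaustive pmf summation over
# the conditional binomial; outcomes with probability <= observed are
# summed (1 + 1e-7 relative guard against floating-point ties).
oracle_poisson_two_sided <- function(a, b, lib_a, lib_b) {
  n <- a + b
  if (n == 0) return(1)
  d <- dbinom(0:n, n, lib_a / (lib_a + lib_b))
  sum(d[d <= d[a + 1] * (1 + 1e-7)])
}

# Hand-rolled BH step-up with cumulative-minimum monotonicity.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Exhaustive alignment scan: every reference, every 5' offset 0..3,
# <= max_mm mismatches each with phred >= qmin; fewest mismatches wins,
# ties are ambiguous. Character-vector arithmetic throughout.
oracle_align <- function(seq, phred, refs, max_mm = 1L, qmin = 30L,
                         max_off = 3L) {
  rchars <- strsplit(seq, "")[[1]]
  L <- length(rchars)
  hits <- list()
  for (i in seq_len(nrow(refs))) {
    refchars <- strsplit(refs$sequence[i], "")[[1]]
    if (L > length(refchars)) next
    for (off in 0:min(max_off, length(refchars) - L)) {
      mm <- which(refchars[(off + 1):(off + L)] != rchars)
      if (length(mm) <= max_mm && all(phred[mm] >= qmin))
        hits[[length(hits) + 1]] <- list(ref_id = refs$id[i],
                                         start = off + 1L,
                                         n_mismatch = length(mm))
    }
  }
  if (!length(hits)) return(list(status = "unaligned"))
  nmm <- vapply(hits, `[[`, integer(1), "n_mismatch")
  best <- which(nmm == min(nmm))
  if (length(best) > 1) return(list(status = "ambiguous"))
  c(list(status = "aligned"), hits[[best]])
}

# Brute-force adaptor scan: every cut point, direct character comparison.
oracle_adaptor_cut <- function(seq, adaptor, min_overlap = 8L) {
  len <- nchar(seq)
  for (start in seq_len(max(0, len - min_overlap + 1))) {
    o <- len - start + 1
    if (o > nchar(adaptor)) next
    a <- strsplit(substr(seq, start, len), "")[[1]]
    b <- strsplit(substr(adaptor, 1, o), "")[[1]]
    if (sum(a != b) <= floor(o / 8)) return(start)
  }
  NA_integer_
}

# Random read set helper used by several tests.
random_reads <- function(n, len = 22L, phred = 40L, prefix = "r") {
  seqs <- vapply(seq_len(n), function(.)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
  data.frame(id = if (n) paste0(prefix, seq_len(n)) else character(0),
             seq = seqs,
             qual = rep(strrep(intToUtf8(phred + 33L), len), n),
             stringsAsFactors = FALSE)
}

make_read <- function(seq, phred, id = "r1") {
  if (length(phred) == 1L) phred <- rep(phred, nchar(seq))
  data.frame(id = id, seq = seq, qual = phred_encode(phred),
             stringsAsFactors = FALSE)
}
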