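# Synthetic data with the statistical structure the analysis assumes:
# mature-miRNA references, adaptor-flanked reads with planted A-to-G
# editing fractions and uniform per-base sequencing error, direct
# position tallies, and Poisson-noised count tables with planted
# fold-changes. All generators are pure functions of (parameters, seed).

# Run code under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Default 3' sequencing adaptor used by the generator
#'
#' The standard Illumina small-RNA 3' adaptor sequence.
#' @export
DEFAULT_ADAPTOR3 <- "TGGAATTCTCGGGTGCCAAGG"

#' Generate a synthetic mature-miRNA reference set
#'
#' Random uppercase sequences with at least one adenosine each, ids
#' `syn-mir-0001` onward; deterministic given the seed.
#'
#' @param n_mirnas number of references (>= 1).
#' @param length_range inclusive sequence length range (nt); the lower
#'   bound must reach the 15 nt read-length gate.
#' @param rng_seed integer seed.
#' @return A [mirna_refs] data frame.
#' @export
make_reference <- function(n_mirnas, length_range = c(20, 24), rng_seed = 1L) {
  if (n_mirnas < 1) stop("n_mirnas must be >= 1", call. = FALSE)
  if (length_range[1L] < 15)
    stop("reference length below 15 nt: reads could never pass the length gate",
         call. = FALSE)
  with_seed(rng_seed, {
    rng <- seq(length_range[1L], length_range[2L])
    lens <- rng[sample.int(length(rng), n_mirnas, replace = TRUE)]
    seqs <- vapply(lens, function(L) {
      s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      if (!any(s == "A")) s[sample.int(L, 1L)] <- "A"
      paste(s, collapse = "")
    }, character(1))
    mirna_refs(sprintf("syn-mir-%04d", seq_len(n_mirnas)), seqs)
  })
}

#' Simulate adaptor-flanked small-RNA reads with planted editing
#'
#' Per reference, the read count is Poisson(`abundance * scale`). Each
#' read starts as the mature sequence; every planted site is flipped A->G
#' independently with its editing fraction; uniform per-base substitution
#' error (to one of the three other bases) is applied at `error_rate`; a
#' 2-base random non-templated 3' tail is appended with probability
#' `tail_prob`; the 3' adaptor is appended and the read is reported at a
#' fixed machine length. Base qualities are drawn from a three-component
#' mixture (defaults: 2% at phred 10-19, 8% at 25-29, 90% at 33-40) so
#' both the phred-20 read filter and the phred-30 tally gate are
#' exercised, and mismatch positions span phreds below and above 30.
#'
#' @param refs a [mirna_refs] reference set.
#' @param abundance named numeric vector of expected read counts per
#'   reference id (unnamed: recycled over all references).
#' @param editing data frame with columns `id`, `position` (1-based on the
#'   mature sequence, reference base must be A) and `fraction`; NULL for
#'   none.
#' @param error_rate per-base substitution error probability (<= 0.05).
#' @param adaptor3 3' adaptor sequence.
#' @param machine_len reported read length (nt).
#' @param tail_prob probability of the 2-base non-templated 3' tail.
#' @param qual_mix length-3 probabilities of the low/mid/high quality
#'   components.
#' @param scale library scale factor.
#' @param rng_seed integer seed.
#' @return A read data frame (`id`, `seq`, `qual`) with a `truth`
#'   attribute: `read_ref` (per-read source reference), `n_per_ref`, and
#'   `edits` (per planted flip: read index, reference id, position).
#' @export
simulate_reads <- function(refs, abundance, editing = NULL,
                           error_rate = 0.001,
                           adaptor3 = DEFAULT_ADAPTOR3,
                           machine_len = 36L, tail_prob = 0.5,
                           qual_mix = c(0.02, 0.08, 0.90),
                           scale = 1, rng_seed = 1L) {
  if (error_rate < 0 || error_rate > 0.05)
    stop("error_rate must lie in [0, 0.05]", call. = FALSE)
  if (is.null(names(abundance)))
    abundance <- stats::setNames(rep_len(abundance, nrow(refs)), refs$id)
  if (!is.null(editing) && nrow(editing)) {
    i <- match(editing$id, refs$id)
    if (anyNA(i))
      stop("editing refers to unknown reference(s)", call. = FALSE)
    refbase <- substr(refs$sequence[i], editing$position, editing$position)
    if (any(refbase != "A"))
      stop("editing position whose reference base is not A", call. = FALSE)
    if (any(editing$fraction < 0 | editing$fraction > 1))
      stop("editing fractions must lie in [0, 1]", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  with_seed(rng_seed, {
    per_ref <- lapply(seq_len(nrow(refs)), function(i) {
      rid <- refs$id[i]
      n <- stats::rpois(1L, abundance[[rid]] * scale)
      if (n == 0L)
        return(list(seq = character(0), ref = rid, edits = NULL))
      L <- nchar(refs$sequence[i])
      seqs <- rep.int(refs$sequence[i], n)
      ed_rows <- NULL
      if (!is.null(editing)) {
        sites <- editing[editing$id == rid, , drop = FALSE]
        for (s in seq_len(nrow(sites))) {
          flip <- which(stats::runif(n) < sites$fraction[s])
          p <- sites$position[s]
          substr(seqs[flip], p, p) <- "G"
          if (length(flip))
            ed_rows <- rbind(ed_rows,
                             data.frame(read = flip, ref_id = rid,
                                        position = p))
        }
      }
      if (error_rate > 0) {
        hit <- which(matrix(stats::runif(n * L) < error_rate, n, L),
                     arr.ind = TRUE)
        for (k in seq_len(nrow(hit))) {
          r <- hit[k, 1L]; p <- hit[k, 2L]
          cur <- substr(seqs[r], p, p)
          substr(seqs[r], p, p) <- sample(setdiff(bases, cur), 1L)
        }
      }
      tails <- stats::runif(n) < tail_prob
      if (any(tails)) {
        tl <- vapply(seq_len(sum(tails)), function(.)
          paste(sample(bases, 2L, replace = TRUE), collapse = ""),
          character(1))
        seqs[tails] <- paste0(seqs[tails], tl)
      }
      list(seq = substr(paste0(seqs, adaptor3), 1L, machine_len),
           ref = rid, edits = ed_rows)
    })
    seqs <- unlist(lapply(per_ref, `[[`, "seq"), use.names = FALSE)
    n_per_ref <- vapply(per_ref, function(x) length(x$seq), integer(1))
    read_ref <- rep.int(refs$id, n_per_ref)
    n_tot <- length(seqs)
    # per-read edit rows need global read indices
    offs <- cumsum(c(0L, n_per_ref[-length(n_per_ref)]))
    edits <- do.call(rbind, lapply(seq_along(per_ref), function(i) {
      e <- per_ref[[i]]$edits
      if (is.null(e)) return(NULL)
      e$read <- e$read + offs[i]
      e
    }))
    lens <- nchar(seqs)
    quals <- vapply(lens, function(L) {
      u <- stats::runif(L)
      q <- integer(L)
      lo <- u < qual_mix[1L]
      mid <- !lo & u < qual_mix[1L] + qual_mix[2L]
      q[lo] <- sample(10:19, sum(lo), replace = TRUE)
      q[mid] <- sample(25:29, sum(mid), replace = TRUE)
      hi <- !lo & !mid
      q[hi] <- sample(33:40, sum(hi), replace = TRUE)
      intToUtf8(q + 33L)
    }, character(1))
    reads <- data.frame(
      id = sprintf("%s_read%06d", read_ref, seq_len(n_tot)),
      seq = seqs, qual = quals, stringsAsFactors = FALSE)
    attr(reads, "truth") <- list(read_ref = read_ref,
                                 n_per_ref = stats::setNames(n_per_ref,
                                                             refs$id),
                                 edits = edits)
    reads
  })
}

#' Simulate a position tally directly
#'
#' Draws, for every reference position, a multinomial base composition at
#' the given coverage under the editing + uniform-error model, without
#' generating reads. This is the fast input for caller-level simulations
#' (type-I error, power, level recovery).
#'
#' @param refs a [mirna_refs] reference set.
#' @param coverage per-position coverage (single value or named per-ref).
#' @param editing as in [simulate_reads()].
#' @param error_rate per-base substitution error probability.
#' @param rng_seed integer seed.
#' @return A `position_tally`.
#' @export
simulate_tally <- function(refs, coverage, editing = NULL,
                           error_rate = 0.001, rng_seed = 1L) {
  bases <- c("A", "C", "G", "T")
  if (is.null(names(coverage)))
    coverage <- stats::setNames(rep_len(coverage, nrow(refs)), refs$id)
  with_seed(rng_seed, {
    tl <- lapply(seq_len(nrow(refs)), function(i) {
      rid <- refs$id[i]
      refb <- strsplit(refs$sequence[i], "")[[1L]]
      L <- length(refb)
      n <- coverage[[rid]]
      frac <- numeric(L)
      if (!is.null(editing)) {
        sites <- editing[editing$id == rid, , drop = FALSE]
        frac[sites$position] <- sites$fraction
      }
      m <- matrix(0L, 4L, L, dimnames = list(bases, NULL))
      for (p in seq_len(L)) {
        probs <- rep(error_rate / 3, 4L)
        bi <- match(refb[p], bases)
        probs[bi] <- 1 - error_rate
        if (frac[p] > 0) {
          # molecule edited A->G with prob frac, then sequencing error
          gi <- match("G", bases)
          pe <- rep(error_rate / 3, 4L)
          pe[gi] <- 1 - error_rate
          probs <- (1 - frac[p]) * probs + frac[p] * pe
        }
        m[, p] <- stats::rmultinom(1L, n, probs)[, 1L]
      }
      m
    })
    names(tl) <- refs$id
    structure(tl, class = "position_tally")
  })
}

#' Simulate per-sample count tables with planted fold-changes
#'
#' Baseline relative abundances are log-normal; a labelled fraction of
#' miRNAs is shifted in the second sample by the planted log2 effect
#' (random sign); observed counts are Poisson at
#' `relative abundance x library size`.
#'
#' @param n_mirnas number of miRNAs.
#' @param libsizes named numeric vector of two library totals.
#' @param frac_changed fraction of miRNAs with a planted change in the
#'   second sample.
#' @param log2_effect absolute planted log2 fold-change.
#' @param baseline_meanlog,baseline_sdlog log-normal abundance parameters.
#' @param rng_seed integer seed.
#' @return A list: `counts` (matrix miRNAs x samples) and `truth`
#'   (data frame `mirna`, `changed`, `log2_effect`).
#' @export
simulate_count_tables <- function(n_mirnas, libsizes, frac_changed = 0,
                                  log2_effect = 1,
                                  baseline_meanlog = 0,
                                  baseline_sdlog = 1.5,
                                  rng_seed = 1L) {
  if (frac_changed < 0 || frac_changed > 1)
    stop("frac_changed must lie in [0, 1]", call. = FALSE)
  if (any(libsizes <= 0)) stop("libsizes must be positive", call. = FALSE)
  if (length(libsizes) != 2L)
    stop("exactly two samples are expected", call. = FALSE)
  if (is.null(names(libsizes))) names(libsizes) <- c("A", "B")
  with_seed(rng_seed, {
    base <- stats::rlnorm(n_mirnas, baseline_meanlog, baseline_sdlog)
    rel <- base / sum(base)
    n_changed <- round(frac_changed * n_mirnas)
    changed <- rep(FALSE, n_mirnas)
    changed[sample.int(n_mirnas, n_changed)] <- TRUE
    eff <- ifelse(changed,
                  log2_effect * sample(c(-1, 1), n_mirnas, replace = TRUE),
                  0)
    rel_b <- rel * 2^eff
    counts <- cbind(stats::rpois(n_mirnas, rel * libsizes[[1L]]),
                    stats::rpois(n_mirnas, rel_b * libsizes[[2L]]))
    dimnames(counts) <- list(sprintf("syn-mir-%04d", seq_len(n_mirnas)),
                             names(libsizes))
    list(counts = counts,
         truth = data.frame(mirna = rownames(counts), changed = changed,
                            log2_effect = eff, stringsAsFactors = FALSE))
  })
}
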