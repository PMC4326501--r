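# Alignment of cleaned reads to the mature-miRNA (or precursor) reference:
# sense strand, ungapped, up to one mismatch, and a mismatch is accepted
# only when the read base has phred >= 30. A small 5' offset window (0-3 nt)
# tolerates isomiR wobble. Exact hits are resolved through a substring hash;
# the one-mismatch search is a vectorized Hamming scan.

MAX_OFFSET5 <- 3L  # maximum 5' start offset on the reference (0-based)

#' Align one read against a reference set
#'
#' Scans the read against every allowed offset of every reference. A
#' candidate hit has at most `cfg$max_mismatches` mismatches, each with
#' read phred >= `cfg$mismatch_quality_min`. The hit with fewest
#' mismatches wins; equally good hits at distinct (reference, offset)
#' positions make the read ambiguous.
#'
#' @param read a single-row read data frame (or list with `seq`, `qual`).
#' @param refs a [mirna_refs] reference set.
#' @param cfg a [pipeline_config()].
#' @return A list with `status` (`"aligned"`, `"unaligned"` or
#'   `"ambiguous"`) and, when aligned, `ref_id`, `start` (1-based on the
#'   reference), `n_mismatch` and `mismatch_pos` (read-relative).
#' @export
align_read <- function(read, refs, cfg = pipeline_config()) {
  if (nrow(refs) == 0L) stop("empty reference set", call. = FALSE)
  seq <- read$seq[[1L]]
  qual <- phred_decode(read$qual[[1L]])[[1L]]
  rr <- charToRaw(seq)
  L <- length(rr)
  hits <- list()
  for (i in seq_len(nrow(refs))) {
    ref_raw <- charToRaw(refs$sequence[i])
    if (L > length(ref_raw)) next
    for (off in 0:min(MAX_OFFSET5, length(ref_raw) - L)) {
      mmpos <- which(ref_raw[(off + 1L):(off + L)] != rr)
      if (length(mmpos) <= cfg$max_mismatches &&
          all(qual[mmpos] >= cfg$mismatch_quality_min)) {
        hits[[length(hits) + 1L]] <-
          list(ref_id = refs$id[i], start = off + 1L,
               n_mismatch = length(mmpos), mismatch_pos = mmpos)
      }
    }
  }
  pick_best_hit(hits)
}

pick_best_hit <- function(hits) {
  if (!length(hits)) return(list(status = "unaligned"))
  nmm <- vapply(hits, `[[`, integer(1), "n_mismatch")
  best <- which(nmm == min(nmm))
  if (length(best) > 1L) return(list(status = "ambiguous"))
  c(list(status = "aligned"), hits[[best]])
}

#' Align a batch of reads
#'
#' Batch driver with the same policy as [align_read()]. Reads are grouped
#' by unique sequence; exact hits come from a precomputed substring hash
#' and only the remainder goes through the Hamming scan. The per-read
#' mismatch-quality rule is then applied read by read.
#'
#' @param reads read data frame.
#' @param refs a [mirna_refs] reference set.
#' @param cfg a [pipeline_config()].
#' @return A data frame with one row per read: `id`, `status`, `ref_id`,
#'   `start`, `n_mismatch` (NA when not aligned).
#' @export
align_reads <- function(reads, refs, cfg = pipeline_config()) {
  if (nrow(refs) == 0L) stop("empty reference set", call. = FALSE)
  n <- nrow(reads)
  out <- data.frame(id = reads$id,
                    status = rep("unaligned", n),
                    ref_id = rep(NA_character_, n),
                    start = rep(NA_integer_, n),
                    n_mismatch = rep(NA_integer_, n),
                    stringsAsFactors = FALSE)
  if (!n) return(out)

  lens <- sort(unique(nchar(reads$seq)))
  idx <- ref_substring_index(refs, lens)
  quals <- phred_decode(reads$qual)

  useq <- unique(reads$seq)
  cand <- candidate_hits(useq, idx)
  map <- match(reads$seq, useq)

  for (j in seq_len(n)) {
    hits <- cand[[map[j]]]
    if (!length(hits)) next
    q <- quals[[j]]
    ok <- vapply(hits, function(h)
      all(q[h$mismatch_pos] >= cfg$mismatch_quality_min), logical(1))
    best <- pick_best_hit(hits[ok])
    out$status[j] <- best$status
    if (best$status == "aligned") {
      out$ref_id[j] <- best$ref_id
      out$start[j] <- best$start
      out$n_mismatch[j] <- best$n_mismatch
    }
  }
  out
}

# Precompute, for each read length L, the reference substrings at 5'
# offsets 0..MAX_OFFSET5: an exact-lookup environment and a raw matrix for
# the Hamming scan.
ref_substring_index <- function(refs, lens) {
  idx <- list()
  for (L in lens) {
    where <- list()
    for (i in seq_len(nrow(refs))) {
      reflen <- nchar(refs$sequence[i])
      for (off in 0:min(MAX_OFFSET5, reflen - L)) {
        if (off + L > reflen) break
        where[[length(where) + 1L]] <-
          list(sub = substr(refs$sequence[i], off + 1L, off + L),
               ref_id = refs$id[i], start = off + 1L)
      }
    }
    if (!length(where)) next
    subs <- vapply(where, `[[`, character(1), "sub")
    mat <- vapply(subs, function(s) charToRaw(s), raw(L))
    exact <- new.env(parent = emptyenv(), hash = TRUE)
    for (k in seq_along(subs))
      exact[[subs[k]]] <- c(exact[[subs[k]]], k)
    idx[[as.character(L)]] <- list(where = where, mat = mat, exact = exact)
  }
  idx
}

# Candidate hits (<= 1 mismatch, before the phred rule) per unique read
# sequence.
candidate_hits <- function(useq, idx) {
  lapply(useq, function(s) {
    entry <- idx[[as.character(nchar(s))]]
    if (is.null(entry)) return(list())
    k_exact <- entry$exact[[s]]
    if (!is.null(k_exact)) {
      return(lapply(k_exact, function(k) {
        w <- entry$where[[k]]
        list(ref_id = w$ref_id, start = w$start, n_mismatch = 0L,
             mismatch_pos = integer(0))
      }))
    }
    rr <- charToRaw(s)
    mm <- colSums(entry$mat != rr)
    ks <- which(mm == 1L)
    lapply(ks, function(k) {
      w <- entry$where[[k]]
      list(ref_id = w$ref_id, start = w$start, n_mismatch = 1L,
           mismatch_pos = which(entry$mat[, k] != rr))
    })
  })
}

#' Accumulate per-position base tallies
#'
#' Every base of every uniquely aligned read with phred >=
#' `cfg$mismatch_quality_min` contributes one count to its reference
#' position; lower-quality bases contribute nothing, neither to the base
#' counts nor to coverage, so the error-rate null of the editing test
#' matches its denominator.
#'
#' @param alignments result of [align_reads()].
#' @param reads the read data frame that was aligned.
#' @param refs a [mirna_refs] reference set.
#' @param cfg a [pipeline_config()].
#' @return An object of class `position_tally`: a named list (one element
#'   per reference) of 4 x L integer matrices with rows A/C/G/T.
#' @export
tally_alignments <- function(alignments, reads, refs,
                             cfg = pipeline_config()) {
  stopifnot(nrow(alignments) == nrow(reads))
  unknown <- setdiff(stats::na.omit(unique(alignments$ref_id)), refs$id)
  if (length(unknown))
    stop("alignment refers to unknown reference(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  tl <- lapply(seq_len(nrow(refs)), function(i)
    matrix(0L, nrow = 4L, ncol = nchar(refs$sequence[i]),
           dimnames = list(c("A", "C", "G", "T"), NULL)))
  names(tl) <- refs$id

  al <- alignments$status == "aligned"
  if (any(al)) {
    ridx <- match(alignments$ref_id[al], refs$id)
    seqs <- reads$seq[al]
    starts <- alignments$start[al]
    lens <- nchar(seqs)
    if (any(starts + lens - 1L > nchar(refs$sequence)[ridx]))
      stop("aligned position outside the reference", call. = FALSE)
    quals <- unlist(phred_decode(reads$qual[al]), use.names = FALSE)
    bases <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
    pos <- unlist(lapply(seq_along(lens), function(j)
      seq.int(starts[j], length.out = lens[j])), use.names = FALSE)
    refrep <- rep.int(ridx, lens)
    keep <- quals >= cfg$mismatch_quality_min
    base_i <- match(bases[keep], c("A", "C", "G", "T"))
    pos <- pos[keep]
    refrep <- refrep[keep]
    ok <- !is.na(base_i)
    maxlen <- max(vapply(tl, ncol, integer(1)))
    key <- ((refrep[ok] - 1L) * maxlen + (pos[ok] - 1L)) * 4L + base_i[ok]
    cnt <- tabulate(key, nbins = nrow(refs) * maxlen * 4L)
    nz <- which(cnt > 0L)
    for (k in nz) {
      b <- (k - 1L) %% 4L + 1L
      p <- ((k - 1L) %/% 4L) %% maxlen + 1L
      r <- (k - 1L) %/% (4L * maxlen) + 1L
      tl[[r]][b, p] <- tl[[r]][b, p] + cnt[k]
    }
  }
  structure(tl, class = "position_tally")
}

#' @export
print.position_tally <- function(x, ...) {
  cov <- vapply(x, function(m) sum(m), numeric(1))
  cat("Position tally over", length(x), "reference(s);",
      sum(cov), "tallied bases\n")
  invisible(x)
}

#' Per-reference coverage from a tally
#'
#' @param tally a `position_tally`.
#' @return A list of integer coverage vectors (column sums).
#' @export
tally_coverage <- function(tally) {
  lapply(tally, colSums)
}

#' Per-miRNA expression counts from alignments
#'
#' Counts uniquely aligned reads per reference; ambiguous and unaligned
#' reads are excluded.
#'
#' @param alignments result of [align_reads()].
#' @param refs a [mirna_refs] reference set.
#' @return Named integer vector over all reference ids.
#' @export
expression_counts <- function(alignments, refs) {
  al <- alignments$ref_id[alignments$status == "aligned"]
  tab <- table(factor(al, levels = refs$id))
  stats::setNames(as.integer(tab), refs$id)
}

#' Write a tally as TSV
#'
#' Schema: `ref_id`, `pos` (1-based), `ref_base`, `nA`, `nC`, `nG`, `nT`,
#' `coverage`.
#'
#' @param tally a `position_tally`.
#' @param refs the matching [mirna_refs].
#' @param path output path.
#' @export
write_tally <- function(tally, refs, path) {
  rows <- lapply(names(tally), function(rid) {
    m <- tally[[rid]]
    seq <- refs$sequence[match(rid, refs$id)]
    data.frame(ref_id = rid, pos = seq_len(ncol(m)),
               ref_base = strsplit(seq, "")[[1L]],
               nA = m["A", ], nC = m["C", ], nG = m["G", ], nT = m["T", ],
               coverage = colSums(m), stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a tally TSV back into a `position_tally`
#'
#' @param path tally TSV path (schema of [write_tally()]).
#' @return A `position_tally`.
#' @export
read_tally <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  tl <- lapply(split(df, factor(df$ref_id, levels = unique(df$ref_id))),
               function(d) {
                 d <- d[order(d$pos), ]
                 m <- t(as.matrix(d[, c("nA", "nC", "nG", "nT")]))
                 rownames(m) <- c("A", "C", "G", "T")
                 colnames(m) <- NULL
                 m
               })
  structure(tl, class = "position_tally")
}
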