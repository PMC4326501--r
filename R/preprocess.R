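# Read cleaning: quality gate, adaptor removal, length gate, 3' trim —
# applied in that order, as the sequencing protocol's 3' modifications and
# ligated adaptors require.

#' Quality filter
#'
#' A read is dropped when strictly more than `max_low_quality_positions` of
#' its bases fall strictly below `quality_threshold` (so a read with
#' exactly three positions at phred 19 is kept under the defaults).
#'
#' @param reads read data frame (`id`, `seq`, `qual`).
#' @param cfg a [pipeline_config()].
#' @return Logical vector: `TRUE` = keep.
#' @export
quality_filter <- function(reads, cfg = pipeline_config()) {
  phred <- phred_decode(reads$qual)
  n_low <- vapply(phred, function(q) sum(q < cfg$quality_threshold),
                  integer(1))
  n_low <= cfg$max_low_quality_positions
}

#' Remove 3' (and optionally 5') adaptor sequence
#'
#' The longest read suffix matching a prefix of `adaptor3` is removed
#' together with its qualities, requiring an overlap of at least 8 nt and
#' tolerating at most one mismatch per 8 nt of overlap. A 5' adaptor, when
#' supplied, is handled symmetrically (longest read prefix matching an
#' adaptor suffix). Reads in which no adaptor is found are returned
#' unchanged and flagged.
#'
#' @param reads read data frame.
#' @param adaptor3 3' adaptor sequence (>= 8 nt).
#' @param adaptor5 optional 5' adaptor sequence.
#' @param min_overlap minimum adaptor overlap (nt).
#' @return The read data frame with trimmed `seq`/`qual` and a logical
#'   column `adaptor_found`.
#' @export
trim_adaptor <- function(reads, adaptor3, adaptor5 = NULL, min_overlap = 8L) {
  if (nchar(adaptor3) < min_overlap)
    stop("adaptor3 must be at least ", min_overlap, " nt", call. = FALSE)
  adaptor3 <- toupper(adaptor3)
  if (!is.null(adaptor5)) adaptor5 <- toupper(adaptor5)
  n <- nrow(reads)
  found <- logical(n)
  if (n) {
    a_raw <- charToRaw(adaptor3)
    for (i in seq_len(n)) {
      cut <- adaptor_cut(charToRaw(reads$seq[i]), a_raw, min_overlap)
      if (!is.na(cut)) {
        found[i] <- TRUE
        reads$seq[i] <- substr(reads$seq[i], 1L, cut - 1L)
        reads$qual[i] <- substr(reads$qual[i], 1L, cut - 1L)
      }
    }
    if (!is.null(adaptor5)) {
      a5r <- rev(charToRaw(adaptor5))
      for (i in seq_len(n)) {
        # mirror: reverse read and adaptor, reuse the suffix scan
        rr <- rev(charToRaw(reads$seq[i]))
        cut <- adaptor_cut(rr, a5r, min_overlap)
        if (!is.na(cut)) {
          found[i] <- TRUE
          keep_from <- length(rr) - cut + 2L
          reads$seq[i] <- substr(reads$seq[i], keep_from,
                                 nchar(reads$seq[i]))
          reads$qual[i] <- substr(reads$qual[i], keep_from,
                                  nchar(reads$qual[i]))
        }
      }
    }
  }
  reads$adaptor_found <- found
  reads
}

# First base (1-based) of the longest read suffix matching an adaptor
# prefix with <= floor(overlap/8) mismatches, or NA. Raw-vector inputs.
adaptor_cut <- function(read_raw, adaptor_raw, min_overlap) {
  len <- length(read_raw)
  max_o <- min(len, length(adaptor_raw))
  if (max_o < min_overlap) return(NA_integer_)
  for (o in seq(max_o, min_overlap)) {
    start <- len - o + 1L
    mm <- sum(read_raw[start:len] != adaptor_raw[seq_len(o)])
    if (mm <= o %/% 8L) return(start)
  }
  NA_integer_
}

#' Length filter
#'
#' Keeps reads whose post-adaptor length lies in the inclusive window
#' `[min_read_length, max_read_length]` (the removal rules are the strict
#' inequalities "shorter than 15" / "longer than 28", so 15 and 28 survive).
#'
#' @inheritParams quality_filter
#' @return Logical vector: `TRUE` = keep.
#' @export
length_filter <- function(reads, cfg = pipeline_config()) {
  len <- nchar(reads$seq)
  len >= cfg$min_read_length & len <= cfg$max_read_length
}

#' Trim the 3'-terminal bases
#'
#' Removes the final `three_prime_trim` bases and their qualities (the 3'
#' end of mature small-RNA reads carries non-templated modifications).
#' Errors if any read is not strictly longer than the trim amount.
#'
#' @inheritParams quality_filter
#' @export
trim_three_prime <- function(reads, cfg = pipeline_config()) {
  k <- cfg$three_prime_trim
  if (k == 0) return(reads)
  len <- nchar(reads$seq)
  if (any(len <= k))
    stop("read(s) shorter than or equal to the 3' trim amount (",
         k, " nt)", call. = FALSE)
  reads$seq <- substr(reads$seq, 1L, len - k)
  reads$qual <- substr(reads$qual, 1L, len - k)
  reads
}

#' Run the full read-cleaning cascade
#'
#' Applies, in order: the quality gate, adaptor removal, the insert length
#' gate (on the post-adaptor length) and the 3' trim. Returns the clean
#' reads together with per-rule drop statistics that conserve the total.
#'
#' @inheritParams trim_adaptor
#' @param cfg a [pipeline_config()].
#' @return A list with `reads` (clean read data frame) and `stats` (named
#'   integer vector: `input`, `dropped_quality`, `dropped_length`,
#'   `no_adaptor`, `retained`).
#' @export
preprocess_reads <- function(reads, adaptor3, adaptor5 = NULL,
                             cfg = pipeline_config()) {
  n_in <- nrow(reads)
  keep_q <- if (n_in) quality_filter(reads, cfg) else logical(0)
  reads <- reads[keep_q, , drop = FALSE]
  reads <- trim_adaptor(reads, adaptor3, adaptor5)
  n_noad <- sum(!reads$adaptor_found)
  keep_l <- if (nrow(reads)) length_filter(reads, cfg) else logical(0)
  reads <- reads[keep_l, , drop = FALSE]
  reads <- trim_three_prime(reads, cfg)
  stats <- c(input = n_in,
             dropped_quality = n_in - sum(keep_q),
             dropped_length = length(keep_l) - sum(keep_l),
             no_adaptor = n_noad,
             retained = nrow(reads))
  list(reads = reads, stats = stats)
}
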