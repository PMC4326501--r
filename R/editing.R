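# The editing-site caller: per-position binomial overrepresentation test of
# each alternate base against the sequencing-error null, editing-level
# estimation with the A/(A+G)-style denominator, ND handling, seed
# annotation, neighbour-context profile and cross-sample comparison.

#' Upper-tail binomial p-value against the sequencing-error null
#'
#' Returns `P(X >= n_alt)` for `X ~ Binomial(n_total, error_rate)`,
#' computed through the survival function, which is exact and numerically
#' stable for very deep coverage. `n_alt = 0` gives 1.
#'
#' @param n_alt observed count of the alternate base (vectorized).
#' @param n_total number of quality-passing bases at the position.
#' @param error_rate per-base sequencing error probability (in (0,1)).
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' binomial_site_pvalue(5, 1000, 0.001)
#' @export
binomial_site_pvalue <- function(n_alt, n_total, error_rate) {
  if (any(error_rate <= 0) || any(error_rate >= 1))
    stop("error_rate must lie strictly inside (0, 1)", call. = FALSE)
  if (any(n_alt < 0) || any(n_alt > n_total))
    stop("n_alt must satisfy 0 <= n_alt <= n_total", call. = FALSE)
  stats::pbinom(n_alt - 1, n_total, error_rate, lower.tail = FALSE)
}

#' Call editing sites from a position tally
#'
#' For every reference position and every alternate base observed there
#' (`n_alt > 0`), the alternate count is tested against the binomial
#' sequencing-error null on the position's quality-passing coverage. The
#' multiple-testing correction (default Bonferroni, over all position x
#' alternate-base tests performed in the sample) is applied across all
#' references in `tally`. A site is `significant` when the adjusted
#' p-value is below `cfg$editing_alpha` and coverage is at least
#' `cfg$nd_min_reads`; any site with coverage below `cfg$nd_min_reads` is
#' `ND` regardless of its p-value. The editing level is
#' `100 * n_alt / (n_ref + n_alt)` — other alternate bases are excluded
#' from the denominator, matching the Sanger peak-ratio definition.
#'
#' @param tally a `position_tally` (one sample).
#' @param refs the matching [mirna_refs].
#' @param cfg a [pipeline_config()].
#' @param correction `"bonferroni"`, `"BH"` or `"none"`.
#' @return A data frame of class `editing_calls`, one row per tested
#'   (reference, position, alternate base): `ref_id`, `position`
#'   (1-based), `ref_base`, `alt_base`, `n_ref`, `n_alt`, `coverage`,
#'   `editing_level` (percent), `p_value`, `p_adj`, `status`, `in_seed`,
#'   `is_AtoG`.
#' @export
call_sites <- function(tally, refs, cfg = pipeline_config(),
                       correction = c("bonferroni", "BH", "none")) {
  correction <- match.arg(correction)
  missing_refs <- setdiff(names(tally), refs$id)
  if (length(missing_refs))
    stop("tally references not in the reference set: ",
         paste(missing_refs, collapse = ", "), call. = FALSE)
  bases <- c("A", "C", "G", "T")
  rows <- vector("list", length(tally))
  for (k in seq_along(tally)) {
    rid <- names(tally)[k]
    m <- tally[[k]]
    i <- match(rid, refs$id)
    refseq <- strsplit(refs$sequence[i], "")[[1L]]
    if (ncol(m) != length(refseq))
      stop("tally and reference length differ for ", rid, call. = FALSE)
    cov <- colSums(m)
    ref_i <- match(refseq, bases)
    n_ref <- m[cbind(ref_i, seq_along(refseq))]
    # one candidate row per (position, alternate base) with n_alt > 0
    alt <- which(m > 0L & row(m) != matrix(ref_i, 4L, ncol(m), byrow = TRUE),
                 arr.ind = TRUE)
    if (!nrow(alt)) next
    pos <- alt[, 2L]
    seed <- seed_span(refs[i, ], cfg)
    in_seed <- if (is.null(seed)) rep(FALSE, length(pos))
               else pos >= seed[1L] & pos <= seed[2L]
    rows[[k]] <- data.frame(
      ref_id = rid,
      position = pos,
      ref_base = refseq[pos],
      alt_base = bases[alt[, 1L]],
      n_ref = n_ref[pos],
      n_alt = m[alt],
      coverage = cov[pos],
      in_seed = in_seed,
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, rows)
  if (is.null(calls))
    calls <- data.frame(ref_id = character(0), position = integer(0),
                        ref_base = character(0), alt_base = character(0),
                        n_ref = integer(0), n_alt = integer(0),
                        coverage = integer(0), in_seed = logical(0),
                        stringsAsFactors = FALSE)
  calls$editing_level <-
    ifelse(calls$n_ref + calls$n_alt > 0,
           100 * calls$n_alt / (calls$n_ref + calls$n_alt), NA_real_)
  calls$p_value <- if (nrow(calls))
    binomial_site_pvalue(calls$n_alt, calls$coverage,
                         cfg$sequencing_error_rate) else numeric(0)
  calls$p_adj <- switch(correction,
                        bonferroni = pmin(1, calls$p_value * nrow(calls)),
                        BH = stats::p.adjust(calls$p_value, method = "BH"),
                        none = calls$p_value)
  calls$status <- ifelse(calls$coverage < cfg$nd_min_reads, "ND",
                         ifelse(calls$p_adj < cfg$editing_alpha,
                                "significant", "not_significant"))
  calls$is_AtoG <- calls$ref_base == "A" & calls$alt_base == "G"
  calls <- calls[, c("ref_id", "position", "ref_base", "alt_base", "n_ref",
                     "n_alt", "coverage", "editing_level", "p_value",
                     "p_adj", "status", "in_seed", "is_AtoG")]
  rownames(calls) <- NULL
  class(calls) <- c("editing_calls", "data.frame")
  calls
}

# Seed span for one reference: its own annotation if present, else the
# config span for mature/star references, none for precursors.
seed_span <- function(ref, cfg) {
  if (!is.na(ref$seed_start) && !is.na(ref$seed_end))
    return(c(ref$seed_start, ref$seed_end))
  if (ref$kind == "precursor") return(NULL)
  c(cfg$seed_start, min(cfg$seed_end, nchar(ref$sequence)))
}

#' @export
print.editing_calls <- function(x, ...) {
  sig <- sum(x$status == "significant")
  nd <- sum(x$status == "ND")
  cat(sprintf(
    "Editing-site calls: %d tested (position x alt base), %d significant, %d ND\n",
    nrow(x), sig, nd))
  sigs <- x[x$status == "significant" & x$is_AtoG, , drop = FALSE]
  if (nrow(sigs)) {
    cat("Significant A-to-G sites:\n")
    print.data.frame(utils::head(
      sigs[order(sigs$p_adj),
           c("ref_id", "position", "editing_level", "p_adj", "in_seed")],
      20L), row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Compare editing calls across samples
#'
#' Builds one row per (reference, position, alternate base) observed in any
#' sample, with per-sample editing levels (NA where the sample has no
#' coverage or the site is ND) and per-sample significance flags. When
#' `active` and `control` sample names are given, sites significant in the
#' active sample but not in the control are flagged enzyme-specific.
#'
#' @param calls_by_sample named list of `editing_calls` sharing a
#'   reference set.
#' @param active,control optional sample names (e.g. the active-enzyme and
#'   catalytically dead conditions).
#' @return A data frame with `level_<sample>` and `significant_<sample>`
#'   columns and, when requested, an `enzyme_specific` flag.
#' @export
compare_conditions <- function(calls_by_sample, active = NULL,
                               control = NULL) {
  stopifnot(length(calls_by_sample) >= 1L, !is.null(names(calls_by_sample)))
  keys <- unique(do.call(rbind, lapply(calls_by_sample, function(d)
    d[, c("ref_id", "position", "ref_base", "alt_base")])))
  keys <- keys[order(keys$ref_id, keys$position, keys$alt_base), ,
               drop = FALSE]
  rownames(keys) <- NULL
  out <- keys
  for (s in names(calls_by_sample)) {
    d <- calls_by_sample[[s]]
    i <- match(paste(keys$ref_id, keys$position, keys$alt_base),
               paste(d$ref_id, d$position, d$alt_base))
    lev <- d$editing_level[i]
    lev[!is.na(i) & d$status[i] == "ND"] <- NA_real_
    out[[paste0("level_", s)]] <- lev
    out[[paste0("significant_", s)]] <-
      !is.na(i) & d$status[i] == "significant"
  }
  if (!is.null(active) && !is.null(control)) {
    for (s in c(active, control))
      if (!s %in% names(calls_by_sample))
        stop("sample not present: ", s, call. = FALSE)
    out$enzyme_specific <- out[[paste0("significant_", active)]] &
      !out[[paste0("significant_", control)]]
  }
  out
}

#' Sequence context of called sites
#'
#' Nucleotide frequencies at the positions immediately upstream (-1) and
#' downstream (+1) of significant A-to-G calls, computed on the reference
#' sequence; sites at a sequence boundary are excluded from the affected
#' side. Genuine A-to-I sites typically show U enriched upstream and G
#' downstream.
#'
#' @param calls an `editing_calls` data frame (non-empty).
#' @param refs the matching [mirna_refs].
#' @param significant_only restrict to significant A-to-G calls (default).
#' @return A list with `upstream` and `downstream` frequency vectors over
#'   A/C/G/T (each summing to 1), plus the site count used.
#' @export
context_profile <- function(calls, refs, significant_only = TRUE) {
  if (significant_only)
    calls <- calls[calls$status == "significant" & calls$is_AtoG, ,
                   drop = FALSE]
  if (!nrow(calls)) stop("no sites to profile", call. = FALSE)
  i <- match(calls$ref_id, refs$id)
  seqs <- refs$sequence[i]
  up <- substr(seqs, calls$position - 1L, calls$position - 1L)
  down <- substr(seqs, calls$position + 1L, calls$position + 1L)
  freq <- function(x) {
    x <- x[nzchar(x)]
    tab <- table(factor(x, levels = c("A", "C", "G", "T")))
    as.vector(tab) / max(1L, length(x))
  }
  list(upstream = stats::setNames(freq(up), c("A", "C", "G", "T")),
       downstream = stats::setNames(freq(down), c("A", "C", "G", "T")),
       n_sites = nrow(calls))
}

#' Per-position A-to-G editing over a precursor amplicon
#'
#' Reuses the site caller on a precursor coordinate system and labels each
#' site relative to a declared anchor (for instance the pre-miRNA start):
#' the anchor base is `+1`, the base before it `-1`, with no position zero.
#'
#' @param tally a `position_tally` over precursor reference(s).
#' @param refs precursor [mirna_refs].
#' @param anchor named integer vector: 1-based anchor position per
#'   reference id (references without an entry keep absolute labels).
#' @param cfg a [pipeline_config()].
#' @param correction multiple-testing correction, as in [call_sites()].
#' @return An `editing_calls` data frame restricted to A-to-G rows, with an
#'   extra `anchor_label` column.
#' @export
amplicon_editing <- function(tally, refs, anchor = NULL,
                             cfg = pipeline_config(),
                             correction = "bonferroni") {
  calls <- call_sites(tally, refs, cfg, correction)
  calls <- calls[calls$is_AtoG, , drop = FALSE]
  lab <- as.character(calls$position)
  if (!is.null(anchor)) {
    for (rid in names(anchor)) {
      a <- anchor[[rid]]
      reflen <- nchar(refs$sequence[match(rid, refs$id)])
      if (is.na(reflen) || a < 1L || a > reflen)
        stop("anchor outside reference ", rid, call. = FALSE)
      sel <- calls$ref_id == rid
      rel <- calls$position[sel] - a
      lab[sel] <- ifelse(rel >= 0, sprintf("+%d", rel + 1L),
                         sprintf("%d", rel))
    }
  }
  calls$anchor_label <- lab
  rownames(calls) <- NULL
  class(calls) <- c("editing_calls", "data.frame")
  calls
}
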