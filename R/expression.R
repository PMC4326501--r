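# Expression half of the pipeline: TMM normalization, exact conditional
# Poisson difference test with Bonferroni correction, the
# log2[(A+1)/(B+1)] fold-change and the selection/reversal filters.

#' log2 fold-change with pseudocount
#'
#' Exactly `log2((a + 1) / (b + 1))`; the +1 pseudocount keeps the ratio
#' finite for zero counts. Vectorized.
#'
#' @param a,b non-negative (normalized) counts.
#' @return Numeric vector of log2 fold-changes.
#' @examples
#' fold_change(5296, 14463)  # -1.4492
#' @export
fold_change <- function(a, b) {
  if (any(a < 0) || any(b < 0))
    stop("counts must be non-negative", call. = FALSE)
  log2((a + 1) / (b + 1))
}

#' TMM normalization of a count table
#'
#' Trimmed-mean-of-M-values normalization (via edgeR): per-sample factors
#' are precision-weighted means of gene-wise log2 ratios to a reference
#' sample after trimming the most extreme M-values (default 30%) and
#' A-values (default 5%), with genes zero in either sample excluded and
#' the reference chosen as the sample whose upper quartile is closest to
#' the across-sample mean. The effective scale factor reported here is
#' library size x TMM factor, rescaled to geometric mean 1, and the
#' normalized table is counts divided by it — so normalizing an already
#' normalized table returns factors of 1.
#'
#' @param counts numeric matrix, miRNAs x samples (>= 2 samples, each with
#'   at least one nonzero count).
#' @param logratio_trim,sum_trim trim fractions for M- and A-values.
#' @return A list of class `tmm_norm`: `factors` (effective per-sample
#'   scale factors), `normalized` (rescaled count matrix, `normalized`
#'   attribute TRUE), `ref_sample`, `trims`.
#' @export
tmm_normalize <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  if (ncol(counts) < 2L)
    stop("TMM normalization needs at least two samples", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib <= 0))
    stop("all-zero sample: ",
         paste(colnames(counts)[lib <= 0], collapse = ", "), call. = FALSE)
  f75 <- apply(counts, 2L, function(x) stats::quantile(x / sum(x), 0.75))
  ref <- which.min(abs(f75 - mean(f75)))
  f <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = ref,
                              logratioTrim = logratio_trim,
                              sumTrim = sum_trim)
  eff <- lib * f
  factors <- eff / exp(mean(log(eff)))
  norm <- sweep(counts, 2L, factors, "/")
  attr(norm, "normalized") <- TRUE
  structure(list(factors = factors, normalized = norm,
                 ref_sample = colnames(counts)[ref] %||% ref,
                 trims = c(logratio_trim = logratio_trim,
                           sum_trim = sum_trim)),
            class = "tmm_norm")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.tmm_norm <- function(x, ...) {
  cat("TMM normalization (reference sample:", x$ref_sample, ")\n")
  print(round(x$factors, 4))
  invisible(x)
}

#' Exact conditional test of equal Poisson rates
#'
#' Conditional on the total `n = a + b`, `a` is Binomial(n,
#' `lib_a / (lib_a + lib_b)`) under the null of equal per-library rates;
#' the two-sided p-value sums all outcome probabilities no larger than the
#' observed one (minimum-likelihood method). `a + b = 0` returns 1 by
#' convention.
#'
#' @param a,b observed counts in the two samples.
#' @param lib_a,lib_b library totals (> 0).
#' @return Two-sided p-value.
#' @export
poisson_diff_pvalue <- function(a, b, lib_a = 1, lib_b = 1) {
  if (a < 0 || b < 0) stop("counts must be non-negative", call. = FALSE)
  if (lib_a <= 0 || lib_b <= 0)
    stop("library totals must be positive", call. = FALSE)
  a <- round(a)
  b <- round(b)
  n <- a + b
  if (n == 0) return(1)
  stats::binom.test(a, n, p = lib_a / (lib_a + lib_b))$p.value
}

#' Differential expression table between two samples
#'
#' Per miRNA: the log2[(A+1)/(B+1)] fold-change, the exact Poisson
#' difference p-value conditioned on the two library totals, Bonferroni
#' adjustment over all miRNAs with a nonzero summed count, and the two
#' selection filters — summed counts strictly above
#' `cfg$expr_min_sum_reads` and |log2 ratio| at least
#' `cfg$expr_log2_cutoff`. A record is `selected` when it passes both
#' filters and is significant at `cfg$expr_alpha`.
#'
#' The Poisson test conditions on the effective library sizes: for a
#' TMM-normalized table (`normalized` attribute TRUE, as produced by
#' [tmm_normalize()]) the libraries are on a common scale by construction
#' and are treated as equal; for raw counts the column totals are used.
#' `lib_sizes` overrides either choice.
#'
#' @param counts numeric matrix of (normalized) counts, miRNAs x samples.
#' @param sample_a,sample_b column names of the contrast (A vs B).
#' @param cfg a [pipeline_config()].
#' @param lib_sizes optional length-2 effective library sizes for the
#'   conditioning.
#' @return A data frame of class `mirna_de`: `mirna`, `count_a`,
#'   `count_b`, `log2_ratio`, `p_value`, `p_adj`, `significant`,
#'   `passes_sum_filter`, `passes_effect_filter`, `selected`.
#' @export
differential_table <- function(counts, sample_a, sample_b,
                               cfg = pipeline_config(),
                               lib_sizes = NULL) {
  for (s in c(sample_a, sample_b))
    if (!s %in% colnames(counts))
      stop("unknown sample: ", s, call. = FALSE)
  a <- counts[, sample_a]
  b <- counts[, sample_b]
  if (is.null(lib_sizes)) {
    lib_sizes <- if (isTRUE(attr(counts, "normalized"))) c(1, 1)
                 else c(sum(a), sum(b))
  }
  lib_a <- lib_sizes[[1L]]
  lib_b <- lib_sizes[[2L]]
  if (nrow(counts) == 0L) lib_a <- lib_b <- 1
  p <- vapply(seq_along(a), function(i)
    poisson_diff_pvalue(a[i], b[i], lib_a, lib_b), numeric(1))
  m <- sum(a + b > 0)
  p_adj <- ifelse(a + b > 0, pmin(1, p * m), 1)
  de <- data.frame(
    mirna = rownames(counts) %||% as.character(seq_along(a)),
    count_a = as.numeric(a), count_b = as.numeric(b),
    log2_ratio = fold_change(a, b),
    p_value = p, p_adj = p_adj,
    significant = p_adj < cfg$expr_alpha,
    passes_sum_filter = a + b > cfg$expr_min_sum_reads,
    passes_effect_filter = abs(fold_change(a, b)) >= cfg$expr_log2_cutoff,
    stringsAsFactors = FALSE)
  de$selected <- de$significant & de$passes_sum_filter &
    de$passes_effect_filter
  rownames(de) <- NULL
  class(de) <- c("mirna_de", "data.frame")
  attr(de, "contrast") <- c(a = sample_a, b = sample_b)
  de
}

#' @export
print.mirna_de <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("Differential miRNA expression (%s vs %s): %d miRNAs\n",
              ct[["a"]], ct[["b"]], nrow(x)))
  cat(sprintf("  significant: %d; selected (sum/effect/significance): %d (%d down, %d up)\n",
              sum(x$significant), sum(x$selected),
              sum(x$selected & x$log2_ratio < 0),
              sum(x$selected & x$log2_ratio > 0)))
  invisible(x)
}

#' Highly expressed subset
#'
#' Keeps records whose summed counts across the contrast reach
#' `cfg$high_expr_min_sum` (inclusive).
#'
#' @param de a [differential_table()] result.
#' @param cfg a [pipeline_config()].
#' @export
high_expression_subset <- function(de, cfg = pipeline_config()) {
  out <- de[de$count_a + de$count_b >= cfg$high_expr_min_sum, ,
            drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expression-trend reversal filter
#'
#' Keeps the miRNAs selected in the first contrast (e.g. active enzyme vs
#' dead enzyme) whose log2 ratio in the second contrast (e.g. silenced vs
#' active) has the strictly opposite sign; a zero second-contrast ratio is
#' no reversal. No magnitude threshold is applied to the second contrast.
#'
#' @param contrast1,contrast2 [differential_table()] results over a shared
#'   miRNA universe.
#' @return Character vector of miRNA ids.
#' @export
reversal_filter <- function(contrast1, contrast2) {
  i <- match(contrast1$mirna, contrast2$mirna)
  l2 <- contrast2$log2_ratio[i]
  keep <- contrast1$selected & !is.na(l2) &
    sign(contrast1$log2_ratio) * sign(l2) < 0
  contrast1$mirna[keep]
}
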