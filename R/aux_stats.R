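# Auxiliary statistics: microarray probe selection (one-sample t-test on
# replicate log-ratios, BH FDR, effect filter), 2^-ddCt relative
# quantification, and the Sanger peak-area editing percentage.

#' Benjamini-Hochberg q-values
#'
#' Standard step-up BH with monotonicity enforcement, input order
#' preserved.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Select differentially expressed array probes
#'
#' Each probe's replicate log2 ratios (e.g. Hy3/Hy5, active vs dead
#' enzyme, from independent hybridizations) are tested against zero with
#' a two-sided one-sample t-test; BH correction is applied across probes,
#' and a probe is selected when its q-value is at most
#' `cfg$array_fdr_cutoff` and its mean log2 ratio is at least
#' `cfg$array_log2_cutoff` in absolute value (both bounds inclusive).
#'
#' @param ratios numeric matrix of replicate log2 ratios, probes x
#'   replicates, with probe ids as row names. Each probe needs >= 2
#'   non-missing replicates.
#' @param cfg a [pipeline_config()].
#' @return A data frame: `mirna`, `mean_log2`, `p_value`, `q_value`,
#'   `selected`.
#' @export
array_select <- function(ratios, cfg = pipeline_config()) {
  ratios <- as.matrix(ratios)
  nrep <- rowSums(!is.na(ratios))
  if (any(nrep < 2L))
    stop("probe(s) with fewer than 2 replicates: ",
         paste(utils::head(rownames(ratios)[nrep < 2L]), collapse = ", "),
         call. = FALSE)
  mean_log2 <- rowMeans(ratios, na.rm = TRUE)
  p <- apply(ratios, 1L, function(x) {
    x <- x[!is.na(x)]
    if (stats::sd(x) == 0) return(if (mean(x) == 0) 1 else 0)
    stats::t.test(x, mu = 0)$p.value
  })
  q <- bh_fdr(p)
  data.frame(mirna = rownames(ratios) %||% as.character(seq_len(nrow(ratios))),
             mean_log2 = mean_log2, p_value = p, q_value = q,
             selected = q <= cfg$array_fdr_cutoff &
               abs(mean_log2) >= cfg$array_log2_cutoff,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Relative quantification by 2^-ddCt
#'
#' Per sample, dCt is the target Ct minus the endogenous-control Ct (e.g.
#' RNU6B or GAPDH); ddCt subtracts the calibrator's dCt, and the relative
#' fold is `2^-ddCt`, so the calibrator maps to 1. Vectorized over
#' samples.
#'
#' @param target_ct,reference_ct sample Ct values for the target and the
#'   endogenous control.
#' @param calibrator_target_ct,calibrator_reference_ct calibrator Cts.
#' @return Relative expression fold(s).
#' @examples
#' ddct_fold(25, 20, 25, 20)  # calibrator itself -> 1
#' @export
ddct_fold <- function(target_ct, reference_ct,
                      calibrator_target_ct, calibrator_reference_ct) {
  cts <- c(target_ct, reference_ct, calibrator_target_ct,
           calibrator_reference_ct)
  if (any(!is.finite(cts)) || any(cts <= 0))
    stop("Ct values must be positive and finite", call. = FALSE)
  dct <- target_ct - reference_ct
  dct_cal <- calibrator_target_ct - calibrator_reference_ct
  2^(-(dct - dct_cal))
}

#' Editing level from Sanger peak areas
#'
#' The direct-sequencing editing percentage: the area under the G peak
#' divided by the summed areas of the A and G peaks at the site, times
#' 100. Vectorized.
#'
#' @param auc_a,auc_g non-negative peak areas (not both zero).
#' @return Editing level in percent.
#' @examples
#' sanger_editing_level(60, 40)  # 40
#' @export
sanger_editing_level <- function(auc_a, auc_g) {
  if (any(auc_a < 0) || any(auc_g < 0))
    stop("peak areas must be non-negative", call. = FALSE)
  if (any(auc_a + auc_g == 0))
    stop("A and G peak areas are both zero", call. = FALSE)
  100 * auc_g / (auc_a + auc_g)
}
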