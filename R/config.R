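#' Pipeline configuration
#'
#' Builds the single typed configuration object holding every threshold used
#' by the pipeline. Defaults are the analysis constants of the study design:
#' reads are dropped when more than three positions fall below phred 20,
#' inserts outside 15--28 nt are removed, the last two 3' bases are trimmed,
#' alignment tolerates one mismatch at phred >= 30, the editing caller tests
#' mismatch counts against a 0.1% sequencing-error null at alpha 0.05, sites
#' under 10 reads are reported ND, expression contrasts require a summed
#' normalized count above 200 and |log2 ratio| >= 0.5 ("highly expressed"
#' means a sum >= 10,000), arrays use BH FDR <= 0.2 with the same effect
#' cutoff, and the seed region is mature positions 2--8.
#'
#' @param quality_threshold phred score below which a base counts as
#'   low-quality in the read filter.
#' @param max_low_quality_positions maximum tolerated number of low-quality
#'   positions per read (strictly more leads to a drop).
#' @param min_read_length,max_read_length inclusive insert length gate (nt),
#'   applied after adaptor removal.
#' @param three_prime_trim number of 3' bases removed before alignment.
#' @param mismatch_quality_min minimum phred for an alignment mismatch (and
#'   for a base to enter the position tally).
#' @param max_mismatches maximum mismatches per alignment.
#' @param sequencing_error_rate per-base error probability of the binomial
#'   null.
#' @param editing_alpha significance level for editing-site calls (applied
#'   after multiple-testing correction).
#' @param nd_min_reads minimum coverage below which a site is "ND".
#' @param expr_min_sum_reads strict lower bound on summed normalized counts
#'   for the expression selection filter.
#' @param expr_log2_cutoff inclusive |log2 fold-change| cutoff for the
#'   expression selection filter.
#' @param high_expr_min_sum inclusive summed-count bound defining the highly
#'   expressed subset.
#' @param expr_alpha significance level for the Poisson difference test
#'   (Bonferroni-adjusted).
#' @param array_fdr_cutoff inclusive BH q-value cutoff for array probes.
#' @param array_log2_cutoff inclusive |mean log2 ratio| cutoff for array
#'   probes.
#' @param seed_start,seed_end 1-based closed seed-region span on the mature
#'   sequence.
#' @param rng_seed integer seed recorded for pipeline runs.
#' @return An object of class `pipeline_config` (a validated named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$quality_threshold
#' @export
pipeline_config <- function(quality_threshold = 20,
                            max_low_quality_positions = 3,
                            min_read_length = 15,
                            max_read_length = 28,
                            three_prime_trim = 2,
                            mismatch_quality_min = 30,
                            max_mismatches = 1,
                            sequencing_error_rate = 0.001,
                            editing_alpha = 0.05,
                            nd_min_reads = 10,
                            expr_min_sum_reads = 200,
                            expr_log2_cutoff = 0.5,
                            high_expr_min_sum = 10000,
                            expr_alpha = 0.05,
                            array_fdr_cutoff = 0.2,
                            array_log2_cutoff = 0.5,
                            seed_start = 2,
                            seed_end = 8,
                            rng_seed = 1L) {
  cfg <- list(
    quality_threshold = quality_threshold,
    max_low_quality_positions = max_low_quality_positions,
    min_read_length = min_read_length,
    max_read_length = max_read_length,
    three_prime_trim = three_prime_trim,
    mismatch_quality_min = mismatch_quality_min,
    max_mismatches = max_mismatches,
    sequencing_error_rate = sequencing_error_rate,
    editing_alpha = editing_alpha,
    nd_min_reads = nd_min_reads,
    expr_min_sum_reads = expr_min_sum_reads,
    expr_log2_cutoff = expr_log2_cutoff,
    high_expr_min_sum = high_expr_min_sum,
    expr_alpha = expr_alpha,
    array_fdr_cutoff = array_fdr_cutoff,
    array_log2_cutoff = array_log2_cutoff,
    seed_start = seed_start,
    seed_end = seed_end,
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  probs <- c("sequencing_error_rate", "editing_alpha", "expr_alpha",
             "array_fdr_cutoff")
  for (f in probs) {
    if (!num1(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(sprintf("config field '%s' must be a probability in [0,1]", f),
           call. = FALSE)
  }
  counts <- c("quality_threshold", "max_low_quality_positions",
              "min_read_length", "max_read_length", "three_prime_trim",
              "mismatch_quality_min", "max_mismatches", "nd_min_reads",
              "expr_min_sum_reads", "high_expr_min_sum",
              "seed_start", "seed_end")
  for (f in counts) {
    if (!num1(cfg[[f]]) || cfg[[f]] < 0)
      stop(sprintf("config field '%s' must be a non-negative number", f),
           call. = FALSE)
  }
  if (!num1(cfg$expr_log2_cutoff) || !num1(cfg$array_log2_cutoff) ||
      cfg$expr_log2_cutoff < 0 || cfg$array_log2_cutoff < 0)
    stop("log2 cutoffs must be non-negative", call. = FALSE)
  if (cfg$min_read_length > cfg$max_read_length)
    stop("min_read_length must not exceed max_read_length", call. = FALSE)
  if (cfg$seed_start > cfg$seed_end)
    stop("seed_start must not exceed seed_end", call. = FALSE)
  if (cfg$seed_start < 1)
    stop("seed_start must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  cat(sprintf("  quality gate: drop if > %d positions below phred %g\n",
              x$max_low_quality_positions, x$quality_threshold))
  cat(sprintf("  insert length gate: %g-%g nt; 3' trim: %g nt\n",
              x$min_read_length, x$max_read_length, x$three_prime_trim))
  cat(sprintf("  alignment: <= %g mismatch(es), mismatch phred >= %g\n",
              x$max_mismatches, x$mismatch_quality_min))
  cat(sprintf("  editing: error null %g, alpha %g, ND below %g reads, seed %g-%g\n",
              x$sequencing_error_rate, x$editing_alpha, x$nd_min_reads,
              x$seed_start, x$seed_end))
  cat(sprintf("  expression: sum > %g, |log2| >= %g, high >= %g, alpha %g\n",
              x$expr_min_sum_reads, x$expr_log2_cutoff, x$high_expr_min_sum,
              x$expr_alpha))
  cat(sprintf("  array: FDR <= %g, |log2| >= %g; rng seed %d\n",
              x$array_fdr_cutoff, x$array_log2_cutoff, x$rng_seed))
  invisible(x)
}

#' Write / read a pipeline configuration as flat key=value text
#'
#' The on-disk form is one `key=value` line per field. `read_config()`
#' starts from the defaults, so a file that omits a field yields the
#' default; the write/read round trip is lossless.
#'
#' @param cfg a [pipeline_config()] object.
#' @param path file path.
#' @return `read_config()` returns a `pipeline_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  vals <- vapply(unclass(cfg), function(v) format(v, digits = 17),
                 character(1))
  writeLines(paste0(names(cfg), "=", vals), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed config line: ", lines[which(bad)[1L]], call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  known <- names(formals(pipeline_config))
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (is.na(n)) stop("non-numeric config value: ", v, call. = FALSE)
    n
  })
  names(args) <- keys
  do.call(pipeline_config, args)
}
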