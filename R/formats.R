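# On-disk formats: FASTA / FASTQ (phred+33) / TSV count tables / TSV reports.
# Readers validate aggressively and name the offending record or cell; all
# writers round-trip exactly with their readers.

#' Decode / encode phred+33 quality strings
#'
#' @param qual character vector of phred+33 encoded quality strings.
#' @param phred list of integer phred vectors (or a single integer vector).
#' @return `phred_decode()`: a list of integer vectors, one per string;
#'   `phred_encode()`: a character vector.
#' @examples
#' phred_decode("I5")[[1]]  # 40 20
#' @export
phred_decode <- function(qual) {
  lapply(qual, function(s) utf8ToInt(s) - 33L)
}

#' @rdname phred_decode
#' @export
phred_encode <- function(phred) {
  if (!is.list(phred)) phred <- list(phred)
  vapply(phred, function(q) intToUtf8(q + 33L), character(1))
}

#' Construct a mature-miRNA reference set
#'
#' A reference set is a data frame with one row per reference sequence:
#' `id`, `sequence` (uppercase over A/C/G/T), `kind` (`mature`, `star` or
#' `precursor`) and an optional seed span.
#'
#' @param id character vector of unique reference names.
#' @param sequence character vector of nucleotide sequences.
#' @param kind reference kind, recycled.
#' @param seed_start,seed_end optional 1-based closed seed span (NA for
#'   none); must lie within the sequence when present.
#' @return A data frame of class `mirna_refs`.
#' @export
mirna_refs <- function(id, sequence, kind = "mature",
                       seed_start = NA_integer_, seed_end = NA_integer_) {
  sequence <- chartr("u", "t", toupper(sequence))
  sequence <- chartr("U", "T", sequence)
  if (any(!nzchar(sequence)))
    stop("reference sequences must be non-empty", call. = FALSE)
  if (anyDuplicated(id))
    stop("duplicate reference id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  bad <- grepl("[^ACGT]", sequence)
  if (any(bad))
    stop("illegal character in reference sequence '", id[which(bad)[1L]],
         "'", call. = FALSE)
  if (!all(kind %in% c("mature", "star", "precursor")))
    stop("kind must be one of mature/star/precursor", call. = FALSE)
  refs <- data.frame(id = as.character(id), sequence = sequence,
                     kind = rep_len(kind, length(id)),
                     seed_start = rep_len(as.integer(seed_start), length(id)),
                     seed_end = rep_len(as.integer(seed_end), length(id)),
                     stringsAsFactors = FALSE)
  has_seed <- !is.na(refs$seed_start) & !is.na(refs$seed_end)
  if (any(has_seed &
          (refs$seed_start < 1 | refs$seed_end > nchar(refs$sequence) |
           refs$seed_start > refs$seed_end)))
    stop("seed span outside the sequence", call. = FALSE)
  class(refs) <- c("mirna_refs", "data.frame")
  refs
}

#' Read a reference FASTA
#'
#' Sequences are uppercased and U converted to T; record order is
#' preserved; duplicate ids and characters outside A/C/G/T/U are rejected
#' (naming the offending line).
#'
#' @param path FASTA file path.
#' @param kind reference kind assigned to every record.
#' @return A [mirna_refs] data frame (zero rows for an empty file).
#' @export
read_fasta <- function(path, kind = "mature") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L)
    return(mirna_refs(character(0), character(0)))
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e)
                    stop("malformed FASTA in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- chartr("Uu", "Tt", toupper(as.character(set)))
  bad <- regexpr("[^ACGT]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1L]
    # locate the offending line for the error message
    lines <- readLines(path, warn = FALSE)
    hit <- which(!startsWith(lines, ">") &
                   grepl("[^ACGTUacgtu[:space:]]", lines))
    where <- if (length(hit)) paste0(" (line ", hit[1L], ")") else ""
    stop("illegal character in sequence of '", ids[i], "'", where,
         call. = FALSE)
  }
  mirna_refs(ids, seqs, kind = kind)
}

#' Write a reference set as FASTA
#'
#' @param refs a [mirna_refs] data frame.
#' @param path output path.
#' @export
write_fasta <- function(refs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(refs))
    writeLines(paste0(">", refs$id, "\n", refs$sequence), con, sep = "\n")
  invisible(path)
}

#' Read / write FASTQ (phred+33)
#'
#' Reads are returned as a data frame with columns `id`, `seq` and `qual`
#' (the phred+33 quality string); use [phred_decode()] for integer phreds.
#' Truncated records and base/quality length mismatches are rejected with
#' the record index.
#'
#' @param path FASTQ file path.
#' @param reads a read data frame as returned by `read_fastq()`.
#' @return `read_fastq()`: a data frame of reads.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop("truncated FASTQ record ", n %/% 4L + 1L, " in ", path,
         call. = FALSE)
  if (n == 0L)
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  hdr <- lines[seq(1L, n, 4L)]
  sep <- lines[seq(3L, n, 4L)]
  bad <- !startsWith(hdr, "@") | !startsWith(sep, "+")
  if (any(bad))
    stop("malformed FASTQ record ", which(bad)[1L], " in ", path,
         call. = FALSE)
  seqs <- toupper(lines[seq(2L, n, 4L)])
  qual <- lines[seq(4L, n, 4L)]
  mism <- nchar(seqs) != nchar(qual)
  if (any(mism))
    stop("base/quality length mismatch in FASTQ record ", which(mism)[1L],
         " in ", path, call. = FALSE)
  data.frame(id = sub("^@", "", sub("\\s.*$", "", hdr)), seq = seqs,
             qual = qual, stringsAsFactors = FALSE)
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads))
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual),
               con)
  invisible(path)
}

#' Read a per-sample count table
#'
#' Expects a TSV with a header row of sample names and the miRNA id in the
#' first column. Thousands separators ("61,575") are accepted and
#' stripped, so published tables can be pasted verbatim; any other
#' non-numeric cell is rejected with its row and column.
#'
#' @param path TSV file path.
#' @return A numeric matrix (miRNAs x samples) with a `normalized`
#'   attribute (FALSE on read).
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("count table needs an id column and at least one sample",
         call. = FALSE)
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate miRNA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  stripped <- gsub(",", "", cells, fixed = TRUE)
  vals <- suppressWarnings(as.numeric(stripped))
  bad <- is.na(vals) | !nzchar(trimws(stripped))
  if (any(bad)) {
    i <- which(bad)[1L]
    r <- (i - 1L) %% nrow(cells) + 1L
    c <- (i - 1L) %/% nrow(cells) + 1L
    stop(sprintf("non-numeric cell '%s' at row %d, column '%s'",
                 cells[r, c], r, colnames(cells)[c]), call. = FALSE)
  }
  m <- matrix(vals, nrow = nrow(cells),
              dimnames = list(ids, colnames(cells)))
  if (any(m < 0)) stop("negative count in table", call. = FALSE)
  attr(m, "normalized") <- FALSE
  m
}

#' @rdname read_count_table
#' @param counts a numeric matrix (miRNAs x samples).
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(miRNA = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a report TSV
#'
#' Writes any rectangular set of report rows as TSV with a header. Columns
#' holding editing levels are printed as percentages with one decimal and
#' `NA` cells in them become the literal `ND` (the published convention for
#' sites with fewer than 10 reads). By default any column whose name
#' contains "level" is treated as a level column holding proportions in
#' [0,1]; set `percent = TRUE` when the values are already percentages
#' (as in editing-call tables).
#'
#' @param records a data frame of report rows.
#' @param path output path.
#' @param level_cols names of the level columns (default: autodetected).
#' @param percent logical; are level values already on the 0-100 scale?
#' @export
write_report <- function(records, path,
                         level_cols = grep("level", names(records),
                                           value = TRUE),
                         percent = FALSE) {
  out <- records
  for (cl in intersect(level_cols, names(out))) {
    v <- out[[cl]]
    if (is.numeric(v)) {
      pct <- if (percent) v else 100 * v
      out[[cl]] <- ifelse(is.na(v), "ND", sprintf("%.1f", pct))
    }
  }
  for (cl in setdiff(names(out), level_cols)) {
    if (anyNA(out[[cl]]) && !is.numeric(out[[cl]]))
      out[[cl]][is.na(out[[cl]])] <- "ND"
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
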