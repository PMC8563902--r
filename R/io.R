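#' Read a FASTQ file into a read table
#'
#' Reads plain or gzipped FASTQ (autodetected by suffix) into the package's
#' read-table representation: a `data.frame` with columns `id`, `seq`,
#' `qual` (Phred+33 strings).  Lower-case bases are upper-cased.
#'
#' @param path FASTQ file path (`.gz` autodetected).
#' @return a `data.frame` with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  out <- tryCatch({
    n_lines <- length(readLines(path, warn = FALSE))
    if (n_lines %% 4L != 0L)
      stop(sprintf("truncated record %d", n_lines %/% 4L + 1L))
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    qual <- as.character(S4Vectors::mcols(x)$qualities)
    data.frame(id = names(x), seq = toupper(as.character(x)),
               qual = qual, stringsAsFactors = FALSE)
  }, error = function(e)
    stop(sprintf("FASTQ parse error in '%s': %s", path, conditionMessage(e)),
         call. = FALSE))
  rownames(out) <- NULL
  validate_read_table(out)
  out
}

#' Write a read table to FASTQ
#'
#' @param reads a read table (`id`, `seq`, `qual`).
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  validate_read_table(reads)
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, filepath = path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

#' Validate a read table
#'
#' Enforces the read-record invariants: per-record sequence and quality
#' strings of equal length, and (when present) a `umi` column matching
#' `[ACGTN]{k}`.
#'
#' @param reads a read table.
#' @return `reads`, invisibly; errors on violation.
#' @export
validate_read_table <- function(reads) {
  stopifnot(is.data.frame(reads),
            all(c("id", "seq", "qual") %in% names(reads)))
  bad <- which(nchar(reads$seq) != nchar(reads$qual))
  if (length(bad))
    stop(sprintf("seq/qual length mismatch at record %d ('%s')",
                 bad[1], reads$id[bad[1]]), call. = FALSE)
  if ("umi" %in% names(reads)) {
    u <- reads$umi[!is.na(reads$umi)]
    if (length(u) && !all(grepl("^[ACGTN]+$", u)))
      stop("umi values must match [ACGTN]+", call. = FALSE)
  }
  invisible(reads)
}

#' Read a FASTA file
#'
#' @param path FASTA path (plain or gzipped); multi-line records accepted.
#' @return a named character vector of upper-cased sequences (empty for an
#'   empty file).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector, or a `trna_reference` table.
#' @param path output path; `.gz` triggers compression.
#' @param width line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$sequence, seqs$ref_id)
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, format = "fasta",
                              width = width, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write a report table as TSV with '#' metadata header lines
#'
#' @param table a data.frame.
#' @param path output path.
#' @param metadata named character vector written as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(table, path, metadata = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(metadata))
    writeLines(sprintf("# %s: %s", names(metadata), unname(metadata)), con)
  write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a TSV report written by [write_tsv_report()]
#'
#' @param path TSV path.
#' @return a data.frame; metadata lines are returned in the `"metadata"`
#'   attribute.
#' @export
read_tsv_report <- function(path) {
  lines <- readLines(path, n = 100L)
  meta <- grep("^#", lines, value = TRUE)
  out <- read.delim(path, comment.char = "#", sep = "\t",
                    stringsAsFactors = FALSE)
  attr(out, "metadata") <- sub("^# ", "", meta)
  out
}

#' Write alignment records as minimal SAM
#'
#' Write-only interoperability output: a header with the reference set and
#' one line per aligned read (fields through CIGAR plus sequence; mapping
#' quality fixed at 255).
#'
#' @param alns alignment table from [align_reads()].
#' @param refs `trna_reference` table (or named sequences) for the header.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alns, refs, path) {
  if (is.data.frame(refs)) refs <- setNames(refs$sequence, refs$ref_id)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(refs), nchar(refs)), con)
  seqcol <- if ("seq" %in% names(alns)) alns$seq else rep("*", nrow(alns))
  writeLines(sprintf("%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*",
                     alns$read_id, alns$ref_id, alns$ref_start + 1L,
                     alns$cigar, seqcol), con)
  invisible(path)
}
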