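#' Preprocessing configuration
#'
#' @param adapter3 3' adapter sequence (default from [library_design()]).
#' @param min_quality Phred threshold for 3' quality trimming (default 20).
#' @param min_overlap minimum adapter suffix-prefix overlap in nt
#'   (default 5).
#' @param mismatch_tol per-base adapter mismatch tolerance as a fraction of
#'   the overlap (default 0.1).
#' @param umi_length 5' random-barcode length (default 10).
#' @param footprint_min,footprint_max qualified ribosome-footprint length
#'   window (defaults 25 and 33 nt).
#' @return a list of class `preprocess_config`; a config hash is attached so
#'   paired library arms can be checked for identical settings.
#' @export
preprocess_config <- function(adapter3 = library_design()$adapter3,
                              min_quality = 20L, min_overlap = 5L,
                              mismatch_tol = 0.1, umi_length = 10L,
                              footprint_min = 25L, footprint_max = 33L) {
  stopifnot(footprint_min > 0, footprint_min <= footprint_max,
            min_quality >= 0, min_overlap >= 1,
            mismatch_tol >= 0, mismatch_tol < 1)
  cfg <- list(adapter3 = adapter3, min_quality = as.integer(min_quality),
              min_overlap = as.integer(min_overlap),
              mismatch_tol = mismatch_tol,
              umi_length = as.integer(umi_length),
              footprint_min = as.integer(footprint_min),
              footprint_max = as.integer(footprint_max))
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "preprocess_config")
}

config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(unlist(x)), unlist(x), sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

#' Trim 3' adapter and low-quality tails from reads
#'
#' The adapter is removed at the longest suffix-prefix match of at least
#' `min_overlap` nt, allowing `floor(mismatch_tol * overlap)` mismatches;
#' then 3' bases are trimmed with the BWA-style running-sum algorithm at
#' `min_quality`.  Reads that become empty are discarded (a normal outcome,
#' counted in the `"summary"` attribute).
#'
#' @param reads a read table.
#' @param cfg a [preprocess_config()].
#' @return the trimmed read table; discarded reads removed; attribute
#'   `"summary"` holds input/kept/discarded counts and the config hash.
#' @export
trim_reads <- function(reads, cfg = preprocess_config()) {
  validate_read_table(reads)
  n_in <- nrow(reads)
  if (n_in == 0L) {
    out <- reads
    attr(out, "summary") <- list(input = 0L, kept = 0L, discarded = 0L,
                                 config_hash = cfg$hash)
    return(out)
  }
  apos <- cpp_find_adapter(reads$seq, cfg$adapter3, cfg$min_overlap,
                           cfg$mismatch_tol)
  seq <- substr(reads$seq, 1L, apos)
  qual <- substr(reads$qual, 1L, apos)
  keep_len <- cpp_qual_trim(qual, cfg$min_quality, 33L)
  seq <- substr(seq, 1L, keep_len)
  qual <- substr(qual, 1L, keep_len)
  ok <- nchar(seq) > 0L
  out <- data.frame(id = reads$id[ok], seq = seq[ok], qual = qual[ok],
                    stringsAsFactors = FALSE)
  attr(out, "summary") <- list(input = n_in, kept = sum(ok),
                               discarded = n_in - sum(ok),
                               config_hash = cfg$hash)
  out
}

#' Trim a single read
#'
#' Single-record convenience wrapper around [trim_reads()].
#'
#' @param read a one-row read table (or list with `id`, `seq`, `qual`).
#' @param cfg a [preprocess_config()].
#' @return a one-row read table, or `NULL` when the read is discarded.
#' @export
trim_read <- function(read, cfg = preprocess_config()) {
  rd <- as.data.frame(read, stringsAsFactors = FALSE)
  out <- trim_reads(rd, cfg)
  if (nrow(out) == 0L) NULL else out
}

#' Extract the 5' random barcode (UMI) from reads
#'
#' The first `umi_length` bases (and qualities) are split off into a `umi`
#' column; reads not longer than the barcode are discarded.
#'
#' @param reads a read table.
#' @param umi_length barcode length (default 10).
#' @return the read table with `seq`/`qual` shortened and a `umi` column;
#'   attribute `"summary"` counts discards.
#' @export
extract_umi <- function(reads, umi_length = 10L) {
  validate_read_table(reads)
  ok <- nchar(reads$seq) > umi_length
  out <- reads[ok, , drop = FALSE]
  out$umi <- substr(out$seq, 1L, umi_length)
  out$seq <- substr(out$seq, umi_length + 1L, nchar(out$seq))
  out$qual <- substr(out$qual, umi_length + 1L, nchar(out$qual))
  rownames(out) <- NULL
  attr(out, "summary") <- list(input = nrow(reads), kept = sum(ok),
                               discarded = sum(!ok))
  out
}

#' Keep qualified ribosome footprints by length
#'
#' Retains trimmed reads whose length lies in
#' `[footprint_min, footprint_max]` (default 25-33 nt).
#'
#' @param reads a read table.
#' @param cfg a [preprocess_config()].
#' @return the filtered read table with a `"summary"` attribute.
#' @export
filter_footprints <- function(reads, cfg = preprocess_config()) {
  validate_read_table(reads)
  len <- nchar(reads$seq)
  ok <- len >= cfg$footprint_min & len <= cfg$footprint_max
  out <- reads[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "summary") <- list(input = nrow(reads), kept = sum(ok),
                               discarded = sum(!ok))
  out
}
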