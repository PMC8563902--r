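#' Alignment parameters
#'
#' Scoring for the self-contained glocal aligner (read aligned end-to-end,
#' reference ends free).  A gap of length L costs
#' `gap_open + L * gap_extend`.  Up to `clip` bases at either read end may
#' be soft-clipped at zero penalty to absorb residual adapter or ligation
#' bases.  Alignments scoring below `min_score_fraction * read_length *
#' match` are reported unaligned.
#'
#' @param match match score (default +1).
#' @param mismatch mismatch score (default -1).
#' @param gap_open gap opening score (default -3).
#' @param gap_extend per-base gap extension score (default -1).
#' @param min_score_fraction minimum score as a fraction of the read's
#'   maximum attainable score (default 0.8).
#' @param multimap_policy tie handling: `"best-unique"` (drop ties),
#'   `"random-tiebreak"` (seeded uniform pick) or `"drop"`.
#' @param clip maximum zero-penalty soft-clip per read end (default 2).
#' @param seed seed for `"random-tiebreak"`.
#' @return a list of class `align_params`.
#' @export
align_params <- function(match = 1L, mismatch = -1L, gap_open = -3L,
                         gap_extend = -1L, min_score_fraction = 0.8,
                         multimap_policy = c("best-unique",
                                             "random-tiebreak", "drop"),
                         clip = 2L, seed = 1L) {
  multimap_policy <- match.arg(multimap_policy)
  stopifnot(is.finite(match), is.finite(mismatch), is.finite(gap_open),
            is.finite(gap_extend),
            min_score_fraction > 0, min_score_fraction <= 1)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_score_fraction = min_score_fraction,
                 multimap_policy = multimap_policy,
                 clip = as.integer(clip), seed = as.integer(seed)),
            class = "align_params")
}

ref_sequences <- function(refs) {
  if (is.data.frame(refs)) setNames(refs$sequence, refs$ref_id)
  else if (is.character(refs) && !is.null(names(refs))) refs
  else stop("`refs` must be a reference table or named character vector")
}

#' Align one read against a reference set (full dynamic programming)
#'
#' Runs the full glocal affine DP against every reference and returns the
#' best hit.  `is_unique` is `FALSE` when two or more references tie at the
#' best score.
#'
#' @param read a read sequence (single string).
#' @param refs reference table or named sequences.
#' @param params an [align_params()].
#' @return a one-row `data.frame` (`read_id = NA`) with `ref_id`,
#'   `ref_start` (0-based), `score`, `n_mismatch`, `cigar`, `is_unique`,
#'   plus attribute `"hits"` holding the per-reference score table;
#'   `NULL` when no alignment reaches the score threshold.
#' @export
align_read <- function(read, refs, params = align_params()) {
  stopifnot(is.character(read), length(read) == 1L, nchar(read) > 0L)
  rs <- ref_sequences(refs)
  stopifnot(length(rs) > 0L)
  res <- cpp_align_one(read, unname(rs), params$match, params$mismatch,
                       params$gap_open, params$gap_extend, params$clip)
  hits <- data.frame(ref_id = names(rs), score = res$score,
                     ref_start = res$ref_start, n_mismatch = res$n_mismatch,
                     cigar = res$cigar, stringsAsFactors = FALSE)
  hits <- hits[res$ok, , drop = FALSE]
  if (nrow(hits) == 0L) return(NULL)
  best <- max(hits$score)
  if (best < params$min_score_fraction * nchar(read) * params$match)
    return(NULL)
  top <- hits[hits$score == best, , drop = FALSE]
  out <- data.frame(read_id = NA_character_, ref_id = top$ref_id[1],
                    ref_start = top$ref_start[1], score = best,
                    n_mismatch = top$n_mismatch[1], cigar = top$cigar[1],
                    is_unique = nrow(top) == 1L, stringsAsFactors = FALSE)
  attr(out, "hits") <- hits
  out
}

#' Resolve multi-mapping alignments
#'
#' @param alns a data.frame of candidate hits for one read (equal-score rows
#'   are the ties).
#' @param policy `"best-unique"`, `"random-tiebreak"` or `"drop"`.
#' @param seed seed for the random tie-break.
#' @return a one-row data.frame, or `NULL` when the read is dropped.
#' @export
resolve_multimap <- function(alns, policy = "best-unique", seed = 1L) {
  if (!policy %in% c("best-unique", "random-tiebreak", "drop"))
    stop(sprintf("unknown multimap policy '%s'", policy), call. = FALSE)
  best <- max(alns$score)
  top <- alns[alns$score == best, , drop = FALSE]
  if (nrow(top) == 1L) return(top)
  switch(policy,
         "best-unique" = NULL,
         "drop" = NULL,
         "random-tiebreak" = with_seed(seed, top[sample.int(nrow(top), 1L), ,
                                                 drop = FALSE]))
}

#' Align a read set against a reference set
#'
#' Batch aligner used by the pipeline.  A provably-safe ungapped screen
#' (accepted only when no gapped alignment could score higher) handles the
#' bulk of reads at C speed; everything else falls back to the same full
#' glocal DP as [align_read()].  Identical reference sequences must be
#' collapsed beforehand (see [collapse_identical_refs()]).
#'
#' @param reads a read table (optionally with a `umi` column).
#' @param refs reference table or named sequences.
#' @param params an [align_params()]; `multimap_policy` is applied to tied
#'   best hits.
#' @return a data.frame with one row per aligned, multimap-resolved read:
#'   `read_id`, `ref_id`, `ref_start` (0-based), `score`, `n_mismatch`,
#'   `cigar`, `seq`, `qwidth`, `is_unique` and (if present) `umi`.
#'   Attribute `"summary"` counts input/aligned/unaligned/multimapped reads.
#' @export
align_reads <- function(reads, refs, params = align_params()) {
  validate_read_table(reads)
  rs <- ref_sequences(refs)
  if (anyDuplicated(unname(rs)))
    stop("reference sequences must be unique; run collapse_identical_refs()",
         call. = FALSE)
  res <- cpp_align_batch(reads$seq, unname(rs), params$match,
                         params$mismatch, params$gap_open,
                         params$gap_extend, params$clip,
                         params$min_score_fraction)
  aligned <- !is.na(res$ref)
  multi <- aligned & res$n_best > 1L
  keep <- aligned & !multi
  if (params$multimap_policy == "random-tiebreak" && any(multi)) {
    pick <- with_seed(params$seed, {
      lapply(which(multi), function(q) {
        hits <- align_read(reads$seq[q], rs, params)
        h <- attr(hits, "hits")
        top <- h[h$score == max(h$score), , drop = FALSE]
        top[sample.int(nrow(top), 1L), , drop = FALSE]
      })
    })
    pick <- do.call(rbind, pick)
  }
  out <- data.frame(
    read_id = reads$id[keep],
    ref_id = names(rs)[res$ref[keep]],
    ref_start = res$ref_start[keep],
    score = res$score[keep],
    n_mismatch = res$n_mismatch[keep],
    cigar = res$cigar[keep],
    seq = reads$seq[keep],
    qwidth = nchar(reads$seq[keep]),
    is_unique = TRUE,
    stringsAsFactors = FALSE
  )
  if ("umi" %in% names(reads)) out$umi <- reads$umi[keep]
  if (params$multimap_policy == "random-tiebreak" && any(multi)) {
    add <- data.frame(
      read_id = reads$id[multi], ref_id = pick$ref_id,
      ref_start = pick$ref_start, score = pick$score,
      n_mismatch = pick$n_mismatch, cigar = pick$cigar,
      seq = reads$seq[multi], qwidth = nchar(reads$seq[multi]),
      is_unique = FALSE, stringsAsFactors = FALSE
    )
    if ("umi" %in% names(reads)) add$umi <- reads$umi[multi]
    out <- rbind(out, add)
  }
  rownames(out) <- NULL
  attr(out, "summary") <- list(
    input = nrow(reads), aligned = sum(aligned),
    unaligned = sum(!aligned), multimapped = sum(multi),
    multimap_policy = params$multimap_policy
  )
  out
}
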