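#' Codon frequency profile of a CDS
#'
#' Counts codons over the internal region (positions 2 to L/3 - 1; the
#' start codon and the stop are excluded by default) and normalizes over the
#' 61 sense codons.  Internal stop codons trigger a warning and are flagged
#' but excluded from the sense-codon denominator.
#'
#' @param cds in-frame CDS string (length a multiple of 3).
#' @param include_start count the start codon too (default `FALSE`).
#' @return a list of class `codon_profile` with `counts` and `frequencies`
#'   (named over the sense codons) and `n_internal_stops`.
#' @export
#' @examples
#' p <- codon_frequencies("ATGGCTGCTAGCTAA")
#' p$frequencies[c("GCT", "AGC")]  # 2/3, 1/3
codon_frequencies <- function(cds, include_start = FALSE) {
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length must be a multiple of 3", call. = FALSE)
  n <- nchar(cds) / 3L
  from <- if (include_start) 1L else 2L
  if (n - 1L < from)
    stop("CDS has no internal codons to count", call. = FALSE)
  starts <- seq.int(from, n - 1L) * 3L - 2L
  codons <- substring(cds, starts, starts + 2L)
  sense <- sense_codons()
  n_stop <- sum(codons %in% STOP_CODONS)
  if (n_stop > 0)
    warning(sprintf("%d internal stop codon(s) found", n_stop))
  counts <- table(factor(codons[codons %in% sense], levels = sense))
  counts <- setNames(as.integer(counts), sense)
  total <- sum(counts)
  structure(list(counts = counts,
                 frequencies = if (total > 0) counts / total
                               else setNames(rep(NA_real_, 61), sense),
                 n_internal_stops = n_stop),
            class = "codon_profile")
}

#' Codon frequency matrix for a transcript set
#'
#' @param transcripts a [make_transcriptome()] table (or named CDS vector).
#' @param include_start count start codons (default `FALSE`).
#' @return numeric matrix (genes x 61 sense codons) of frequencies.
#' @export
codon_profiles <- function(transcripts, include_start = FALSE) {
  cds <- if (is.data.frame(transcripts))
    setNames(transcripts$cds, transcripts$gene_id) else transcripts
  out <- t(vapply(cds, function(s)
    codon_frequencies(s, include_start)$frequencies,
    numeric(61)))
  rownames(out) <- names(cds)
  out
}

#' Transcriptome rank percentile of a codon's frequency
#'
#' The fraction of transcripts with strictly greater frequency of `codon`
#' than the queried transcript ("top X%" means percentile <= X/100; ties
#' rank equal under the strict-greater convention).
#'
#' @param transcript_id queried transcript.
#' @param codon a sense codon.
#' @param profiles matrix from [codon_profiles()] (>= 2 transcripts).
#' @return percentile in `[0, 1)`.
#' @export
codon_rank_percentile <- function(transcript_id, codon, profiles) {
  if (!transcript_id %in% rownames(profiles))
    stop(sprintf("unknown transcript '%s'", transcript_id), call. = FALSE)
  if (!codon %in% colnames(profiles))
    stop(sprintf("unknown codon '%s'", codon), call. = FALSE)
  if (nrow(profiles) < 2L) stop("need at least 2 transcripts")
  v <- profiles[, codon]
  mean(v > v[transcript_id])
}

#' Permutation test for target-codon enrichment in a TE-up gene set
#'
#' Statistic: mean summed target-codon frequency in the TE-up set minus the
#' background set.  The label permutation p-value is
#' `(1 + #{permuted >= observed}) / (n_perm + 1)`.
#'
#' @param te_up_ids,background_ids disjoint, non-empty gene-id sets.
#' @param target_codons codons decoded by the m1A-elevated tRNAs.
#' @param profiles matrix from [codon_profiles()].
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return a list of class `enrichment_test` with `statistic`, `p_value`,
#'   `n_up`, `n_background`, `n_perm`, `target_codons`.
#' @export
te_codon_enrichment <- function(te_up_ids, background_ids, target_codons,
                                profiles, n_perm = 1000L, seed = 1L) {
  if (length(intersect(te_up_ids, background_ids)))
    stop("te_up and background sets must be disjoint", call. = FALSE)
  if (!length(te_up_ids) || !length(background_ids))
    stop("both gene sets must be non-empty", call. = FALSE)
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  stopifnot(all(target_codons %in% colnames(profiles)),
            all(c(te_up_ids, background_ids) %in% rownames(profiles)))
  v <- rowSums(profiles[c(te_up_ids, background_ids), target_codons,
                        drop = FALSE])
  n1 <- length(te_up_ids)
  n <- length(v)
  obs <- mean(v[seq_len(n1)]) - mean(v[(n1 + 1):n])
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ix <- sample.int(n, n1)
      mean(v[ix]) - mean(v[-ix])
    }, numeric(1))
  })
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  structure(list(statistic = obs, p_value = p, n_up = n1,
                 n_background = n - n1, n_perm = as.integer(n_perm),
                 target_codons = target_codons),
            class = "enrichment_test")
}

#' Codons decoded by the m1A-elevated tRNAs
#'
#' Union of decoded codons over the tRNAs flagged `elevated_in_B` in a
#' differential-methylation table.  Anticodons are parsed from the
#' `family-anticodon-copy` ref-id pattern (joint ids from collapsed
#' references are split first).
#'
#' @param diff a [differential_m1a()] table.
#' @param wobble use the wobble-expanded decoding table (default `FALSE`,
#'   the narrow exact table).
#' @return character vector of codons (possibly empty).
#' @export
#' @examples
#' # tRNA-Ala-AGC decodes GCT under the exact table
linked_codons <- function(diff, wobble = FALSE) {
  ids <- diff$ref_id[diff$elevated_in_B]
  if (!length(ids)) return(character(0))
  ids <- unlist(strsplit(ids, "|", fixed = TRUE))
  anticodon <- vapply(strsplit(ids, "-", fixed = TRUE), function(p) {
    if (length(p) < 3L) stop(sprintf("cannot parse anticodon from '%s'",
                                     paste(p, collapse = "-")))
    p[3]
  }, character(1))
  sort(unique(decoded_codons(anticodon, wobble = wobble)))
}

#' Dual-luciferase translation index
#'
#' Firefly/Renilla ratio of the codon-insert reporter normalized by the
#' same ratio of the no-insert control vector, removing transfection-level
#' and inherent translation differences between cell lines.
#'
#' @param test,control lists (or one-row data.frames) with `f_luc` and
#'   `r_luc` luminescence values; `r_luc` must be positive.
#' @return the normalized translation index
#'   `(test F/R) / (control F/R)`.
#' @export
#' @examples
#' normalize_reporter(list(f_luc = 4, r_luc = 2),
#'                    list(f_luc = 1, r_luc = 1))  # 2
normalize_reporter <- function(test, control) {
  for (m in list(test, control)) {
    if (!is.numeric(m$r_luc) || m$r_luc <= 0)
      stop("r_luc must be positive", call. = FALSE)
  }
  (test$f_luc / test$r_luc) / (control$f_luc / control$r_luc)
}
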