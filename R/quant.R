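#' Site-calling configuration
#'
#' Thresholds for m1A58 calling from the demethylation contrast.  A site is
#' called when both arms reach `min_coverage` at the position-58 adenosine
#' and the untreated-minus-demethylated misincorporation difference is at
#' least `delta_min`.  Stoichiometry bands follow the observation that
#' highly methylated tRNAs leave little room for further elevation while
#' medium-level tRNAs do: `low` < 0.3 <= `medium` < 0.9 <= `high`.
#'
#' @param min_coverage minimum deduplicated coverage per arm (default 50).
#' @param delta_min minimum untreated-minus-demethylated rate difference for
#'   a call (default 0.05).
#' @param background_subtract report `delta` instead of the raw untreated
#'   rate as the stoichiometry (default `FALSE`; the raw misincorporation
#'   rate represents the stoichiometry).
#' @param band_bounds numeric `c(medium_lo, high_lo)` (default 0.3, 0.9).
#' @param elevation_min minimum cross-condition stoichiometry increase to
#'   flag a tRNA as elevated (default 0.05).
#' @return a list of class `call_config`.
#' @export
call_config <- function(min_coverage = 50L, delta_min = 0.05,
                        background_subtract = FALSE,
                        band_bounds = c(0.3, 0.9), elevation_min = 0.05) {
  stopifnot(min_coverage >= 1, delta_min > 0, delta_min < 1,
            length(band_bounds) == 2L, band_bounds[1] < band_bounds[2],
            elevation_min > 0)
  structure(list(min_coverage = as.integer(min_coverage),
                 delta_min = delta_min,
                 background_subtract = isTRUE(background_subtract),
                 band_bounds = band_bounds,
                 elevation_min = elevation_min),
            class = "call_config")
}

#' Remove PCR duplicates by mapping position and barcode
#'
#' Reads aligned to an identical `(ref_id, ref_start)` position carrying the
#' same 10-nt random barcode are PCR duplicates; one representative is kept
#' per key — the first record in a stable sort by `read_id`, so the result
#' is deterministic.
#'
#' @param alns alignment table from [align_reads()]; every record must carry
#'   a `umi`.
#' @return the deduplicated alignment table; attribute `"summary"` holds
#'   input/kept/duplicate counts.
#' @export
dedup <- function(alns) {
  if (!"umi" %in% names(alns) || anyNA(alns$umi))
    stop("every alignment record must carry a umi", call. = FALSE)
  ord <- order(alns$read_id, method = "radix")
  x <- alns[ord, , drop = FALSE]
  key <- paste(x$ref_id, x$ref_start, x$umi, sep = "\r")
  keep <- !duplicated(key)
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "summary") <- list(input = nrow(alns), kept = sum(keep),
                               duplicates = nrow(alns) - sum(keep))
  out
}

#' Per-position base counts from deduplicated alignments
#'
#' Tabulates aligned read bases per reference position.  `N` bases are
#' skipped entirely; deletions are tracked in their own column and excluded
#' from coverage (read-through chemistry yields mismatches, not gaps).
#'
#' @param alns deduplicated alignment table.
#' @param refs reference table or named sequences.
#' @return a `data.frame` of class `pileup`: `ref_id`, `pos` (0-based),
#'   `ref_base`, `A`, `C`, `G`, `T`, `deletions`, `coverage`.
#' @export
pileup <- function(alns, refs) {
  rs <- ref_sequences(refs)
  unknown <- setdiff(unique(alns$ref_id), names(rs))
  if (length(unknown))
    stop(sprintf("alignment references unknown ref '%s'", unknown[1]),
         call. = FALSE)
  ridx <- match(alns$ref_id, names(rs))
  mats <- cpp_pileup(ridx, alns$ref_start, alns$cigar, alns$seq,
                     nchar(unname(rs)))
  out_l <- lapply(seq_along(rs), function(r) {
    m <- mats[[r]]
    len <- ncol(m)
    data.frame(ref_id = names(rs)[r], pos = seq_len(len) - 1L,
               ref_base = strsplit(unname(rs[r]), "")[[1]],
               A = m[1, ], C = m[2, ], G = m[3, ], T = m[4, ],
               deletions = m[5, ],
               coverage = colSums(m[1:4, , drop = FALSE]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out_l)
  rownames(out) <- NULL
  class(out) <- c("pileup", "data.frame")
  out
}

#' Misincorporation rate at pileup positions
#'
#' The fraction of aligned bases differing from the reference base:
#' `(coverage - count(ref_base)) / coverage`.  Returns `NA` (undefined, as
#' distinct from 0) where coverage is zero.
#'
#' @param p a `pileup` table (or subset of rows).
#' @param ref_base optional override of the per-row reference base.
#' @return numeric vector of rates in `[0, 1]`, `NA` at zero coverage.
#' @export
mismatch_rate <- function(p, ref_base = p$ref_base) {
  counts <- as.matrix(p[, c("A", "C", "G", "T")])
  refn <- counts[cbind(seq_len(nrow(p)), match(ref_base, c("A", "C", "G", "T")))]
  rate <- (p$coverage - refn) / p$coverage
  rate[p$coverage == 0L] <- NA_real_
  rate
}

#' Call m1A58 sites from the demethylation contrast
#'
#' For each tRNA's position-58 adenosine, computes the misincorporation rate
#' in the untreated and demethylated arms.  A site is called when both arms
#' reach `min_coverage` and the rate difference (`delta`) is at least
#' `delta_min`; the modification stoichiometry is the untreated
#' misincorporation rate (or `delta` under `background_subtract`).
#' Uncovered sites are recorded with `min_cov_ok = FALSE`, never dropped.
#'
#' @param pu_untreated,pu_demethylated `pileup` tables for the two arms.
#' @param refs a `trna_reference` table.
#' @param cfg a [call_config()].
#' @return a `data.frame` of class `m1a_calls`: `ref_id`, `position`
#'   (0-based a58 index), `mism_untreated`, `mism_demethylated`, `delta`,
#'   `stoichiometry`, `cov_untreated`, `cov_demethylated`, `min_cov_ok`,
#'   `called`, `band`.
#' @export
call_m1a58 <- function(pu_untreated, pu_demethylated, refs,
                       cfg = call_config()) {
  key_u <- paste(pu_untreated$ref_id, pu_untreated$pos)
  key_d <- paste(pu_demethylated$ref_id, pu_demethylated$pos)
  want <- paste(refs$ref_id, refs$a58_index)
  iu <- match(want, key_u)
  id <- match(want, key_d)
  cov_u <- ifelse(is.na(iu), 0L, pu_untreated$coverage[iu])
  cov_d <- ifelse(is.na(id), 0L, pu_demethylated$coverage[id])
  rate_u <- rep(NA_real_, nrow(refs))
  rate_d <- rep(NA_real_, nrow(refs))
  rate_u[!is.na(iu)] <- mismatch_rate(pu_untreated[iu[!is.na(iu)], ,
                                                   drop = FALSE])
  rate_d[!is.na(id)] <- mismatch_rate(pu_demethylated[id[!is.na(id)], ,
                                                      drop = FALSE])
  delta <- rate_u - rate_d
  min_cov_ok <- cov_u >= cfg$min_coverage & cov_d >= cfg$min_coverage
  called <- min_cov_ok & !is.na(delta) & delta >= cfg$delta_min
  stoich <- if (cfg$background_subtract) delta else rate_u
  band <- cut(stoich, breaks = c(-Inf, cfg$band_bounds, Inf),
              labels = c("low", "medium", "high"), right = FALSE)
  out <- data.frame(ref_id = refs$ref_id, position = refs$a58_index,
                    mism_untreated = rate_u, mism_demethylated = rate_d,
                    delta = delta, stoichiometry = stoich,
                    cov_untreated = cov_u, cov_demethylated = cov_d,
                    min_cov_ok = min_cov_ok, called = called,
                    band = as.character(band), stringsAsFactors = FALSE)
  class(out) <- c("m1a_calls", "data.frame")
  out
}

#' Cross-condition differential m1A58 methylation
#'
#' Per-tRNA stoichiometry difference between two conditions.  A tRNA is
#' `elevated_in_B` when it is called in both conditions and its
#' stoichiometry increase reaches `elevation_min`.  tRNAs present (called)
#' in only one condition are reported with `missing_condition = TRUE` and
#' excluded from the elevated set.  Output sorted by `diff`, descending.
#'
#' @param calls_A,calls_B `m1a_calls` tables for the two conditions.
#' @param cfg a [call_config()].
#' @return a `data.frame` of class `diff_m1a`: `ref_id`, `stoich_A`,
#'   `stoich_B`, `diff`, `band` (from the lower-stoichiometry condition),
#'   `elevated_in_B`, `missing_condition`.
#' @export
differential_m1a <- function(calls_A, calls_B, cfg = call_config()) {
  ids <- union(calls_A$ref_id, calls_B$ref_id)
  ia <- match(ids, calls_A$ref_id)
  ib <- match(ids, calls_B$ref_id)
  sA <- calls_A$stoichiometry[ia]
  sB <- calls_B$stoichiometry[ib]
  cA <- !is.na(ia) & calls_A$called[ia]
  cB <- !is.na(ib) & calls_B$called[ib]
  d <- sB - sA
  lower_band <- ifelse(!is.na(sA) & !is.na(sB) & sA <= sB,
                       calls_A$band[ia], calls_B$band[ib])
  out <- data.frame(ref_id = ids, stoich_A = sA, stoich_B = sB, diff = d,
                    band = lower_band,
                    elevated_in_B = cA & cB & !is.na(d) &
                      d >= cfg$elevation_min,
                    missing_condition = xor(is.na(ia), is.na(ib)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$diff, out$ref_id, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("diff_m1a", "data.frame")
  out
}
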