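#' Footprint profiles per transcript
#'
#' Collects, for each transcript, the 5'-end positions of its assigned
#' footprints relative to the CDS start (0-based; negative values lie in the
#' 5' UTR) together with read lengths.
#'
#' @param alns alignment table of footprints against the transcript set.
#' @param transcripts a [make_transcriptome()] table.
#' @return a `data.frame` of class `footprint_profiles` with columns
#'   `transcript_id`, `rel5` (5' end minus CDS start) and `len`; the
#'   transcript table is attached as attribute `"transcripts"`.
#' @export
footprint_profiles <- function(alns, transcripts) {
  ix <- match(alns$ref_id, transcripts$gene_id)
  if (anyNA(ix)) stop("alignment references unknown transcript")
  out <- data.frame(transcript_id = alns$ref_id,
                    rel5 = alns$ref_start - transcripts$cds_start[ix],
                    len = alns$qwidth,
                    stringsAsFactors = FALSE)
  attr(out, "transcripts") <- transcripts
  class(out) <- c("footprint_profiles", "data.frame")
  out
}

#' Length histogram of footprints
#'
#' @param profiles a [footprint_profiles()] table.
#' @return a named integer vector of counts by read length.
#' @export
footprint_length_histogram <- function(profiles) {
  table(factor(profiles$len, levels = sort(unique(profiles$len))))
}

#' Estimate the P-site offset from aggregate 5'-end counts
#'
#' Searches offsets 0..`max_offset` for the one maximizing the aggregate
#' footprint 5'-end count at `CDS_start - offset` across transcripts.  With
#' initiation-paused data the maximum sits at the canonical 12-nt offset.
#'
#' @param profiles a [footprint_profiles()] table.
#' @param max_offset largest offset searched (default 18).
#' @return the offset (integer nt); `NA` with a warning when no footprint
#'   5' end falls on any candidate position.
#' @export
p_site_offset <- function(profiles, max_offset = 18L) {
  offsets <- 0:max_offset
  counts <- vapply(offsets, function(o) sum(profiles$rel5 == -o), integer(1))
  if (all(counts == 0L)) {
    warning("no footprint 5' ends near CDS starts; offset undefined")
    return(NA_integer_)
  }
  offsets[which.max(counts)]
}

#' 3-nt periodicity: fraction of P-sites in frame 0
#'
#' Shifts each footprint 5' end by `offset` to its P-site and reports the
#' fraction of P-sites falling in frame 0 of the CDS, over footprints whose
#' P-site lies within the CDS.
#'
#' @param profiles a [footprint_profiles()] table.
#' @param offset the P-site offset in nt (e.g. from [p_site_offset()]).
#' @return fraction in `[0, 1]`; `NA` when no P-site falls inside a CDS.
#' @export
periodicity <- function(profiles, offset) {
  if (is.na(offset)) return(NA_real_)
  tx <- attr(profiles, "transcripts")
  ix <- match(profiles$transcript_id, tx$gene_id)
  p <- profiles$rel5 + offset
  ok <- p >= 0L & p < tx$cds_len[ix]
  if (!any(ok)) return(NA_real_)
  mean(p[ok] %% 3L == 0L)
}

#' Frame counts relative to the CDS
#'
#' @param profiles a [footprint_profiles()] table.
#' @param offset P-site offset in nt.
#' @return integer vector of counts for frames 0, 1, 2 (P-sites within the
#'   CDS).
#' @export
frame_counts <- function(profiles, offset) {
  tx <- attr(profiles, "transcripts")
  ix <- match(profiles$transcript_id, tx$gene_id)
  p <- profiles$rel5 + offset
  ok <- p >= 0L & p < tx$cds_len[ix]
  tabulate(p[ok] %% 3L + 1L, nbins = 3L)
}

#' Reads per kilobase of CDS per million mapped reads
#'
#' `count / ((cds_length / 1000) * (total_mapped / 1e6))`.
#'
#' @param count reads assigned to the CDS (vectorized).
#' @param cds_length CDS length in nt (> 0).
#' @param total_mapped total mapped reads in the library (> 0).
#' @return numeric RPKM values.
#' @export
#' @examples
#' rpkm(100, 500, 1e6)  # 200
rpkm <- function(count, cds_length, total_mapped) {
  if (any(cds_length <= 0)) stop("cds_length must be > 0")
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0")
  count / ((cds_length / 1000) * (total_mapped / 1e6))
}

#' Translation efficiency
#'
#' The ratio of Ribo-seq RPKM to RNA-seq RPKM.  Undefined (returned as
#' `NA`) when the RNA RPKM is zero; no pseudocount is added by default.
#'
#' @param rpkm_ribo,rpkm_rna RPKM vectors.
#' @param pseudocount optional value added to both RPKMs (default 0).
#' @return numeric TE values; `NA` where `rpkm_rna + pseudocount == 0`.
#' @export
translation_efficiency <- function(rpkm_ribo, rpkm_rna, pseudocount = 0) {
  num <- rpkm_ribo + pseudocount
  den <- rpkm_rna + pseudocount
  ifelse(den > 0, num / den, NA_real_)
}

#' Count footprints and RNA reads per CDS and compute TE
#'
#' Footprints are counted when their P-site (5' end plus `offset`) lies
#' within the CDS; RNA reads when their 5' end lies within the CDS.  RPKM
#' denominators are the per-library totals of such CDS-assigned reads, which
#' keeps the Ribo and RNA denominators commensurable.
#'
#' @param ribo_alns,rna_alns alignment tables against the transcript set.
#' @param transcripts a [make_transcriptome()] table.
#' @param offset P-site offset in nt (default 12).
#' @return a `data.frame` of class `te_table`: `transcript_id`,
#'   `count_ribo`, `count_rna`, `rpkm_ribo`, `rpkm_rna`, `te`.
#' @export
compute_te <- function(ribo_alns, rna_alns, transcripts, offset = 12L) {
  ixr <- match(ribo_alns$ref_id, transcripts$gene_id)
  p <- ribo_alns$ref_start + offset - transcripts$cds_start[ixr]
  okr <- p >= 0L & p < transcripts$cds_len[ixr]
  count_ribo <- tabulate(ixr[okr], nbins = nrow(transcripts))
  ixn <- match(rna_alns$ref_id, transcripts$gene_id)
  q <- rna_alns$ref_start - transcripts$cds_start[ixn]
  okn <- q >= 0L & q < transcripts$cds_len[ixn]
  count_rna <- tabulate(ixn[okn], nbins = nrow(transcripts))
  rk_ribo <- rpkm(count_ribo, transcripts$cds_len, max(sum(count_ribo), 1L))
  rk_rna <- rpkm(count_rna, transcripts$cds_len, max(sum(count_rna), 1L))
  out <- data.frame(transcript_id = transcripts$gene_id,
                    count_ribo = count_ribo, count_rna = count_rna,
                    rpkm_ribo = rk_ribo, rpkm_rna = rk_rna,
                    te = translation_efficiency(rk_ribo, rk_rna),
                    stringsAsFactors = FALSE)
  class(out) <- c("te_table", "data.frame")
  out
}

#' Cross-condition TE classification
#'
#' Transcripts with a TE fold change of at least `fc_threshold` between
#' conditions are classified `up` (B over A) or `down`; the rest are
#' `unchanged`.  Transcripts with undefined TE in either condition are
#' excluded (`te_class = NA`, `excluded = TRUE`).
#'
#' @param te_A,te_B `te_table`s for the two conditions (matched by
#'   `transcript_id`).
#' @param fc_threshold fold-change threshold (default 4).
#' @return a `data.frame` of class `diff_te`: `transcript_id`, `te_A`,
#'   `te_B`, `log2fc_te`, `te_class`, `excluded`.
#' @export
differential_te <- function(te_A, te_B, fc_threshold = 4) {
  ids <- union(te_A$transcript_id, te_B$transcript_id)
  a <- te_A$te[match(ids, te_A$transcript_id)]
  b <- te_B$te[match(ids, te_B$transcript_id)]
  fc <- b / a
  cls <- ifelse(fc >= fc_threshold, "up",
                ifelse(fc <= 1 / fc_threshold, "down", "unchanged"))
  cls[is.na(a) | is.na(b)] <- NA_character_
  out <- data.frame(transcript_id = ids, te_A = a, te_B = b,
                    log2fc_te = log2(fc), te_class = cls,
                    excluded = is.na(cls), stringsAsFactors = FALSE)
  class(out) <- c("diff_te", "data.frame")
  out
}
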