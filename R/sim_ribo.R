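#' Simulate Ribo-seq footprints and matched RNA-seq reads
#'
#' RNA read counts are proportional to transcript abundance (times CDS
#' length, since reads are sampled per CDS position); footprint counts are
#' additionally proportional to the gene's true translation efficiency.
#' Footprint 5' ends are placed 12 nt upstream of an in-frame P-site codon
#' with optional symmetric positional jitter, footprint lengths are drawn
#' from a distribution concentrated on 28-32 nt, and the initiation codon
#' receives an occupancy multiplier (`init_peak`) emulating initiation
#' pausing, which is what makes the aggregate-count offset search
#' well-posed.  The truth sidecar records each gene's true and expected
#' (estimable) TE; the two differ by the library-wide TE normalization
#' inherent to RPKM ratios.
#'
#' @param transcripts a [make_transcriptome()] table.
#' @param true_te per-gene true translation efficiencies (> 0), recycled.
#' @param depth_ribo,depth_rna total footprint / RNA read counts (>= 1).
#' @param seed integer seed.
#' @param jitter maximum absolute 5'-end jitter in nt; draws are symmetric
#'   and centered (triangular weights over `-jitter..jitter`), so the
#'   canonical offset remains the modal position (default 0).
#' @param init_peak occupancy multiplier for the initiation codon
#'   (default 5).
#' @param len_probs footprint length distribution over 25-33 nt (named or
#'   ordered vector of 9 weights; default peaked at 30 within 28-32).
#' @param rna_read_len RNA-seq read length (default 50).
#' @param abundance per-gene relative abundances (default uniform).
#' @param p_site_offset distance from footprint 5' end to the P-site codon
#'   (default 12 nt).
#' @return a list of class `ribo_sim` with read tables `ribo` and `rna`,
#'   a `truth` sidecar (`gene_id`, `true_te`, `expected_te`, `abundance`)
#'   and `params`.
#' @export
simulate_ribo_rna <- function(transcripts, true_te, depth_ribo, depth_rna,
                              seed = 1L, jitter = 0L, init_peak = 5,
                              len_probs = c(0, 0, 0, 0.05, 0.15, 0.40,
                                            0.25, 0.10, 0.05),
                              rna_read_len = 50L, abundance = NULL,
                              p_site_offset = 12L) {
  stopifnot_scalar_count(depth_ribo, "depth_ribo")
  stopifnot_scalar_count(depth_rna, "depth_rna")
  n <- nrow(transcripts)
  te <- rep_len(true_te, n)
  if (any(te <= 0)) stop("true_te must be positive for all transcripts")
  if (is.null(abundance)) abundance <- rep(1, n)
  stopifnot(length(len_probs) == 9L, all(len_probs >= 0), sum(len_probs) > 0)
  lens <- 25:33
  n_codons <- transcripts$cds_len / 3L

  # expected estimable TE: ratio of footprint to RNA sampling proportions;
  # RPKM's per-kilobase factors cancel in the ratio, leaving a library-wide
  # normalization constant that is part of the estimand
  w_ribo <- abundance * te * (n_codons - 1 + init_peak)
  w_rna <- abundance * transcripts$cds_len
  expected_te <- (w_ribo / sum(w_ribo)) / (w_rna / sum(w_rna))

  with_seed(seed, {
    ## footprints
    g <- sample.int(n, depth_ribo, replace = TRUE, prob = w_ribo)
    ribo_l <- vector("list", n)
    for (i in seq_len(n)) {
      m <- sum(g == i)
      if (m == 0L) next
      nc <- n_codons[i]
      wcod <- c(init_peak, rep(1, nc - 1))
      codon <- sample.int(nc, m, replace = TRUE, prob = wcod) - 1L
      jit <- if (jitter > 0) {
        # symmetric, centered digestion variability: triangular weights so
        # the unjittered offset stays the unique mode
        off <- seq(-jitter, jitter)
        sample(off, m, replace = TRUE, prob = jitter + 1 - abs(off))
      } else integer(m)
      p5 <- transcripts$cds_start[i] + 3L * codon - p_site_offset + jit
      len <- sample(lens, m, replace = TRUE, prob = len_probs)
      L <- nchar(transcripts$transcript[i])
      ok <- p5 >= 0L & (p5 + len) <= L
      p5 <- p5[ok]; len <- len[ok]
      if (!length(p5)) next
      ribo_l[[i]] <- data.frame(
        gene = i, p5 = p5, len = len,
        seq = substr(rep(transcripts$transcript[i], length(p5)),
                     p5 + 1L, p5 + len),
        stringsAsFactors = FALSE
      )
    }
    ribo <- do.call(rbind, ribo_l)
    ribo_reads <- data.frame(
      id = sprintf("fp%07d_g%04d", seq_len(nrow(ribo)), ribo$gene),
      seq = ribo$seq,
      qual = strrep("I", ribo$len),
      stringsAsFactors = FALSE
    )

    ## RNA-seq: 5' ends uniform over CDS positions
    gr <- sample.int(n, depth_rna, replace = TRUE, prob = w_rna)
    rna_l <- vector("list", n)
    for (i in seq_len(n)) {
      m <- sum(gr == i)
      if (m == 0L) next
      L <- nchar(transcripts$transcript[i])
      p5 <- transcripts$cds_start[i] +
        sample.int(transcripts$cds_len[i], m, replace = TRUE) - 1L
      end <- pmin(p5 + rna_read_len, L)
      rna_l[[i]] <- data.frame(
        gene = i, p5 = p5,
        seq = substr(rep(transcripts$transcript[i], m), p5 + 1L, end),
        stringsAsFactors = FALSE
      )
    }
    rna <- do.call(rbind, rna_l)
    rna_reads <- data.frame(
      id = sprintf("rna%07d_g%04d", seq_len(nrow(rna)), rna$gene),
      seq = rna$seq,
      qual = strrep("I", nchar(rna$seq)),
      stringsAsFactors = FALSE
    )

    truth <- data.frame(gene_id = transcripts$gene_id,
                        true_te = te,
                        expected_te = expected_te,
                        abundance = abundance,
                        stringsAsFactors = FALSE)
    structure(list(
      ribo = ribo_reads, rna = rna_reads, truth = truth,
      ribo_truth = data.frame(read_id = ribo_reads$id,
                              gene_id = transcripts$gene_id[ribo$gene],
                              p5 = ribo$p5, len = ribo$len,
                              stringsAsFactors = FALSE),
      rna_truth = data.frame(read_id = rna_reads$id,
                             gene_id = transcripts$gene_id[rna$gene],
                             p5 = rna$p5, stringsAsFactors = FALSE),
      params = list(seed = seed, jitter = jitter, init_peak = init_peak,
                    p_site_offset = p_site_offset, depth_ribo = depth_ribo,
                    depth_rna = depth_rna)
    ), class = "ribo_sim")
  })
}
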