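STOP_CODONS <- c("TAA", "TAG", "TGA")

#' All 61 sense codons
#'
#' @return character vector of the sense codons (stops excluded).
#' @export
sense_codons <- function() {
  all64 <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0),
                           DNA_BASES, paste0))
  sort(setdiff(all64, STOP_CODONS))
}

#' Simulate a transcriptome with controllable codon bias
#'
#' Generates two gene classes: `"target-codon-rich"` genes whose internal
#' codons are drawn with an inflated weight on `target_codons`, and
#' `"background"` genes drawn uniformly over the sense codons.  Every CDS
#' starts with ATG, ends with a stop, and is flanked by random UTRs so
#' ribosome footprints can extend upstream of the start codon.
#'
#' @param n_genes number of genes (>= 2).
#' @param seed integer seed.
#' @param target_fraction fraction of genes in the target-codon-rich class
#'   (default 0.25).
#' @param target_codons codons to enrich in the target class (default
#'   `c("AGC", "GAG")`).
#' @param target_weight multiplicative weight on `target_codons` in the
#'   target class (default 3).
#' @param codon_bias optional list with named numeric weight vectors
#'   `target` and `background` over the 61 sense codons, overriding the
#'   default construction.
#' @param n_codons_range total codons per CDS including start and stop,
#'   sampled uniformly from this range (default 100-200).
#' @param utr5,utr3 UTR lengths in nt (defaults 30 and 30).
#' @return a `data.frame` of class `transcriptome` with columns `gene_id`,
#'   `class`, `cds`, `transcript`, `cds_start` (0-based), `cds_len`.
#' @export
make_transcriptome <- function(n_genes, seed,
                               target_fraction = 0.25,
                               target_codons = c("AGC", "GAG"),
                               target_weight = 3,
                               codon_bias = NULL,
                               n_codons_range = c(100L, 200L),
                               utr5 = 30L, utr3 = 30L) {
  stopifnot_scalar_count(n_genes, "n_genes", min = 2L)
  sense <- sense_codons()
  if (is.null(codon_bias)) {
    w_bg <- setNames(rep(1, length(sense)), sense)
    w_tg <- w_bg
    stopifnot(all(target_codons %in% sense))
    w_tg[target_codons] <- target_weight
    codon_bias <- list(target = w_tg, background = w_bg)
  }
  for (w in codon_bias) {
    if (any(w < 0) || sum(w) <= 0)
      stop("codon weights must be non-negative with a positive sum",
           call. = FALSE)
  }
  n_target <- round(n_genes * target_fraction)
  cls <- c(rep("target-codon-rich", n_target),
           rep("background", n_genes - n_target))
  with_seed(seed, {
    n_cod <- sample(n_codons_range[1]:n_codons_range[2], n_genes,
                    replace = TRUE)
    cds <- character(n_genes)
    for (i in seq_len(n_genes)) {
      w <- if (cls[i] == "target-codon-rich") codon_bias$target
           else codon_bias$background
      internal <- sample(names(w), n_cod[i] - 2L, replace = TRUE,
                         prob = w / sum(w))
      cds[i] <- paste0("ATG", paste(internal, collapse = ""),
                       sample(STOP_CODONS, 1L))
    }
    transcript <- paste0(random_dna(n_genes, utr5), cds,
                         random_dna(n_genes, utr3))
    out <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(n_genes)),
      class = cls,
      cds = cds,
      transcript = transcript,
      cds_start = as.integer(utr5),
      cds_len = nchar(cds),
      stringsAsFactors = FALSE
    )
    class(out) <- c("transcriptome", "data.frame")
    out
  })
}
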