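#' Library design constants for the tRNA m1A-seq protocol
#'
#' Fixed constants of the sequencing library: a 10-nt random 5' barcode
#' (UMI), the 3' RNA linker sequence, the RT primer, 150-nt reads with
#' read 2 carrying the analyzed strand.
#'
#' @param umi_length barcode length in nt (default 10).
#' @param adapter3 3' adapter/linker DNA sequence.
#' @param rt_primer RT primer sequence (recorded for provenance; not used in
#'   read processing).
#' @param post_adapter fixed construct sequence the instrument reads into
#'   past the 3' linker on short inserts (PCR-primer region).
#' @param read_length instrument read length in nt (default 150).
#' @return a list of class `library_design`.
#' @export
library_design <- function(umi_length = 10L,
                           adapter3 = "AGATCGGAAGAGCGTCGTG",
                           rt_primer = "ACACGACGCTCTTCCGATCT",
                           post_adapter = "GTGACTGGAGTTCAGACGTGTGCTCTTCCGATC",
                           read_length = 150L) {
  stopifnot_scalar_count(umi_length, "umi_length")
  stopifnot_scalar_count(read_length, "read_length")
  structure(list(umi_length = as.integer(umi_length),
                 adapter3 = adapter3,
                 rt_primer = rt_primer,
                 post_adapter = post_adapter,
                 read_length = as.integer(read_length),
                 analyzed_read = 2L),
            class = "library_design")
}

# anticodons by tRNA family; the first four are the default planted targets
# for differential methylation and are always emitted first
TRNA_FAMILIES <- c(
  "Asp-GTC", "Ala-AGC", "Glu-CTC", "Ser-GCT",
  "Gly-GCC", "Lys-CTT", "Leu-AAG", "Val-AAC", "Arg-ACG", "Pro-AGG",
  "Thr-AGT", "Ile-AAT", "Phe-GAA", "Asn-GTT", "His-GTG", "Gln-CTG",
  "Tyr-GTA", "Cys-GCA", "Trp-CCA", "Met-CAT", "Gly-CCC", "Lys-TTT",
  "Leu-CAA", "Val-CAC", "Arg-CCT", "Ser-AGA", "Thr-CGT", "Ala-CGC"
)

# T-loop consensus fragment; the A at offset 5 stands for canonical
# position 58
TLOOP_MOTIF <- "GTTCGAATC"
TLOOP_A58_OFFSET <- 5L

#' Generate a synthetic mature-tRNA reference set
#'
#' Builds `n_families` mature tRNA sequences with a fixed anticodon placed in
#' the anticodon-loop region, a T-loop consensus fragment whose adenosine
#' stands for canonical position 58, and a 3'-terminal CCA.  When
#' `n_families >= 4` the first four families are tRNA-Asp-GTC, tRNA-Ala-AGC,
#' tRNA-Glu-CTC and tRNA-Ser-GCT.
#'
#' All positions in the returned table are 0-based.
#'
#' @param n_families number of tRNA families to generate (>= 1).
#' @param seed integer seed; output is deterministic given the seed.
#' @return a `data.frame` of class `trna_reference` with columns `ref_id`,
#'   `sequence`, `anticodon`, `a58_index` (0-based) and `length`.
#' @export
#' @examples
#' refs <- make_trna_reference(4, seed = 7)
#' substr(refs$sequence, refs$a58_index + 1, refs$a58_index + 1)  # all "A"
make_trna_reference <- function(n_families, seed) {
  stopifnot_scalar_count(n_families, "n_families")
  n_families <- as.integer(n_families)
  with_seed(seed, {
    fams <- if (n_families <= length(TRNA_FAMILIES)) {
      TRNA_FAMILIES[seq_len(n_families)]
    } else {
      extra <- n_families - length(TRNA_FAMILIES)
      c(TRNA_FAMILIES,
        paste0(sample(TRNA_FAMILIES, extra, replace = TRUE), "-x",
               seq_len(extra)))
    }
    anticodon <- vapply(strsplit(fams, "-", fixed = TRUE),
                        function(p) p[2], character(1))
    anticodon <- substr(anticodon, 1, 3)
    repeat {
      k <- sample(15:20, n_families, replace = TRUE)   # variable-arm spacer
      t <- sample(3:5, n_families, replace = TRUE)     # post-T-loop spacer
      seqs <- paste0(random_dna(n_families, 38L),
                     anticodon,
                     vapply(seq_len(n_families),
                            function(i) random_dna(1L, k[i]), character(1)),
                     TLOOP_MOTIF,
                     vapply(seq_len(n_families),
                            function(i) random_dna(1L, t[i]), character(1)),
                     "CCA")
      if (!anyDuplicated(seqs)) break
    }
    a58 <- 38L + 3L + k + TLOOP_A58_OFFSET
    out <- data.frame(
      ref_id = paste0("tRNA-", fams, "-1"),
      sequence = seqs,
      anticodon = anticodon,
      a58_index = as.integer(a58),
      length = nchar(seqs),
      stringsAsFactors = FALSE
    )
    class(out) <- c("trna_reference", "data.frame")
    validate_trna_reference(out)
    out
  })
}

#' Validate a tRNA reference table
#'
#' Checks the structural invariants: the base at `a58_index` is A, the
#' sequence ends in CCA, `a58_index` lies in the 3' quarter, ids are unique
#' and sequence lengths are in the 70-95 nt mature-tRNA range.
#'
#' @param refs a `trna_reference` data.frame.
#' @return `refs`, invisibly; errors on violation.
#' @export
validate_trna_reference <- function(refs) {
  stopifnot(is.data.frame(refs),
            all(c("ref_id", "sequence", "anticodon", "a58_index") %in%
                  names(refs)))
  if (anyDuplicated(refs$ref_id)) stop("ref_ids must be unique")
  len <- nchar(refs$sequence)
  if (any(len < 70L | len > 95L))
    stop("tRNA sequences must be 70-95 nt")
  if (!all(substr(refs$sequence, len - 2L, len) == "CCA"))
    stop("tRNA sequences must end with CCA")
  b58 <- substr(refs$sequence, refs$a58_index + 1L, refs$a58_index + 1L)
  if (!all(b58 == "A")) stop("base at a58_index must be 'A'")
  if (any(refs$a58_index < 0.75 * len))
    stop("a58_index must lie within the 3' quarter of the sequence")
  invisible(refs)
}

#' Codons decoded by an anticodon
#'
#' The exact codon is the reverse complement of the anticodon.  With
#' `wobble = TRUE` the standard wobble pairs at anticodon position 34 are
#' added: G34 also reads codons ending in T, and T34 also reads codons
#' ending in G.  The default is the narrow (exact) table.
#'
#' @param anticodon character vector of 3-mers (DNA alphabet, 5'->3').
#' @param wobble include standard wobble expansions (default `FALSE`).
#' @return character vector of unique codons.
#' @export
#' @examples
#' decoded_codons("AGC")           # "GCT" (alanine)
#' decoded_codons("GTC")           # "GAC" (aspartate)
decoded_codons <- function(anticodon, wobble = FALSE) {
  stopifnot(all(nchar(anticodon) == 3L))
  exact <- revcomp(anticodon)
  if (!wobble) return(unique(exact))
  extra <- character(0)
  for (i in seq_along(anticodon)) {
    a34 <- substr(anticodon[i], 1, 1)
    stem <- substr(exact[i], 1, 2)
    if (a34 == "G") extra <- c(extra, paste0(stem, "T"))
    if (a34 == "T") extra <- c(extra, paste0(stem, "G"))
  }
  unique(c(exact, extra))
}

#' Collapse identical reference sequences
#'
#' Indistinguishable references (identical sequence) are merged before
#' alignment and reported jointly under a combined id (`id1|id2`), because
#' mismatch-rate attribution between them is undefined.
#'
#' @param refs a `trna_reference` data.frame.
#' @return a `trna_reference` data.frame with unique sequences.
#' @export
collapse_identical_refs <- function(refs) {
  grp <- split(seq_len(nrow(refs)), refs$sequence)
  keep <- vapply(grp, function(ix) ix[1], integer(1))
  out <- refs[sort(keep), , drop = FALSE]
  ids <- vapply(split(refs$ref_id, refs$sequence),
                paste, character(1), collapse = "|")
  out$ref_id <- ids[out$sequence]
  rownames(out) <- NULL
  class(out) <- c("trna_reference", "data.frame")
  out
}
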