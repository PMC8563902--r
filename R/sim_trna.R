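#' Ground-truth parameter table for the tRNA-seq simulator
#'
#' Collects the simulator's free parameters: per-tRNA m1A58 stoichiometry in
#' two biological conditions, the in-vitro demethylation efficiency, the
#' per-base sequencing error rate and the mean PCR duplication count.  Every
#' simulated output records the seed it was generated under, so runs are
#' reproducible bit-for-bit.
#'
#' @param refs a `trna_reference` table.
#' @param stoichiometry_condA,stoichiometry_condB per-tRNA modification
#'   fractions in `[0, 1]`, recycled to `nrow(refs)`.
#' @param demethylation_efficiency fraction of modified sites erased by the
#'   demethylase arm (default 1: the signal disappears completely).
#' @param sequencing_error_rate independent per-base substitution error rate
#'   (default 0.002).
#' @param pcr_duplication_mean mean of the Poisson extra-copy count; each
#'   molecule is emitted `1 + Poisson(mean)` times (default 1).
#' @return a `data.frame` of class `sim_truth` with global parameters stored
#'   as attributes.
#' @export
sim_truth <- function(refs,
                      stoichiometry_condA,
                      stoichiometry_condB = stoichiometry_condA,
                      demethylation_efficiency = 1.0,
                      sequencing_error_rate = 0.002,
                      pcr_duplication_mean = 1.0) {
  n <- nrow(refs)
  sA <- rep_len(stoichiometry_condA, n)
  sB <- rep_len(stoichiometry_condB, n)
  fr <- c(sA, sB, demethylation_efficiency, sequencing_error_rate)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (pcr_duplication_mean < 0) stop("pcr_duplication_mean must be >= 0")
  out <- data.frame(ref_id = refs$ref_id,
                    stoichiometry_condA = sA,
                    stoichiometry_condB = sB,
                    stringsAsFactors = FALSE)
  attr(out, "demethylation_efficiency") <- demethylation_efficiency
  attr(out, "sequencing_error_rate") <- sequencing_error_rate
  attr(out, "pcr_duplication_mean") <- pcr_duplication_mean
  class(out) <- c("sim_truth", "data.frame")
  out
}

# scatter substitution errors over a vector of equal-length strings;
# positions drawn uniformly, replacement drawn from the 3 other bases
apply_seq_errors <- function(seqs, len, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  n_err <- rbinom(1L, length(seqs) * len, rate)
  if (n_err == 0) return(seqs)
  idx <- sample.int(length(seqs), n_err, replace = TRUE)
  pos <- sample.int(len, n_err, replace = TRUE)
  sub <- sample(DNA_BASES, n_err, replace = TRUE)
  # same read may be hit more than once: apply in rounds so vectorized
  # substr<- never writes twice to one element in one call
  while (length(idx)) {
    first <- !duplicated(idx)
    i <- idx[first]; p <- pos[first]; s <- sub[first]
    cur <- substr(seqs[i], p, p)
    s <- ifelse(s == cur, chartr("ACGT", "CGTA", s), s)  # force a change
    substr(seqs[i], p, p) <- s
    idx <- idx[!first]; pos <- pos[!first]; sub <- sub[!first]
  }
  seqs
}

#' Simulate a tRNA m1A-seq library arm
#'
#' Draws `n_molecules` tRNA molecules (uniform abundance by default), flips
#' the base at each molecule's position-58 adenosine to a non-A base with
#' probability `stoichiometry` (times `1 - demethylation_efficiency` in the
#' demethylated arm), emits each molecule `1 + Poisson(pcr_duplication_mean)`
#' times (duplicates share the molecule's random 10-nt barcode and fragment),
#' adds independent per-base sequencing errors to every emitted read,
#' prepends the barcode, appends the 3' adapter, and pads or truncates to the
#' instrument read length.  The returned object carries a molecule-level
#' truth sidecar so every read is traceable to its source molecule and
#' modification state.
#'
#' @param refs a `trna_reference` table.
#' @param truth a [sim_truth()] table covering every reference.
#' @param n_molecules total number of molecules to draw (>= 1).
#' @param demethylated simulate the demethylase-treated arm?
#' @param condition `"A"` or `"B"`: which stoichiometry column applies.
#' @param seed integer seed.
#' @param design a [library_design()].
#' @param abundance optional per-tRNA relative abundances (default uniform).
#' @param misinc_spectrum named weights over the non-A bases read at a
#'   modified site (default uniform over C/G/T).
#' @param truncation_rate probability that RT falls off at a modified site
#'   instead of reading through (default 0; read-through chemistry).
#' @return a list of class `trna_library` with elements `reads` (read table
#'   with `umi` truth column), `sidecar` (per-read truth), and `params`.
#' @export
simulate_trna_library <- function(refs, truth, n_molecules,
                                  demethylated = FALSE, condition = "A",
                                  seed = 1L, design = library_design(),
                                  abundance = NULL,
                                  misinc_spectrum = c(C = 1, G = 1, T = 1),
                                  truncation_rate = 0) {
  stopifnot_scalar_count(n_molecules, "n_molecules")
  if (!all(refs$ref_id %in% truth$ref_id))
    stop("truth table is missing entries for some references", call. = FALSE)
  condition <- match.arg(condition, c("A", "B"))
  scol <- paste0("stoichiometry_cond", condition)
  truth_m <- truth[match(refs$ref_id, truth$ref_id), ]
  eff <- attr(truth, "demethylation_efficiency")
  err <- attr(truth, "sequencing_error_rate")
  dupmean <- attr(truth, "pcr_duplication_mean")
  if (is.null(abundance)) abundance <- rep(1, nrow(refs))
  stopifnot(length(abundance) == nrow(refs), all(abundance >= 0))
  spec_bases <- names(misinc_spectrum)
  stopifnot(length(spec_bases) > 0, !"A" %in% spec_bases)
  specp <- misinc_spectrum / sum(misinc_spectrum)

  with_seed(seed, {
    counts <- as.vector(rmultinom(1L, n_molecules, abundance))
    p_mod <- truth_m[[scol]] * (if (demethylated) (1 - eff) else 1)
    arm <- if (demethylated) "D" else "U"
    reads_l <- vector("list", nrow(refs))
    side_l <- vector("list", nrow(refs))
    mol_offset <- 0L
    for (i in seq_len(nrow(refs))) {
      n <- counts[i]
      if (n == 0L) next
      L <- refs$length[i]
      a58 <- refs$a58_index[i] + 1L  # 1-based for substr
      mol_seq <- rep(refs$sequence[i], n)
      u <- runif(n)
      modified <- u < p_mod[i]
      truncated <- rep(FALSE, n)
      if (any(modified)) {
        nm <- sum(modified)
        if (truncation_rate > 0)
          truncated[modified] <- runif(nm) < truncation_rate
        flip <- modified & !truncated
        if (any(flip)) {
          newb <- sample(spec_bases, sum(flip), replace = TRUE, prob = specp)
          substr(mol_seq[flip], a58, a58) <- newb
        }
        if (any(truncated))  # RT fall-off: cDNA covers only 3' of the site
          mol_seq[truncated] <- substr(mol_seq[truncated], a58 + 1L, L)
      }
      umi <- random_dna(n, design$umi_length)
      ndup <- 1L + rpois(n, dupmean)
      mol_id <- mol_offset + seq_len(n)
      mol_offset <- mol_offset + n
      rep_ix <- rep(seq_len(n), ndup)
      seqs <- mol_seq[rep_ix]
      # per-emitted-read sequencing errors on the insert
      if (truncation_rate > 0 && any(truncated)) {
        full <- !truncated[rep_ix]
        seqs[full] <- apply_seq_errors(seqs[full], L, err)
      } else {
        seqs <- apply_seq_errors(seqs, L, err)
      }
      reads_l[[i]] <- data.frame(
        mol = mol_id[rep_ix],
        umi = umi[rep_ix],
        insert = seqs,
        stringsAsFactors = FALSE
      )
      side_l[[i]] <- data.frame(
        mol = mol_id, ref_id = refs$ref_id[i], modified = modified,
        truncated = truncated, n_copies = ndup, umi = umi,
        stringsAsFactors = FALSE
      )
    }
    rd <- do.call(rbind, reads_l)
    sidecar <- do.call(rbind, side_l)
    # assemble full instrument reads: UMI + insert + 3' linker, running into
    # the fixed downstream construct sequence, cut to the instrument length
    pad_src <- strrep(design$post_adapter,
                      ceiling(design$read_length /
                                nchar(design$post_adapter)) + 1L)
    raw <- paste0(rd$umi, rd$insert, design$adapter3, pad_src)
    raw <- substr(raw, 1L, design$read_length)
    dup_rank <- stats::ave(rd$mol, rd$mol, FUN = seq_along)
    ids <- sprintf("%s_%s_m%07d_d%d", condition, arm, rd$mol, dup_rank)
    reads <- data.frame(id = ids, seq = raw,
                        qual = strrep("I", nchar(raw)),
                        stringsAsFactors = FALSE)
    structure(list(
      reads = reads,
      sidecar = cbind(first_read_id = ids[match(sidecar$mol, rd$mol)],
                      sidecar),
      params = list(condition = condition, demethylated = demethylated,
                    seed = seed, n_molecules = n_molecules,
                    demethylation_efficiency = eff,
                    sequencing_error_rate = err,
                    pcr_duplication_mean = dupmean,
                    truncation_rate = truncation_rate)
    ), class = "trna_library")
  })
}
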