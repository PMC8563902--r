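# Run one simulated tRNA-seq arm through the full read-level pipeline:
# simulate -> adapter/quality trim -> barcode extraction -> alignment ->
# UMI dedup -> pileup.  Returns the pileup (and intermediates on request).
trna_arm_pileup <- function(refs, truth, n_molecules, demethylated,
                            condition = "A", seed = 1L,
                            keep_intermediates = FALSE) {
  lib <- simulate_trna_library(refs, truth, n_molecules,
                               demethylated = demethylated,
                               condition = condition, seed = seed)
  trimmed <- trim_reads(lib$reads)
  um <- extract_umi(trimmed)
  alns <- align_reads(um, refs)
  dd <- dedup(alns)
  pu <- pileup(dd, refs)
  if (keep_intermediates)
    list(pileup = pu, lib = lib, alns = alns, dedup = dd)
  else pu
}

# 3-SE binomial band around the truth for an observed misincorporation rate
# measured at the given coverage with an independent per-base error rate:
# the observed success probability is truth + (1 - truth) * error.
stoich_bound <- function(truth, coverage, error) {
  p <- truth + (1 - truth) * error
  3 * sqrt(p * (1 - p) / coverage) + error
}
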