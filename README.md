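# trnam1a

Quantitative detection of **N1-methyladenosine at tRNA position 58
(m1A58)** from reverse-transcription misincorporation signatures, with the
downstream ribosome-profiling and codon-content analysis that links
hypermethylated tRNAs to translationally upregulated transcripts.

## The scientific problem

m1A58 sits on the Watson–Crick face of the T-loop adenosine of mature
tRNAs. A thermostable reverse transcriptase reads through the lesion but
misincorporates, so in a small-RNA sequencing library the fraction of
non-A bases aligned to the position-58 adenosine estimates the fraction of
molecules carrying the modification — its **stoichiometry**:

```
r = (coverage − count(ref base)) / coverage        (per arm)
stoichiometry ≈ r_untreated,   validated by   r_untreated − r_demethylated ≥ δ_min
```

Each library is sequenced twice: untreated, and after in-vitro AlkB
demethylation. A genuine m1A signal collapses in the demethylated arm;
mismatches that survive (SNPs, other modifications) are background. Reads
carry a 10-nt random barcode (UMI) before PCR, and duplicates — reads at an
identical mapping position with the same barcode — are collapsed before the
pileup.

Downstream, ribosome footprints (25–33 nt, P-site 12 nt from the 5' end)
and matched RNA-seq yield per-CDS RPKM and translation efficiency
`TE = RPKM_ribo / RPKM_rna`; transcripts with a TE fold change ≥ 4 between
conditions are differentially translated, and a label-permutation test asks
whether codons decoded by the m1A-elevated tRNAs are enriched in the TE-up
gene set.

The package is aimed at computational biologists who want a transparent,
fully seeded implementation of this pipeline: every stage (simulation,
trimming, barcode handling, a self-contained glocal aligner, deduplication,
pileup, calling, Ribo-seq QC, TE, enrichment) is an exported R function,
and a synthetic-data module with machine-readable truth tables makes every
claim testable offline. See `vignettes/methods.Rmd` for models,
assumptions and design choices.

## Worked example

Simulate two conditions over 8 tRNA families (the generator always emits
tRNA-Asp-GTC, tRNA-Ala-AGC, tRNA-Glu-CTC and tRNA-Ser-GCT first; the first
two are planted with elevated methylation in condition B here), run each
arm through the read-level pipeline, and call sites:

```r
library(trnam1a)

refs  <- make_trna_reference(n_families = 8, seed = 7)
truth <- sim_truth(refs,
                   stoichiometry_condA = c(0.45, 0.45, 0.92, 0.92, 0.5, 0.5, 0.2, 0),
                   stoichiometry_condB = c(0.60, 0.60, 0.92, 0.92, 0.5, 0.5, 0.2, 0))

arm <- function(demethylated, condition, seed) {
  lib <- simulate_trna_library(refs, truth, n_molecules = 8000,
                               demethylated = demethylated,
                               condition = condition, seed = seed)
  reads <- extract_umi(trim_reads(lib$reads))
  pileup(dedup(align_reads(reads, refs)), refs)
}

calls_A <- call_m1a58(arm(FALSE, "A", 1), arm(TRUE, "A", 2), refs)
calls_B <- call_m1a58(arm(FALSE, "B", 3), arm(TRUE, "B", 4), refs)
print(calls_A[, c("ref_id", "mism_untreated", "mism_demethylated",
                  "stoichiometry", "called", "band")], digits = 2)
#>           ref_id mism_untreated mism_demethylated stoichiometry called   band
#> 1 tRNA-Asp-GTC-1         0.4571            0.0051        0.4571   TRUE medium
#> 2 tRNA-Ala-AGC-1         0.4423            0.0019        0.4423   TRUE medium
#> 3 tRNA-Glu-CTC-1         0.9090            0.0010        0.9090   TRUE   high
#> 4 tRNA-Ser-GCT-1         0.9138            0.0020        0.9138   TRUE   high
#> 5 tRNA-Gly-GCC-1         0.4861            0.0019        0.4861   TRUE medium
#> 6 tRNA-Lys-CTT-1         0.4879            0.0031        0.4879   TRUE medium
#> 7 tRNA-Leu-AAG-1         0.1994            0.0020        0.1994   TRUE    low
#> 8 tRNA-Val-AAC-1         0.0021            0.0000        0.0021  FALSE    low
```

The untreated misincorporation rate recovers the planted stoichiometries
(0.45/0.92/0.5/0.2/0) within binomial noise, and the demethylated arm
collapses to the sequencing-error floor (~0.002–0.005), which is what makes
the rate interpretable as stoichiometry. The unmodified tRNA is correctly
not called. Cross-condition comparison flags exactly the planted elevated
tRNAs and maps them to the codons they decode:

```r
dm <- differential_m1a(calls_A, calls_B)
subset(dm, elevated_in_B, c(ref_id, stoich_A, stoich_B, diff, band))
#>           ref_id stoich_A stoich_B diff   band
#> 1 tRNA-Ala-AGC-1     0.44     0.60 0.16 medium
#> 2 tRNA-Asp-GTC-1     0.46     0.59 0.13 medium
linked_codons(dm)
#> [1] "GAC" "GCT"
```

`run_all(run_config(seed = 1), out_dir)` runs the whole study design — two
conditions × two arms of tRNA-seq plus per-condition Ribo-seq/RNA-seq over
a codon-biased transcriptome — and writes `calls_A.tsv`, `calls_B.tsv`,
`diff.tsv`, `te.tsv`, `enrichment.tsv`, `qc.json` (P-site offset, frame-0
fraction, length histogram, dedup rates) and a manifest with the config
hash.

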