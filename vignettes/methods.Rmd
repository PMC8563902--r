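---
title: "Quantifying tRNA m1A58 from misincorporation signatures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tRNA m1A58 from misincorporation signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnam1a)
```

## The measurement model

N1-methyladenosine at canonical tRNA position 58 (m1A58) sits on the
Watson–Crick face of the adenosine. A thermostable group II intron reverse
transcriptase reads through the lesion but misincorporates at an elevated
rate, so in a small-RNA sequencing library the fraction of non-A read bases
at the position-58 adenosine is a direct proxy for the fraction of molecules
carrying the modification — its *stoichiometry*. Because SNPs, other
modifications and alignment artifacts can also produce mismatches, every
library is sequenced in two arms: untreated, and treated in vitro with a
bacterial AlkB demethylase that erases m1A. A genuine m1A58 signal collapses
in the demethylated arm; anything that survives demethylation is background.

For tRNA `t` with deduplicated coverage `n_t` at its position-58 adenosine,
the pipeline computes the misincorporation rate in both arms,

    r = (coverage - count(ref base)) / coverage,

calls a site when both arms reach `min_coverage` (default 50) and the
contrast `delta = r_untreated - r_demethylated` reaches `delta_min`
(default 0.05), and reports `r_untreated` as the stoichiometry. The raw
untreated rate, not the difference, is the estimand; background subtraction
(`background_subtract = TRUE`) is available because the contrast description
admits either reading, and the two coincide when demethylation is complete
and sequencing error is small. Neither threshold follows from the
chemistry; both are config-exposed and recorded in output headers.

The observed rate at a site with true stoichiometry `p` and per-base error
rate `e` is binomial with success probability approximately `p + (1 - p)e`,
which is what the validation suite uses for its 3-standard-error recovery
bands.

Stoichiometries are banded `low` (< 0.3), `medium` ([0.3, 0.9)) and `high`
([0.9, 1]): saturated tRNAs have no headroom for further elevation between
conditions, and it is the medium band where biological elevation is
detectable. Cross-condition comparison flags a tRNA as elevated when it is
called in both conditions and its stoichiometry increase reaches
`elevation_min` (default 0.05).

## Library structure and read processing

The library constants are fixed by the protocol: a 10-nt random 5' barcode
(UMI) ligated to each cDNA molecule before PCR, the 3' RNA linker
`AGATCGGAAGAGCGTCGTG`, 150-nt reads with read 2 carrying the tRNA sense
strand. Processing order: 3' adapter removal (longest
suffix–prefix match, minimum overlap 5 nt, 10% per-overlap mismatch
tolerance — Trim-Galore-like defaults), BWA-style running-sum quality
trimming at Q20, then removal of the first 10 nt as the UMI. Reads mapped to
an identical reference position that share the same barcode are PCR
duplicates; one representative per `(ref, start, UMI)` key is kept, chosen
as the first record in a stable sort by read id so the operation is
deterministic. Barcode collisions between distinct molecules at the same
position are possible and intended — the key is position *and* barcode.

## Alignment

Reads are aligned to the mature-tRNA set with a self-contained glocal
aligner: the read aligns end to end (up to 2 nt may be soft-clipped at zero
cost at either end, absorbing residual adapter or ligation bases), the
reference ends are free. Scoring is match +1, mismatch −1, and a gap of
length L costs −3 − L. `N` bases score 0 and never count as mismatches.
Alignments below 0.8 × read length are discarded as unaligned.

The batch path first evaluates ungapped placements located by exact seed
k-mers. The acceptance rule is conservative: an ungapped result is kept only
when its score is at least `m·match + gap_open + gap_extend`, a bound no
gapped alignment can exceed, and any placement admissible under that bound
has at most two mismatches, so at least one of three disjoint interior seed
k-mers must match exactly — the seed lookup is therefore complete, not
heuristic. Everything else falls through to the full affine dynamic
program, and `align_read()` always runs the full DP. The test suite checks
both paths against an independently written row-vectorized DP oracle.

Identical reference sequences are collapsed before alignment and reported
jointly (`id1|id2`): mismatch attribution between indistinguishable
isodecoders is undefined. Reads tying across distinct references follow the
`multimap_policy`; the default `best-unique` drops ties, because
stoichiometry estimates should not mix reads of ambiguous origin. A seeded
`random-tiebreak` and plain `drop` are provided.

## The synthetic data generator

The generator is first-class, tested code: it defines the conditions every
validation claim refers to. Defaults, chosen once as the study conditions:

* 20 tRNA families, with tRNA-Asp-GTC, tRNA-Ala-AGC, tRNA-Glu-CTC and
  tRNA-Ser-GCT always first (the default planted targets for differential
  methylation); synthetic 71–78 nt
  bodies with the anticodon at its loop position, a T-loop consensus
  fragment whose adenosine stands for position 58, and a 3' CCA.
* uniform tRNA abundance, equal across conditions — the biology of
  interest is a change in modification level at constant expression; the
  truth table still accepts any abundance vector.
* sequencing error 0.002 per base, independent; demethylation efficiency
  1.0 (complete erasure — the ideal-control limit for AlkB in vitro); PCR duplication
  `1 + Poisson(1)` copies per molecule, duplicates sharing barcode and
  fragment; misincorporation spectrum uniform over C/G/T, overridable —
  TGIRT misincorporation spectra vary across sites and protocols, and no
  result here depends on the split.
* RT fall-off at the modified site (`truncation_rate`) defaults to 0: the
  stoichiometry readout is read-through-based.
* reads padded past the 3' linker with the fixed downstream PCR-primer
  sequence, as a real read 2 would be.

The Ribo-seq generator places footprint 5' ends 12 nt upstream of in-frame
P-site codons, draws lengths concentrated on 28–32 nt (within the 25–33 nt
qualified window), gives the initiation codon a 5× occupancy multiplier
(initiation pausing; this is also what makes the aggregate-count offset
search well-posed — under perfectly uniform codon occupancy every offset in
{0, 3, 6, 9, 12} collects the same count), and jitters positions with a
centered triangular distribution so the canonical offset remains the unique
mode. RNA reads are drawn uniformly across CDS positions with gene weights
proportional to abundance × CDS length; footprint gene weights additionally
carry the true translation efficiency.

What the simulator does not model: ligation sequence biases, tRNA
secondary-structure-dependent RT behavior, other modifications (m1G, m3C),
positional coverage unevenness, UMI sequencing errors, and overdispersed
counts. Passing tests therefore demonstrate correctness of the estimators
under clean sampling assumptions, not robustness to every artifact of real
libraries.

## Translation efficiency and its estimand

RPKM is computed over the CDS: `count / ((cds_len/1000) · (total/1e6))`.
A footprint is counted for a CDS when its P-site (5' end + offset) falls
inside it; an RNA read when its 5' end does. The RPKM denominator is the
per-library total of CDS-assigned reads — the denominator is a free
choice, and this one keeps the Ribo and RNA denominators commensurable. TE is the Ribo/RNA RPKM ratio, undefined (flagged, excluded)
when the RNA RPKM is zero; no pseudocount is added by default so the ratio
definition holds literally. Transcripts with a TE fold change of at least 4
between conditions are classified `up`/`down`.

Because both RPKMs are normalized within their own library, the estimable
quantity is TE up to a library-wide constant (the abundance-weighted mean
TE). The generator's truth sidecar therefore records both `true_te` and
`expected_te` — the normalized value an ideal estimator converges to — and
recovery tests compare against the latter. Cross-condition fold changes are
similarly compressed by the ratio of the two normalization constants — a
composition effect exactly analogous to library-size bias in differential
expression. With most genes unchanged the constant stays near 1; the demo
design therefore plants a 10-fold TE increase in 10% of genes (constant
1.9, estimable fold about 5.3), which clears the fold-4 classification
rule, whereas a large changed fraction would compress even a strong planted
fold below it.

## Codon-content enrichment

Codon frequencies are counted over the internal CDS (start and stop
excluded; counting the start is a flag, since rank claims for individual
genes are sensitive to it). "Top X%" rank percentiles use the
strict-greater convention with ties reported equal. The link from elevated
tRNAs to codons defaults to the exact anticodon reverse complement. The
module-level default deliberately stays narrow even though a wobble table
is available (`wobble = TRUE`): dual-luciferase reporter controls built on
synonymous wobble codons (e.g. Ala-GCG, Glu-GAA) are the natural check of
decoding breadth, and they argue for attributing translational effects only
to the exact cognate codon, so the narrow table is the conservative
default.

Enrichment of target codons in a TE-up gene set is tested by label
permutation on the mean summed target-codon frequency — no test is
canonical for this contrast, so a distribution-free procedure is declared
here. The p-value is
`(1 + #{permuted ≥ observed}) / (n_perm + 1)`. The suite checks both
calibration under the null (P(p ≤ α) within Monte Carlo slack of α) and
power ≥ 90% at a planted +0.03 absolute frequency shift with 50 vs 200
genes and 1000 permutations.

## Numerical and design choices

* Coordinates are 0-based half-open internally; SAM output is 1-based as
  the format requires; report tables state their convention.
* Zero coverage yields an undefined rate (`NA`), never 0 — the two are
  scientifically different.
* Deletions at the inspected site are excluded from both numerator and
  denominator (read-through chemistry yields mismatches, not gaps); a
  pileup column tracks them separately.
* All randomness flows through explicit seeds; every simulator restores
  the caller's RNG state. Stage seeds in `run_all()` derive
  deterministically from one global seed, and each report embeds the config
  hash, so a config + seed pair fixes the bundle byte for byte (the demo
  bundle writes uncompressed FASTQ so byte identity is about the pipeline,
  not gzip framing).
* The command-line surface is the exported function API plus
  `scripts/acceptance.R`; the package is driven from R, so no separate
  shell tool is shipped.

## Problem sizes used in validation

The suite exercises the full read-level pipeline at: 20 tRNAs × coverage
2000 × 100 replicate pairs (stoichiometry recovery, error 0.002,
demethylation efficiency 1.0, duplication 0 — stated coverages are
post-dedup molecule counts); coverage 300 × 50 seeds (truth-table calling);
coverage 4000 × 20 seeds × 2 conditions (differential recovery, chosen so 3
standard errors of a stoichiometry stay below half the elevation
threshold); 500 random read/reference pairs against the DP oracle; 20k
footprints for QC recovery; and 100 null + 50 powered enrichment runs. The
orchestrated demo (`run_config()` defaults) uses 20 tRNAs at coverage 1500
per arm and 60 genes at 40k reads per library.

## Known limitations

Stoichiometry estimates are not corrected for incomplete demethylation
(efficiency < 1 biases the contrast down) or RT fall-off; multimapped reads
are dropped rather than rescued, slightly depressing coverage for
near-identical isodecoders; TE inference has no shrinkage or replicate
dispersion model — fold-change-4 classification on single libraries is a
hard rule, not a statistical test; and the codon enrichment treats
genes as exchangeable units, ignoring length and expression covariates.
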