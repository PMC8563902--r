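test_that("codon frequencies count the internal region only", {
  p <- codon_frequencies("ATGGCTGCTAGCTAA")
  expect_equal(unname(p$frequencies["GCT"]), 2 / 3)
  expect_equal(unname(p$frequencies["AGC"]), 1 / 3)
  expect_equal(sum(p$counts), 3L)
  expect_error(codon_frequencies("ATGGCTGA"), "multiple of 3")
  expect_error(codon_frequencies("ATGTAA"), "internal")
  expect_warning(codon_frequencies("ATGGCTTAAGCTTAA"), "internal stop")
  withs <- codon_frequencies("ATGGCTGCTAGCTAA", include_start = TRUE)
  expect_equal(unname(withs$frequencies["ATG"]), 1 / 4)
})

test_that("frequencies are normalized over random CDSs", {
  tx <- make_transcriptome(100, seed = 31, n_codons_range = c(20L, 40L))
  prof <- codon_profiles(tx)
  expect_equal(unname(rowSums(prof)), rep(1, 100), tolerance = 1e-12)
})

test_that("rank percentile uses the strict-greater convention", {
  prof <- matrix(0, nrow = 3, ncol = 61,
                 dimnames = list(c("t1", "t2", "t3"), sense_codons()))
  prof[, "AGC"] <- c(0.10, 0.05, 0.01)
  expect_equal(codon_rank_percentile("t1", "AGC", prof), 0)
  expect_equal(codon_rank_percentile("t2", "AGC", prof), 1 / 3)
  prof[, "AGC"] <- 0.05
  expect_equal(unname(vapply(rownames(prof), codon_rank_percentile,
                             numeric(1), codon = "AGC", profiles = prof)),
               rep(0, 3))
  expect_error(codon_rank_percentile("nope", "AGC", prof), "unknown")
  # a planted codon-rich gene among 199 background genes ranks in the top 1%
  tx <- make_transcriptome(200, seed = 33, target_fraction = 1 / 200,
                           target_codons = "AGC", target_weight = 8)
  prof2 <- codon_profiles(tx)
  planted <- tx$gene_id[tx$class == "target-codon-rich"]
  expect_lte(codon_rank_percentile(planted, "AGC", prof2), 0.005)
})

test_that("rank percentile ignores transcript order and duplication", {
  tx <- make_transcriptome(30, seed = 35)
  prof <- codon_profiles(tx)
  shuffled <- prof[rev(seq_len(nrow(prof))), ]
  expect_equal(codon_rank_percentile("gene0005", "GAG", prof),
               codon_rank_percentile("gene0005", "GAG", shuffled))
})

test_that("enrichment statistic is antisymmetric and input-checked", {
  tx <- make_transcriptome(60, seed = 37)
  prof <- codon_profiles(tx)
  up <- tx$gene_id[1:15]
  bg <- tx$gene_id[16:60]
  e1 <- te_codon_enrichment(up, bg, c("AGC", "GAG"), prof, n_perm = 200,
                            seed = 1)
  e2 <- te_codon_enrichment(bg, up, c("AGC", "GAG"), prof, n_perm = 200,
                            seed = 1)
  expect_equal(e1$statistic, -e2$statistic)
  expect_error(te_codon_enrichment(up, c(bg, up[1]), "AGC", prof), "disjoint")
  expect_error(te_codon_enrichment(up, bg, "AGC", prof, n_perm = 10),
               "n_perm")
})

test_that("elevated tRNAs map to their decoded codons", {
  mkdiff <- function(ids, elev) {
    data.frame(ref_id = ids, stoich_A = 0.5, stoich_B = 0.6, diff = 0.1,
               band = "medium", elevated_in_B = elev,
               missing_condition = FALSE, stringsAsFactors = FALSE)
  }
  d1 <- mkdiff("tRNA-Ala-AGC-1", TRUE)
  expect_equal(linked_codons(d1), "GCT")
  expect_equal(linked_codons(mkdiff("tRNA-Ala-AGC-1", FALSE)), character(0))
  four <- mkdiff(c("tRNA-Asp-GTC-1", "tRNA-Ala-AGC-1", "tRNA-Glu-CTC-1",
                   "tRNA-Ser-GCT-1"), TRUE)
  expect_setequal(linked_codons(four), c("GAC", "GCT", "GAG", "AGC"))
  expect_setequal(linked_codons(four, wobble = TRUE),
                  c("GAC", "GAT", "GCT", "GAG", "AGC", "AGT"))
})

test_that("reporter normalization is a ratio of F/R ratios", {
  expect_equal(normalize_reporter(list(f_luc = 4, r_luc = 2),
                                  list(f_luc = 1, r_luc = 1)), 2)
  expect_equal(normalize_reporter(list(f_luc = 3, r_luc = 3),
                                  list(f_luc = 3, r_luc = 3)), 1)
  expect_equal(normalize_reporter(list(f_luc = 40, r_luc = 20),
                                  list(f_luc = 10, r_luc = 10)), 2)
  expect_error(normalize_reporter(list(f_luc = 1, r_luc = 0),
                                  list(f_luc = 1, r_luc = 1)), "r_luc")
})
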