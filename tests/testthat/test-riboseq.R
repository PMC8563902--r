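test_that("P-site offset is recovered from construction, including shifts", {
  tx <- make_transcriptome(10, seed = 4)
  txref <- setNames(tx$transcript, tx$gene_id)
  sim12 <- simulate_ribo_rna(tx, 1, 4000, 10, seed = 6, jitter = 0)
  prof12 <- footprint_profiles(
    align_reads(filter_footprints(sim12$ribo), txref), tx)
  expect_equal(p_site_offset(prof12), 12L)
  expect_equal(periodicity(prof12, 12L), 1.0)
  # footprints constructed with a 13-nt offset are detected as such
  sim13 <- simulate_ribo_rna(tx, 1, 4000, 10, seed = 6, jitter = 0,
                             p_site_offset = 13L)
  prof13 <- footprint_profiles(
    align_reads(filter_footprints(sim13$ribo), txref), tx)
  expect_equal(p_site_offset(prof13), 13L)
  # 1-nt symmetric jitter still leaves 12 as the modal offset
  simj <- simulate_ribo_rna(tx, 1, 4000, 10, seed = 8, jitter = 1)
  profj <- footprint_profiles(
    align_reads(filter_footprints(simj$ribo), txref), tx)
  expect_equal(p_site_offset(profj), 12L)
})

test_that("periodicity is invariant to transcript relabeling", {
  tx <- make_transcriptome(6, seed = 9)
  txref <- setNames(tx$transcript, tx$gene_id)
  sim <- simulate_ribo_rna(tx, 1, 2000, 10, seed = 3, jitter = 1)
  prof <- footprint_profiles(
    align_reads(filter_footprints(sim$ribo), txref), tx)
  f1 <- periodicity(prof, 12L)
  perm <- rev(seq_len(nrow(tx)))
  tx2 <- tx[perm, ]
  tx2$gene_id <- paste0("re", seq_len(nrow(tx)))
  prof2 <- prof
  prof2$transcript_id <- tx2$gene_id[match(prof$transcript_id,
                                           tx$gene_id[perm])]
  attr(prof2, "transcripts") <- tx2
  expect_equal(periodicity(prof2, 12L), f1)
  expect_equal(sum(frame_counts(prof, 12L)),
               sum(prof$rel5 + 12 >= 0 &
                     prof$rel5 + 12 < tx$cds_len[match(prof$transcript_id,
                                                       tx$gene_id)]))
})

test_that("RPKM follows its closed form and scaling law", {
  expect_equal(rpkm(100, 500, 1e6), 200)
  expect_equal(rpkm(0, 500, 1e6), 0)
  expect_equal(rpkm(100, 500, 2e6), 100)  # doubling the library halves RPKM
  expect_error(rpkm(10, 0, 1e6), "cds_length")
  expect_error(rpkm(10, 500, 0), "total_mapped")
})

test_that("TE is the Ribo/RNA RPKM ratio, undefined at zero RNA", {
  expect_equal(translation_efficiency(200, 50), 4)
  expect_equal(translation_efficiency(0, 50), 0)
  expect_true(is.na(translation_efficiency(200, 0)))
  expect_equal(translation_efficiency(200, 0, pseudocount = 1), 201 / 1)
})

test_that("TE recovery: rank correlation and limiting unbiasedness", {
  tx <- make_transcriptome(40, seed = 12)
  txref <- setNames(tx$transcript, tx$gene_id)
  te_true <- rep(c(0.5, 1, 2, 8), each = 10)
  sim <- simulate_ribo_rna(tx, te_true, depth_ribo = 1e5, depth_rna = 1e5,
                           seed = 14)
  al_r <- align_reads(filter_footprints(sim$ribo), txref)
  al_n <- align_reads(sim$rna, txref)
  te <- compute_te(al_r, al_n, tx)
  expect_gte(cor(te$te, sim$truth$expected_te, method = "spearman"), 0.9)
  # limiting unbiasedness: with >= 500 counts per gene the mean estimate
  # tracks the expected (normalization-adjusted) TE within 5%
  tx2 <- make_transcriptome(8, seed = 15)
  txref2 <- setNames(tx2$transcript, tx2$gene_id)
  te2 <- rep(c(1, 4), each = 4)
  ratios <- vapply(1:30, function(s) {
    sm <- simulate_ribo_rna(tx2, te2, depth_ribo = 6000, depth_rna = 6000,
                            seed = 100 + s)
    t <- compute_te(align_reads(filter_footprints(sm$ribo), txref2),
                    align_reads(sm$rna, txref2), tx2)
    mean(t$te / sm$truth$expected_te)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.05)
})

test_that("fold-change-4 classification is exact and antisymmetric", {
  mk_te <- function(te) data.frame(transcript_id = paste0("g", seq_along(te)),
                                   te = te, stringsAsFactors = FALSE)
  a <- mk_te(c(1, 1, 8, 2, 0, 1))
  b <- mk_te(c(8, 3.9, 1, 2, 1, NA))
  d <- differential_te(a, b)
  expect_equal(d$te_class[1:4], c("up", "unchanged", "down", "unchanged"))
  expect_equal(d$te_class[5], "up")        # 0 -> 1 is an infinite fold
  expect_true(d$excluded[6])
  # swapping conditions maps up <-> down and fixes unchanged
  dswap <- differential_te(b, a)
  map <- c(up = "down", down = "up", unchanged = "unchanged")
  expect_equal(unname(map[d$te_class[1:5]]), dswap$te_class[1:5])
})
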