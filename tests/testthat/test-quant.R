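mk_aln <- function(read_id, ref_id, ref_start, umi, seq = "ACGT",
                   cigar = paste0(nchar(seq), "M")) {
  data.frame(read_id = read_id, ref_id = ref_id, ref_start = ref_start,
             score = nchar(seq), n_mismatch = 0L, cigar = cigar, seq = seq,
             qwidth = nchar(seq), is_unique = TRUE, umi = umi,
             stringsAsFactors = FALSE)
}

test_that("dedup keeps one representative per (ref, start, barcode) key", {
  alns <- rbind(mk_aln("r1", "t1", 0L, "AAAAAAAAAA"),
                mk_aln("r2", "t1", 0L, "AAAAAAAAAA"),
                mk_aln("r3", "t1", 0L, "CCCCCCCCCC"))
  out <- dedup(alns)
  expect_equal(nrow(out), 2L)
  expect_true("r1" %in% out$read_id)  # first in stable read_id order
  # same barcode at a different position is NOT a duplicate: both conditions
  # (identical position AND identical barcode) are required
  alns2 <- rbind(mk_aln("r1", "t1", 0L, "AAAAAAAAAA"),
                 mk_aln("r2", "t1", 5L, "AAAAAAAAAA"))
  expect_equal(nrow(dedup(alns2)), 2L)
  # idempotence
  expect_identical(dedup(out)$read_id, out$read_id)
  expect_error(dedup(alns[, setdiff(names(alns), "umi")]), "umi")
})

test_that("dedup equals the independent distinct-key construction", {
  refs <- make_trna_reference(6, seed = 3)
  truth <- sim_truth(refs, 0.5, pcr_duplication_mean = 1.5)
  lib <- simulate_trna_library(refs, truth, 3000, seed = 17)
  alns <- align_reads(extract_umi(trim_reads(lib$reads)), refs)
  dd <- dedup(alns)
  expect_equal(nrow(dd), oracle_dedup_count(alns))
  expect_identical(dedup(dd)$read_id, dd$read_id)
  expect_lte(nrow(dd), nrow(alns))
})

test_that("pileup counts bases per position and skips N", {
  ref <- c(t1 = "AACCGGTTAACC")
  reads <- vapply(1:10, function(i) substr(ref, 1, 12), character(1))
  alns <- mk_aln(paste0("r", 1:10), "t1", 0L, strrep("A", 10), seq = reads,
                 cigar = "12M")
  pu <- pileup(alns, ref)
  expect_equal(pu$A[1], 10L)
  expect_equal(pu$coverage, rep(10L, 12))
  # one substitution A->G at position 0
  alns$seq[1] <- paste0("G", substr(alns$seq[1], 2, 12))
  pu2 <- pileup(alns, ref)
  expect_equal(pu2$A[1], 9L)
  expect_equal(pu2$G[1], 1L)
  # N contributes to neither numerator nor denominator
  alns$seq[2] <- paste0("N", substr(alns$seq[2], 2, 12))
  pu3 <- pileup(alns, ref)
  expect_equal(pu3$coverage[1], 9L)
  expect_error(pileup(mk_aln("r", "nope", 0L, "AAAAAAAAAA"), ref), "unknown")
})

test_that("pileup equals a direct recount from alignment records", {
  refs <- make_trna_reference(5, seed = 21)
  truth <- sim_truth(refs, c(0, 0.3, 0.6, 0.9, 0.5))
  lib <- simulate_trna_library(refs, truth, 800, seed = 23)
  dd <- dedup(align_reads(extract_umi(trim_reads(lib$reads)), refs))
  pu <- pileup(dd, refs)
  oc <- oracle_pileup(dd, refs)
  for (rid in refs$ref_id) {
    sub <- pu[pu$ref_id == rid, ]
    expect_equal(unname(as.matrix(sub[, c("A", "C", "G", "T", "deletions")])),
                 unname(t(oc[[rid]])))
  }
})

test_that("mismatch rate follows its closed form and flags zero coverage", {
  p <- data.frame(ref_id = "t", pos = 0L, ref_base = "A",
                  A = 900L, C = 20L, G = 50L, T = 30L, deletions = 0L,
                  coverage = 1000L)
  expect_equal(mismatch_rate(p), 0.10)
  p$C <- p$G <- p$T <- 0L; p$coverage <- 900L
  expect_equal(mismatch_rate(p), 0)
  p$A <- 0L; p$coverage <- 0L
  expect_true(is.na(mismatch_rate(p)))
})

test_that("site calling requires coverage and a demethylation contrast", {
  refs <- make_trna_reference(3, seed = 2)
  mkpu <- function(rates, cov) {
    do.call(rbind, lapply(seq_len(nrow(refs)), function(i) {
      nonref <- round(cov * rates[i])
      data.frame(ref_id = refs$ref_id[i], pos = refs$a58_index[i],
                 ref_base = "A", A = cov - nonref, C = nonref, G = 0L, T = 0L,
                 deletions = 0L, coverage = cov)
    }))
  }
  calls <- call_m1a58(mkpu(c(0.45, 0.004, 0.30), 1000L),
                      mkpu(c(0.01, 0.003, 0.29), 1000L), refs)
  expect_equal(calls$called, c(TRUE, FALSE, FALSE))
  expect_equal(calls$stoichiometry[1], 0.45)
  expect_equal(calls$delta[1], 0.44)
  expect_equal(calls$band, c("medium", "low", "medium"))
  # background subtraction mode reports delta as the stoichiometry
  calls_bs <- call_m1a58(mkpu(c(0.45, 0.004, 0.30), 1000L),
                         mkpu(c(0.01, 0.003, 0.29), 1000L), refs,
                         call_config(background_subtract = TRUE))
  expect_equal(calls_bs$stoichiometry[1], 0.44)
  # insufficient coverage is recorded, not dropped
  low <- call_m1a58(mkpu(c(0.45, 0, 0), 10L), mkpu(c(0, 0, 0), 10L), refs)
  expect_equal(nrow(low), 3L)
  expect_false(any(low$called))
  expect_false(any(low$min_cov_ok))
})

test_that("perfect demethylation with no error leaves a rate of exactly 0", {
  refs <- make_trna_reference(4, seed = 11)
  truth <- sim_truth(refs, 0.9, demethylation_efficiency = 1.0,
                     sequencing_error_rate = 0, pcr_duplication_mean = 0)
  pu_d <- trna_arm_pileup(refs, truth, 800, demethylated = TRUE, seed = 31)
  calls <- call_m1a58(pu_d, pu_d, refs)
  expect_equal(calls$mism_demethylated, rep(0, 4))
})

test_that("differential methylation flags elevated tRNAs and sorts by diff", {
  mkcalls <- function(ids, stoich, called) {
    data.frame(ref_id = ids, position = 60L, mism_untreated = stoich,
               mism_demethylated = 0, delta = stoich, stoichiometry = stoich,
               cov_untreated = 1000L, cov_demethylated = 1000L,
               min_cov_ok = TRUE, called = called,
               band = as.character(cut(stoich, c(-Inf, 0.3, 0.9, Inf),
                                       labels = c("low", "medium", "high"),
                                       right = FALSE)),
               stringsAsFactors = FALSE)
  }
  a <- mkcalls(c("tRNA-Ala-AGC-1", "tRNA-Asp-GTC-1", "tRNA-Gly-GCC-1"),
               c(0.50, 0.95, 0.10), c(TRUE, TRUE, TRUE))
  b <- mkcalls(c("tRNA-Ala-AGC-1", "tRNA-Asp-GTC-1", "tRNA-Gly-GCC-1"),
               c(0.62, 0.95, 0.10), c(TRUE, TRUE, TRUE))
  dm <- differential_m1a(a, b)
  expect_equal(dm$ref_id[1], "tRNA-Ala-AGC-1")  # sorted by diff, descending
  expect_equal(dm$diff[1], 0.12)
  expect_true(dm$elevated_in_B[dm$ref_id == "tRNA-Ala-AGC-1"])
  # saturated tRNAs show no apparent difference and are never flagged
  expect_false(dm$elevated_in_B[dm$ref_id == "tRNA-Asp-GTC-1"])
  # a ref missing from one condition is flagged and excluded
  dm2 <- differential_m1a(a[-3, ], b)
  expect_true(dm2$missing_condition[dm2$ref_id == "tRNA-Gly-GCC-1"])
  expect_false(dm2$elevated_in_B[dm2$ref_id == "tRNA-Gly-GCC-1"])
})
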