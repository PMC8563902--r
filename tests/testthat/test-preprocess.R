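cfg <- preprocess_config()
adapter <- cfg$adapter3

mk_read <- function(seq, qual = strrep("I", nchar(seq)), id = "r1") {
  data.frame(id = id, seq = seq, qual = qual, stringsAsFactors = FALSE)
}

test_that("full and partial adapters are removed; adapter-free reads kept", {
  insert <- "ACGTACGTACGTACGTACGTACGTACGT"
  out <- trim_reads(mk_read(paste0(insert, adapter)), cfg)
  expect_equal(out$seq, insert)
  out2 <- trim_reads(mk_read(insert), cfg)
  expect_equal(out2$seq, insert)
  # partial 7-nt adapter overlap at the very end
  out3 <- trim_reads(mk_read(paste0(insert, substr(adapter, 1, 7))), cfg)
  expect_equal(out3$seq, insert)
  # 4-nt overlap is below the minimum and stays
  out4 <- trim_reads(mk_read(paste0(insert, substr(adapter, 1, 4))), cfg)
  expect_equal(nchar(out4$seq), nchar(insert) + 4L)
})

test_that("adapter matching tolerates mismatches like the exhaustive scan", {
  set.seed(42)
  insert <- random_read(40)
  mut <- adapter
  substr(mut, 5, 5) <- "T"  # adapter has C there
  out <- trim_reads(mk_read(paste0(insert, mut)), cfg)
  expect_equal(out$seq, insert)
  # agreement with the brute-force best-overlap oracle on random reads
  for (i in 1:25) {
    sq <- paste0(random_read(sample(20:60, 1)),
                 substr(adapter, 1, sample(0:19, 1)))
    expect_equal(cpp_find_adapter(sq, adapter, cfg$min_overlap,
                                  cfg$mismatch_tol),
                 oracle_adapter_pos(sq, adapter, cfg$min_overlap,
                                    cfg$mismatch_tol),
                 info = sq)
  }
})

test_that("3' quality trimming removes low-quality tails at Q20", {
  sq <- strrep("A", 30)
  qual <- paste0(strrep("I", 20), strrep("#", 10))  # Q40 then Q2 tail
  out <- trim_reads(mk_read(sq, qual), cfg)
  expect_equal(nchar(out$seq), 20L)
  expect_equal(nchar(out$seq), nchar(out$qual))
  # an all-bad read is discarded, counted in the summary
  gone <- trim_reads(mk_read(strrep("A", 10), strrep("#", 10)), cfg)
  expect_equal(nrow(gone), 0L)
  expect_equal(attr(gone, "summary")$discarded, 1L)
})

test_that("trimming never lengthens and umi+remainder rebuilds the read", {
  refs <- make_trna_reference(4, seed = 7)
  truth <- sim_truth(refs, 0.5)
  lib <- simulate_trna_library(refs, truth, 300, seed = 4)
  tr <- trim_reads(lib$reads, cfg)
  ix <- match(tr$id, lib$reads$id)
  expect_true(all(nchar(tr$seq) <= nchar(lib$reads$seq[ix])))
  um <- extract_umi(tr, 10)
  expect_identical(paste0(um$umi, um$seq), tr$seq[match(um$id, tr$id)])
  expect_true(all(nchar(um$seq) == nchar(um$qual)))
})

test_that("barcode extraction discards reads not longer than the barcode", {
  r <- mk_read("ACGTACGTACTTTT")
  um <- extract_umi(r, 10)
  expect_equal(um$umi, "ACGTACGTAC")
  expect_equal(um$seq, "TTTT")
  short <- extract_umi(mk_read("ACGTACGTAC"), 10)
  expect_equal(nrow(short), 0L)
  expect_equal(attr(short, "summary")$discarded, 1L)
})

test_that("footprint length filter keeps the 25-33 nt window inclusively", {
  reads <- do.call(rbind, lapply(c(24, 25, 33, 34), function(L)
    mk_read(strrep("A", L), id = paste0("len", L))))
  out <- filter_footprints(reads, cfg)
  expect_equal(out$id, c("len25", "len33"))
  expect_equal(nrow(filter_footprints(reads[0, ], cfg)), 0L)
  # retained count matches a direct recount on a simulated footprint set
  tx <- make_transcriptome(5, seed = 5)
  sim <- simulate_ribo_rna(tx, 1, depth_ribo = 10000, depth_rna = 10,
                           seed = 5, len_probs = rep(1, 9))
  kept <- filter_footprints(sim$ribo, cfg)
  expect_equal(nrow(kept),
               sum(nchar(sim$ribo$seq) >= 25 & nchar(sim$ribo$seq) <= 33))
})
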