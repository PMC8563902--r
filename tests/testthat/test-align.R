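params <- align_params()

test_that("an exact substring aligns at the right offset with full score", {
  set.seed(1)
  refs <- setNames(vapply(1:4, function(i) random_read(80), character(1)),
                   paste0("ref", 1:4))
  read <- substr(refs[1], 11, 50)
  hit <- align_read(read, refs, params)
  expect_equal(hit$ref_id, "ref1")
  expect_equal(hit$ref_start, 10L)
  expect_equal(hit$score, 40L)
  expect_equal(hit$n_mismatch, 0L)
  expect_true(hit$is_unique)
})

test_that("a substitution adds one mismatch without moving the alignment", {
  set.seed(2)
  refs <- setNames(vapply(1:4, function(i) random_read(80), character(1)),
                   paste0("ref", 1:4))
  read <- substr(refs[2], 11, 50)
  pos <- 20L
  old <- substr(read, pos, pos)
  substr(read, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  hit <- align_read(read, refs, params)
  expect_equal(hit$ref_id, "ref2")
  expect_equal(hit$ref_start, 10L)
  expect_equal(hit$n_mismatch, 1L)
  expect_equal(hit$score, 38L)
  expect_equal(hit$score, oracle_glocal_score(read, refs[[2]]))
})

test_that("random reads fail the score threshold and are unaligned", {
  set.seed(3)
  refs <- setNames(vapply(1:4, function(i) random_read(80), character(1)),
                   paste0("ref", 1:4))
  for (i in 1:5) expect_null(align_read(random_read(40), refs, params))
})

test_that("terminal junk is absorbed by bounded zero-cost soft clips", {
  set.seed(4)
  ref <- c(r = random_read(80))
  core <- substr(ref, 21, 60)
  read <- paste0(core, "NN")
  substr(read, 41, 42) <- "GG"  # junk unlikely to match downstream ref
  hit <- align_read(read, ref, params)
  expect_gte(hit$score, 38L)
  chk <- score_from_cigar(read, ref[[1]], hit$ref_start, hit$cigar)
  expect_equal(chk$score, hit$score)
})

test_that("aligner score and path agree with the DP oracle on random pairs", {
  set.seed(5)
  for (i in 1:60) {
    m <- sample(20:100, 1)
    n <- sample(30:100, 1)
    ref <- random_read(n)
    if (i %% 3 == 0) {
      read <- random_read(m)          # unrelated pair
    } else {                          # mutated substring with an indel
      s <- sample(seq_len(max(1, n - m + 1)), 1)
      read <- substr(ref, s, min(n, s + m - 1))
      if (nchar(read) > 10) {
        p <- sample(3:(nchar(read) - 3), 1)
        read <- if (i %% 2 == 0)
          paste0(substr(read, 1, p), substr(read, p + 2, nchar(read)))
        else paste0(substr(read, 1, p), "A", substr(read, p + 1, nchar(read)))
      }
    }
    res <- cpp_align_one(read, ref, 1L, -1L, -3L, -1L, 2L)
    expect_equal(res$score[1], oracle_glocal_score(read, ref),
                 info = paste(read, ref))
    chk <- score_from_cigar(read, ref, res$ref_start[1], res$cigar[1])
    expect_equal(chk$score, res$score[1])
    expect_equal(chk$n_mismatch, res$n_mismatch[1])
    expect_equal(chk$read_consumed, nchar(read))
  }
})

test_that("batch alignment equals single-read DP alignment on library reads", {
  refs <- make_trna_reference(8, seed = 7)
  truth <- sim_truth(refs, 0.5, pcr_duplication_mean = 0)
  lib <- simulate_trna_library(refs, truth, 400, seed = 13)
  um <- extract_umi(trim_reads(lib$reads))
  batch <- align_reads(um, refs)
  take <- seq(1, nrow(batch), by = 7)
  for (q in take) {
    single <- align_read(batch$seq[q], refs)
    expect_equal(batch$score[q], single$score)
    expect_equal(batch$ref_id[q], single$ref_id)
    expect_equal(batch$ref_start[q], single$ref_start)
  }
})

test_that("a substitution at position 58 never moves the mapping position", {
  refs <- make_trna_reference(6, seed = 9)
  for (i in seq_len(nrow(refs))) {
    clean <- refs$sequence[i]
    mod <- clean
    p <- refs$a58_index[i] + 1L
    substr(mod, p, p) <- "T"
    h0 <- align_read(clean, refs)
    h1 <- align_read(mod, refs)
    expect_equal(h1$ref_id, refs$ref_id[i])
    expect_equal(h1$ref_start, h0$ref_start)
    expect_equal(h1$n_mismatch, h0$n_mismatch + 1L)
  }
})

test_that("multimap resolution honors its policy and is seeded", {
  hits <- data.frame(read_id = "r", ref_id = c("a", "b"), ref_start = c(0, 0),
                     score = c(40, 40), n_mismatch = c(0, 0),
                     cigar = c("40M", "40M"), stringsAsFactors = FALSE)
  expect_null(resolve_multimap(hits, "best-unique"))
  expect_null(resolve_multimap(hits, "drop"))
  p1 <- resolve_multimap(hits, "random-tiebreak", seed = 5)
  p2 <- resolve_multimap(hits, "random-tiebreak", seed = 5)
  expect_identical(p1, p2)
  single <- hits[1, , drop = FALSE]
  expect_identical(resolve_multimap(single, "best-unique"), single)
  expect_error(resolve_multimap(hits, "nonsense"), "unknown")
})
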