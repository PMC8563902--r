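# Independent oracles used to cross-check the implementation.  These are
# written as separate formulations (row-vectorized DP with a running-maximum
# gap recurrence, set constructions, direct recounts) so they share no code
# path with the package internals they validate.

# Best glocal score: read global with up to `clip` free bases at either end,
# reference ends free, gap of length L costing gap_open + L * gap_ext.
oracle_glocal_score <- function(read, ref, match = 1, mismatch = -1,
                                gap_open = -3, gap_ext = -1, clip = 2) {
  rd <- strsplit(read, "")[[1]]
  rf <- strsplit(ref, "")[[1]]
  m <- length(rd); n <- length(rf)
  NEG <- -1e9
  Mprev <- rep(NEG, n + 1)
  Xprev <- rep(NEG, n + 1)
  Yprev <- rep(NEG, n + 1)
  best <- NEG
  for (i in seq_len(m)) {
    s <- ifelse(rd[i] == "N" | rf == "N", 0,
                ifelse(rd[i] == rf, match, mismatch))
    start <- if (i - 1 <= clip) 0 else NEG
    diagmax <- pmax(Mprev[1:n], Xprev[1:n], Yprev[1:n], start)
    Mrow <- c(NEG, ifelse(diagmax <= NEG, NEG, diagmax + s))
    Xrow <- pmax(Mprev + gap_open + gap_ext, Xprev + gap_ext)
    # gap in the read along the row, via the running-maximum identity
    # Y[j] = go + ge*j + max_{j' < j} (M[j'] - ge*j')
    z <- Mrow - gap_ext * (0:n)
    run <- cummax(z)[1:n]
    Yrow <- c(NEG, gap_open + gap_ext * (1:n) + run)
    Yrow[Yrow < NEG / 2] <- NEG
    Xrow[Xrow < NEG / 2] <- NEG
    if (i >= m - clip) best <- max(best, Mrow[2:(n + 1)])
    Mprev <- Mrow; Xprev <- Xrow; Yprev <- Yrow
  }
  best
}

# Recompute score / mismatches implied by a CIGAR path; used to verify that
# the aligner's reported path is a valid alignment achieving its score.
score_from_cigar <- function(read, ref, ref_start, cigar, match = 1,
                             mismatch = -1, gap_open = -3, gap_ext = -1) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDS]", cigar))[[1]]
  len <- as.integer(sub("[MIDS]", "", ops))
  op <- sub("[0-9]+", "", ops)
  qi <- 0L; ri <- ref_start; sc <- 0; nmm <- 0L; nclip <- 0L
  for (t in seq_along(op)) {
    L <- len[t]
    if (op[t] == "S") { qi <- qi + L; nclip <- nclip + L }
    else if (op[t] == "I") { sc <- sc + gap_open + gap_ext * L; qi <- qi + L }
    else if (op[t] == "D") { sc <- sc + gap_open + gap_ext * L; ri <- ri + L }
    else {
      av <- strsplit(substr(read, qi + 1L, qi + L), "")[[1]]
      bv <- strsplit(substr(ref, ri + 1L, ri + L), "")[[1]]
      isn <- av == "N" | bv == "N"
      sc <- sc + sum(!isn & av == bv) * match + sum(!isn & av != bv) * mismatch
      nmm <- nmm + sum(!isn & av != bv)
      qi <- qi + L; ri <- ri + L
    }
  }
  list(score = sc, n_mismatch = nmm, read_consumed = qi, clipped = nclip)
}

# Distinct-(ref, start, umi) set size, built independently of dedup()
oracle_dedup_count <- function(alns) {
  length(unique(mapply(function(a, b, c) paste(a, b, c, sep = "\036"),
                       alns$ref_id, alns$ref_start, alns$umi)))
}

# Earliest adapter position by exhaustive best-overlap scan
oracle_adapter_pos <- function(seq, adapter, min_overlap = 5L, tol = 0.1) {
  L <- nchar(seq); alen <- nchar(adapter)
  for (i in 0:(L - min_overlap)) {
    ov <- min(alen, L - i)
    a <- strsplit(substr(seq, i + 1L, i + ov), "")[[1]]
    b <- strsplit(substr(adapter, 1L, ov), "")[[1]]
    if (sum(a != b) <= floor(tol * ov)) return(i)
  }
  L
}

# Direct per-position base recount from alignment records
oracle_pileup <- function(alns, refs) {
  rs <- if (is.data.frame(refs)) setNames(refs$sequence, refs$ref_id) else refs
  counts <- lapply(rs, function(s)
    matrix(0L, nrow = 5, ncol = nchar(s),
           dimnames = list(c("A", "C", "G", "T", "del"), NULL)))
  for (q in seq_len(nrow(alns))) {
    ops <- regmatches(alns$cigar[q], gregexpr("[0-9]+[MIDS]",
                                              alns$cigar[q]))[[1]]
    len <- as.integer(sub("[MIDS]", "", ops))
    op <- sub("[0-9]+", "", ops)
    qi <- 0L; ri <- alns$ref_start[q]
    cm <- counts[[alns$ref_id[q]]]
    for (t in seq_along(op)) {
      L <- len[t]
      if (op[t] %in% c("S", "I")) qi <- qi + L
      else if (op[t] == "D") {
        cm["del", (ri + 1L):(ri + L)] <- cm["del", (ri + 1L):(ri + L)] + 1L
        ri <- ri + L
      } else {
        b <- strsplit(substr(alns$seq[q], qi + 1L, qi + L), "")[[1]]
        for (u in seq_len(L)) {
          if (b[u] %in% c("A", "C", "G", "T"))
            cm[b[u], ri + u] <- cm[b[u], ri + u] + 1L
        }
        qi <- qi + L; ri <- ri + L
      }
    }
    counts[[alns$ref_id[q]]] <- cm
  }
  counts
}

random_read <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
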