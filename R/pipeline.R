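#' End-to-end run configuration
#'
#' Bundles every stage's parameters plus a global seed.  Stage seeds are
#' derived deterministically from the global seed, so one config + seed
#' pair fixes the whole report bundle byte-for-byte.
#'
#' @param seed global integer seed.
#' @param n_trna number of tRNA families (default 20).
#' @param coverage target deduplicated molecules per tRNA per arm
#'   (default 1500).
#' @param stoich_A,stoich_B per-tRNA stoichiometries for the two biological
#'   conditions, recycled to `n_trna`.  Defaults plant four elevated
#'   medium-methylation tRNAs (the first four families) on a background of
#'   high / medium / low / unmethylated tRNAs.
#' @param demethylation_efficiency,sequencing_error_rate,pcr_duplication_mean
#'   simulator globals (see [sim_truth()]).
#' @param n_genes,target_fraction,target_weight transcriptome parameters
#'   (see [make_transcriptome()]); by default the target class is enriched
#'   for the codons decoded by the four elevated tRNAs.
#' @param te_fold true TE fold increase of target-class genes in condition B
#'   (default 10).  Estimated folds are compressed by the library-wide TE
#'   normalization (the abundance-weighted mean TE of the changed
#'   condition), so the planted fold must clear `fc_threshold` times that
#'   constant; with 10% of genes at 10x the constant is 1.9 and the
#'   estimable fold is ~5.3.
#' @param depth_ribo,depth_rna per-condition Ribo-seq / RNA-seq depths.
#' @param preprocess,align,call stage configs ([preprocess_config()],
#'   [align_params()], [call_config()]).
#' @param n_perm permutations for the enrichment test (default 1000).
#' @return a list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       n_trna = 20L,
                       coverage = 1500L,
                       stoich_A = c(rep(0.45, 4),
                                    rep(c(0.92, 0.5, 0.2, 0), each = 4)),
                       stoich_B = c(rep(0.60, 4),
                                    rep(c(0.92, 0.5, 0.2, 0), each = 4)),
                       demethylation_efficiency = 1.0,
                       sequencing_error_rate = 0.002,
                       pcr_duplication_mean = 1.0,
                       n_genes = 60L,
                       target_fraction = 0.1,
                       target_weight = 3,
                       te_fold = 10,
                       depth_ribo = 40000L,
                       depth_rna = 40000L,
                       preprocess = preprocess_config(),
                       align = align_params(),
                       call = call_config(),
                       n_perm = 1000L) {
  fr <- c(sequencing_error_rate = sequencing_error_rate,
          demethylation_efficiency = demethylation_efficiency,
          target_fraction = target_fraction)
  bad <- names(fr)[fr < 0 | fr > 1]
  if (length(bad))
    stop(sprintf("`%s` must be a fraction in [0, 1]", bad[1]), call. = FALSE)
  cfg <- list(seed = as.integer(seed), n_trna = as.integer(n_trna),
              coverage = as.integer(coverage),
              stoich_A = rep_len(stoich_A, n_trna),
              stoich_B = rep_len(stoich_B, n_trna),
              demethylation_efficiency = demethylation_efficiency,
              sequencing_error_rate = sequencing_error_rate,
              pcr_duplication_mean = pcr_duplication_mean,
              n_genes = as.integer(n_genes),
              target_fraction = target_fraction,
              target_weight = target_weight,
              te_fold = te_fold,
              depth_ribo = as.integer(depth_ribo),
              depth_rna = as.integer(depth_rna),
              preprocess = preprocess, align = align, call = call,
              n_perm = as.integer(n_perm))
  cfg$hash <- config_hash(cfg[setdiff(names(cfg), "hash")])
  structure(cfg, class = "run_config")
}

# run one tRNA-seq arm end to end (simulate -> trim -> umi -> align -> dedup
# -> pileup), returning the pileup plus stage accounting
run_trna_arm <- function(refs, truth, cfg, condition, demethylated, seed) {
  lib <- simulate_trna_library(
    refs, truth, n_molecules = cfg$coverage * nrow(refs),
    demethylated = demethylated, condition = condition, seed = seed
  )
  trimmed <- trim_reads(lib$reads, cfg$preprocess)
  um <- extract_umi(trimmed, cfg$preprocess$umi_length)
  alns <- align_reads(um, refs, cfg$align)
  dd <- dedup(alns)
  pu <- pileup(dd, refs)
  list(pileup = pu, library = lib,
       log = list(condition = condition,
                  arm = if (demethylated) "demethylated" else "untreated",
                  simulated = nrow(lib$reads),
                  trimmed = attr(trimmed, "summary")$kept,
                  aligned = attr(alns, "summary")$aligned,
                  multimapped = attr(alns, "summary")$multimapped,
                  deduplicated = nrow(dd),
                  duplicate_fraction =
                    attr(dd, "summary")$duplicates / max(nrow(alns), 1L)))
}

#' Run the full pipeline on simulated data
#'
#' Simulates the study design (two biological conditions, each with an
#' untreated and a demethylated tRNA-seq arm, plus per-condition Ribo-seq
#' and RNA-seq libraries over a codon-biased transcriptome), processes every
#' arm through trimming, barcode extraction, alignment, deduplication and
#' pileup, calls m1A58 sites and differential methylation, computes
#' footprint QC and translation efficiency, classifies TE changes, and
#' tests the TE-up gene set for enrichment of codons decoded by the
#' elevated tRNAs.  Writes `calls_A.tsv`, `calls_B.tsv`, `diff.tsv`,
#' `te.tsv`, `enrichment.tsv`, `qc.json` and `manifest.json` (plus the
#' simulated FASTQ/FASTA inputs) under `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with every intermediate result (`refs`,
#'   `truth`, `calls_A`, `calls_B`, `diff`, `te`, `diff_te`, `enrichment`,
#'   `qc`, `logs`).
#' @export
run_all <- function(config = run_config(), out_dir) {
  if (missing(out_dir) || !is.character(out_dir))
    stop("`out_dir` must be supplied", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config
  refs <- make_trna_reference(cfg$n_trna, seed = derive_seed(cfg$seed, 1L))
  truth <- sim_truth(refs, cfg$stoich_A, cfg$stoich_B,
                     cfg$demethylation_efficiency,
                     cfg$sequencing_error_rate,
                     cfg$pcr_duplication_mean)
  write_fasta(refs, file.path(out_dir, "trna_refs.fasta"))

  arms <- list(
    A_U = run_trna_arm(refs, truth, cfg, "A", FALSE, derive_seed(cfg$seed, 2L)),
    A_D = run_trna_arm(refs, truth, cfg, "A", TRUE, derive_seed(cfg$seed, 3L)),
    B_U = run_trna_arm(refs, truth, cfg, "B", FALSE, derive_seed(cfg$seed, 4L)),
    B_D = run_trna_arm(refs, truth, cfg, "B", TRUE, derive_seed(cfg$seed, 5L))
  )
  for (nm in names(arms))
    write_fastq(arms[[nm]]$library$reads,
                file.path(out_dir, paste0("trna_", nm, ".fastq")))

  calls_A <- call_m1a58(arms$A_U$pileup, arms$A_D$pileup, refs, cfg$call)
  calls_B <- call_m1a58(arms$B_U$pileup, arms$B_D$pileup, refs, cfg$call)
  dm <- differential_m1a(calls_A, calls_B, cfg$call)
  codons <- linked_codons(dm)

  ## transcriptome biased toward the codons linked to elevated tRNAs
  target_codons <- if (length(codons)) codons else c("AGC", "GAG")
  tx <- make_transcriptome(cfg$n_genes, seed = derive_seed(cfg$seed, 6L),
                           target_fraction = cfg$target_fraction,
                           target_codons = target_codons,
                           target_weight = cfg$target_weight)
  te_true_A <- rep(1, cfg$n_genes)
  te_true_B <- ifelse(tx$class == "target-codon-rich", cfg$te_fold, 1)
  sim_A <- simulate_ribo_rna(tx, te_true_A, cfg$depth_ribo, cfg$depth_rna,
                             seed = derive_seed(cfg$seed, 7L))
  sim_B <- simulate_ribo_rna(tx, te_true_B, cfg$depth_ribo, cfg$depth_rna,
                             seed = derive_seed(cfg$seed, 8L))
  write_fastq(sim_B$ribo, file.path(out_dir, "ribo_B.fastq"))

  tx_refs <- setNames(tx$transcript, tx$gene_id)
  process_fp <- function(reads) {
    fp <- filter_footprints(reads, cfg$preprocess)
    align_reads(fp, tx_refs, cfg$align)
  }
  ribo_alns_A <- process_fp(sim_A$ribo)
  ribo_alns_B <- process_fp(sim_B$ribo)
  rna_alns_A <- align_reads(sim_A$rna, tx_refs, cfg$align)
  rna_alns_B <- align_reads(sim_B$rna, tx_refs, cfg$align)

  prof_B <- footprint_profiles(ribo_alns_B, tx)
  offset <- p_site_offset(prof_B)
  frame0 <- periodicity(prof_B, offset)
  lenhist <- footprint_length_histogram(prof_B)

  te_A <- compute_te(ribo_alns_A, rna_alns_A, tx, offset = offset)
  te_B <- compute_te(ribo_alns_B, rna_alns_B, tx, offset = offset)
  dte <- differential_te(te_A, te_B, fc_threshold = 4)

  up_ids <- dte$transcript_id[!is.na(dte$te_class) & dte$te_class == "up"]
  bg_ids <- dte$transcript_id[!is.na(dte$te_class) &
                                dte$te_class == "unchanged"]
  profiles <- codon_profiles(tx)
  enr <- if (length(up_ids) && length(bg_ids))
    te_codon_enrichment(up_ids, bg_ids, target_codons, profiles,
                        n_perm = cfg$n_perm,
                        seed = derive_seed(cfg$seed, 9L))
  else NULL

  meta <- c(config_hash = cfg$hash, seed = as.character(cfg$seed),
            tool = paste0("trnam1a ",
                          as.character(utils::packageVersion("trnam1a"))))
  write_tsv_report(calls_A, file.path(out_dir, "calls_A.tsv"), meta)
  write_tsv_report(calls_B, file.path(out_dir, "calls_B.tsv"), meta)
  write_tsv_report(dm, file.path(out_dir, "diff.tsv"), meta)
  te_out <- data.frame(transcript_id = te_B$transcript_id,
                       rpkm_ribo = te_B$rpkm_ribo, rpkm_rna = te_B$rpkm_rna,
                       te_A = dte$te_A[match(te_B$transcript_id,
                                             dte$transcript_id)],
                       te_B = dte$te_B[match(te_B$transcript_id,
                                             dte$transcript_id)],
                       te_class = dte$te_class[match(te_B$transcript_id,
                                                     dte$transcript_id)],
                       stringsAsFactors = FALSE)
  write_tsv_report(te_out, file.path(out_dir, "te.tsv"), meta)
  if (!is.null(enr))
    write_tsv_report(
      data.frame(statistic = enr$statistic, p_value = enr$p_value,
                 n_up = enr$n_up, n_background = enr$n_background,
                 codons = paste(enr$target_codons, collapse = ",")),
      file.path(out_dir, "enrichment.tsv"), meta)

  qc <- list(
    p_site_offset = offset,
    frame0_fraction = frame0,
    footprint_length_histogram = as.list(lenhist),
    dedup = lapply(arms, function(a) a$log$duplicate_fraction),
    stage_logs = lapply(arms, function(a) a$log)
  )
  jsonlite::write_json(qc, file.path(out_dir, "qc.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  jsonlite::write_json(
    list(config_hash = cfg$hash, seed = cfg$seed,
         outputs = sort(list.files(out_dir))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)

  invisible(list(refs = refs, truth = truth, calls_A = calls_A,
                 calls_B = calls_B, diff = dm, linked_codons = codons,
                 transcripts = tx, te_A = te_A, te_B = te_B, diff_te = dte,
                 enrichment = enr, qc = qc,
                 ribo_truth = list(A = sim_A$truth, B = sim_B$truth),
                 logs = lapply(arms, function(a) a$log)))
}
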