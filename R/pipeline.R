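# End-to-end run modes mirroring the tool's workflows: simulate (synthetic
# truth-tagged data, full SB/MB/AB categorization), predict (real reads with
# known HETs), scan (no variant foreknowledge), and compare (two workflows,
# joint baseline).

#' Simulate mode: end-to-end synthetic bias measurement
#'
#' Builds the two personalized haplotypes, simulates truth-tagged reads,
#' places them with the oracle aligner, optionally injects a bias event,
#' tallies evidence and writes the per-site bias report (TSV), the NMB-NAB
#' scatter and the bias-by-allele-length plot.
#'
#' @param ref_seqs named character vector of reference sequences (or a FASTA
#'   path).
#' @param variants variant data.frame (or a VCF path).
#' @param out_dir output directory (created); NULL skips all file output.
#' @param params a [sim_params()].
#' @param config an [assignment_config()].
#' @param classifier a [classifier_config()].
#' @param injections list of [bias_spec()] objects applied in order.
#' @param method assignment method for AB.
#' @param seed seed for bias injection sampling.
#' @return invisible list with `records` (per-site [balance_table()]),
#'   `reads`, `aligned`, `prep` per chromosome.
#' @export
run_simulate <- function(ref_seqs, variants, out_dir = NULL,
                         params = sim_params(), config = assignment_config(),
                         classifier = classifier_config(),
                         injections = list(), method = "context", seed = 1L) {
  if (is.character(ref_seqs) && length(ref_seqs) == 1L && file.exists(ref_seqs)) {
    ref_seqs <- read_fasta(ref_seqs)
  }
  if (is.character(variants)) variants <- read_phased_vcf(variants)
  all_records <- list(); all_aligned <- list(); preps <- list()
  for (chrom in names(ref_seqs)) {
    v <- variants[variants$chrom == chrom, , drop = FALSE]
    prep <- prepare_het_sites(v, ref_seqs[[chrom]], config)
    sim <- simulate_reads(list(prep$haps[[1]]$seq, prep$haps[[2]]$seq), params)
    aligned <- oracle_align(sim, list(prep$haps[[1]]$map, prep$haps[[2]]$map),
                            chrom, mapq_max = config$mapq_max)
    truth <- aligned
    for (k in seq_along(injections)) {
      aligned <- inject_bias(aligned, injections[[k]], seed = seed + k,
                             ref_seqs = ref_seqs,
                             read_length = params$read_length)
    }
    rec <- balance_table(prep$sites, truth, aligned, config, method = method,
                         cohorts = prep$cohorts, classifier = classifier)
    all_records[[chrom]] <- rec
    all_aligned[[chrom]] <- aligned
    preps[[chrom]] <- prep
  }
  records <- do.call(rbind, all_records)
  rownames(records) <- NULL
  aligned <- do.call(rbind, all_aligned)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (chrom in names(ref_seqs)) {
      write_fasta(setNames(
        c(preps[[chrom]]$haps[[1]]$seq, preps[[chrom]]$haps[[2]]$seq),
        paste0(chrom, c("_hap1", "_hap2"))),
        file.path(out_dir, paste0(chrom, "_haplotypes.fa")))
    }
    write_sam(aligned, vapply(ref_seqs, nchar, integer(1)),
              file.path(out_dir, "aligned_reads.sam"))
    write.table(drop_context_cols(records),
                file.path(out_dir, "bias_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    save_plot(plot_nmb_nab(records), file.path(out_dir, "nmb_nab.png"))
    bl <- bias_by_length(records)
    if (NROW(bl)) save_plot(plot_bias_by_length(bl),
                            file.path(out_dir, "bias_by_length.png"))
  }
  invisible(list(records = records, aligned = aligned, preps = preps))
}

drop_context_cols <- function(records) {
  records[, setdiff(names(records), c("ref_context", "alt_context"))]
}

#' Predict mode: rank likely-biased sites on real alignments
#'
#' Runs context-aware assignment at the prepared HET sites, filters
#' phasing-affected sites, computes the multiplicative and additive
#' prediction scores, and — when labels are supplied — evaluates the
#' rankings with ROC/PR curves.
#'
#' @param ref_seqs named reference sequences (or FASTA path).
#' @param variants variant data.frame (or VCF path).
#' @param alignments alignment data.frame (or SAM/BAM path).
#' @param out_dir output directory; NULL skips file output.
#' @param config an [assignment_config()].
#' @param pconfig a [predict_config()].
#' @param labels optional data.frame (`chrom`, `pos`, `label` in
#'   balanced/biased) for evaluation.
#' @param seed unused; kept for interface uniformity.
#' @return invisible list with `predictions`, `evidence`, and `evaluation`
#'   (per score mode) when labels were given.
#' @export
run_predict <- function(ref_seqs, variants, alignments, out_dir = NULL,
                        config = assignment_config(),
                        pconfig = predict_config(), labels = NULL, seed = 1L) {
  if (is.character(ref_seqs) && length(ref_seqs) == 1L && file.exists(ref_seqs)) {
    ref_seqs <- read_fasta(ref_seqs)
  }
  if (is.character(variants)) variants <- read_phased_vcf(variants)
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  preds <- list(); evs <- list()
  for (chrom in names(ref_seqs)) {
    v <- variants[variants$chrom == chrom, , drop = FALSE]
    if (!nrow(v)) next
    prep <- prepare_het_sites(v, ref_seqs[[chrom]], config)
    ev <- tally_sites(prep$sites, alignments, config, method = "context",
                      cohorts = prep$cohorts)
    preds[[chrom]] <- predict_sites(prep$sites, ev, pconfig)
    evs[[chrom]] <- cbind(prep$sites[, c("chrom", "pos", "ref", "alt")], ev)
  }
  predictions <- do.call(rbind, preds)
  evidence <- do.call(rbind, evs)
  rownames(predictions) <- rownames(evidence) <- NULL
  evaluation <- NULL
  if (!is.null(labels)) {
    lp <- transfer_labels(predictions, labels)
    keep <- !lp$affected & !is.na(lp$label) & !is.na(lp$AB)
    evaluation <- list(
      mul = evaluate_ranking(lp$score_mul[keep], lp$label[keep]),
      add = evaluate_ranking(lp$score_add[keep], lp$label[keep]))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(predictions, file.path(out_dir, "site_predictions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(evaluation)) {
      summ <- data.frame(mode = c("mul", "add"),
                         auc = c(evaluation$mul$auc, evaluation$add$auc),
                         auprc = c(evaluation$mul$auprc, evaluation$add$auprc))
      write.table(summ, file.path(out_dir, "ranking_summary.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      save_plot(plot_roc(evaluation), file.path(out_dir, "roc.png"))
      save_plot(plot_pr(evaluation), file.path(out_dir, "pr.png"))
    }
  }
  invisible(list(predictions = predictions, evidence = evidence,
                 evaluation = evaluation))
}

#' Scan mode: call biased regions with no variant foreknowledge
#'
#' @param pileup pileup data.frame, mpileup text path, or SAM/BAM path (the
#'   latter requires `ref_seqs`).
#' @param out_dir output directory; NULL skips file output.
#' @param config a [scan_config()].
#' @param baseline optional pre-computed `scan_baseline`.
#' @param ref_seqs named reference sequences (for SAM/BAM input).
#' @param seed baseline sampling seed.
#' @return invisible [scan_pileup()] result.
#' @export
run_scan <- function(pileup, out_dir = NULL, config = scan_config(),
                     baseline = NULL, ref_seqs = NULL, seed = 1L) {
  pileup <- load_pileup(pileup, ref_seqs)
  res <- scan_pileup(pileup, config, baseline = baseline, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_regions_bed(res$regions, file.path(out_dir, "biased_regions.bed"))
    bg <- sprintf("%s\t%d\t%d\t%.4f", pileup$chrom[1],
                  res$windows$start - 1L, res$windows$end,
                  res$windows$bias_score)
    writeLines(bg, file.path(out_dir, "window_scores.bedGraph"))
  }
  invisible(res)
}

load_pileup <- function(pileup, ref_seqs = NULL) {
  if (is.character(pileup) && length(pileup) == 1L) {
    if (grepl("\\.(sam|bam)$", pileup, ignore.case = TRUE)) {
      stopifnot(!is.null(ref_seqs))
      reads <- read_alignments(pileup)
      chrom <- reads$chrom[1]
      return(pileup_from_alignments(reads[reads$chrom == chrom, ],
                                    ref_seqs[[chrom]], chrom))
    }
    return(read_mpileup(pileup))
  }
  pileup
}

#' Compare mode: scan two workflows against one joint baseline
#'
#' @param pileup_a,pileup_b pileups of the two alignment workflows (same
#'   reference extent).
#' @param out_dir output directory; NULL skips file output.
#' @param config a [scan_config()].
#' @param seed baseline sampling seed.
#' @return invisible list with both scans, the joint `baseline` and the
#'   per-region `verdicts` (A's biased regions judged against B).
#' @export
run_compare <- function(pileup_a, pileup_b, out_dir = NULL,
                        config = scan_config(), seed = 1L) {
  pa <- load_pileup(pileup_a); pb <- load_pileup(pileup_b)
  prof_a <- profile_pileup(pa, config); prof_b <- profile_pileup(pb, config)
  baseline <- estimate_baseline(list(prof_a, prof_b), config, seed = seed)
  scan_a <- scan_pileup(pa, config, baseline = baseline)
  scan_b <- scan_pileup(pb, config, baseline = baseline)
  verdicts <- compare_workflows(scan_a$regions, scan_b$regions,
                                depth_b = pb$depth,
                                mean_depth_b = mean(pb$depth), config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_regions_bed(scan_a$regions, file.path(out_dir, "regions_a.bed"))
    write_regions_bed(scan_b$regions, file.path(out_dir, "regions_b.bed"))
    write.table(verdicts, file.path(out_dir, "compare_verdicts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(scan_a = scan_a, scan_b = scan_b, baseline = baseline,
                 verdicts = verdicts))
}
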