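# Predicting biased sites on real data from two features: context-aware
# allelic balance and the mean mapping quality of overlapping reads.

#' Prediction configuration
#'
#' @param mapq_max maximum possible MAPQ of the aligner (42 for Bowtie 2 /
#'   BWA-MEM scoring; 60 for VG Giraffe).
#' @param add_weight weight of the MAPQ term in the additive score.
#' @param other_frac_affected a site is "affected" (excluded as a likely
#'   phasing artifact) when more than this fraction of covering reads carry
#'   an `other` allele.
#' @param other_frac_absent the lower "affected" threshold applying when the
#'   evidence for one HET allele is completely absent.
#' @return a `predict_config` list.
#' @export
predict_config <- function(mapq_max = 42L, add_weight = 1.5,
                           other_frac_affected = 0.9,
                           other_frac_absent = 0.4) {
  stopifnot(mapq_max > 0, other_frac_affected > 0, other_frac_affected < 1,
            other_frac_absent > 0, other_frac_absent < 1)
  structure(list(mapq_max = as.integer(mapq_max), add_weight = add_weight,
                 other_frac_affected = other_frac_affected,
                 other_frac_absent = other_frac_absent),
            class = "predict_config")
}

#' Flag sites affected by incomplete phasing information
#'
#' A site is "affected" — and excluded from prediction evaluation — when
#' more than 90% of the reads covering it carry an `other` (neither REF nor
#' ALT) allele, or when evidence for one of the two HET alleles is absent
#' and more than 40% of reads carry an `other` allele. Zero-coverage sites
#' are affected.
#'
#' @param evidence output of [tally_sites()].
#' @param config a [predict_config()].
#' @return logical vector; TRUE = affected (exclude).
#' @export
filter_affected <- function(evidence, config = predict_config()) {
  cov <- evidence$n_ref + evidence$n_alt + evidence$n_both + evidence$n_other
  other_frac <- ifelse(cov > 0, evidence$n_other / cov, 1)
  absent <- evidence$n_ref == 0L | evidence$n_alt == 0L
  cov == 0L |
    other_frac > config$other_frac_affected |
    (absent & other_frac > config$other_frac_absent)
}

#' Two-feature bias prediction score
#'
#' Combines mean MAPQ (normalized by the aligner's maximum) with assignment
#' balance:
#' \deqn{mul: \frac{\bar q - q_{max}}{q_{max}} \times AB \qquad
#'       add: \frac{\bar q - q_{max}}{q_{max}} \times w + AB}
#' with `w = 1.5` by default. Lower scores rank as more likely biased:
#' biased sites pair extreme (REF-skewed) AB with depressed mean MAPQ, and
#' the MAPQ term is the signed, negative one. `flip = TRUE` negates the
#' orientation for ALT-skew investigations.
#'
#' @param mean_mapq mean mapping quality of reads overlapping the site.
#' @param ab assignment balance; NA yields NA (no score).
#' @param mode `"mul"` or `"add"`.
#' @param config a [predict_config()].
#' @param flip reverse the ranking orientation.
#' @return numeric score vector.
#' @export
prediction_score <- function(mean_mapq, ab, mode = c("mul", "add"),
                             config = predict_config(), flip = FALSE) {
  mode <- match.arg(mode)
  qn <- (mean_mapq - config$mapq_max) / config$mapq_max
  s <- if (mode == "mul") qn * ab else qn * config$add_weight + ab
  if (flip) s <- -s
  s
}

#' Score sites for likely reference bias
#'
#' @param sites site table aligned row-wise with `evidence`.
#' @param evidence output of [tally_sites()].
#' @param config a [predict_config()].
#' @return data.frame with site coordinates, `affected` flag, `AB`,
#'   `mean_mapq`, `score_mul`, `score_add`.
#' @export
predict_sites <- function(sites, evidence, config = predict_config()) {
  ab <- assignment_balance(evidence)
  data.frame(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
    affected = filter_affected(evidence, config),
    AB = ab, mean_mapq = evidence$mean_mapq,
    score_mul = prediction_score(evidence$mean_mapq, ab, "mul", config),
    score_add = prediction_score(evidence$mean_mapq, ab, "add", config),
    stringsAsFactors = FALSE)
}

#' Evaluate a bias ranking against labels (ROC and PR curves)
#'
#' Sweeps a threshold over the scores (lower score = predicted biased; tied
#' scores cross the threshold simultaneously) and reports ROC points with
#' trapezoidal AUC and precision/recall points with trapezoidal AUPRC.
#'
#' @param scores numeric scores; lower = more likely biased.
#' @param labels `"biased"` / `"balanced"` (or logical, TRUE = biased).
#' @return list with `roc` (data.frame `fpr`, `tpr`), `auc`, `pr`
#'   (data.frame `recall`, `precision`), `auprc`, `n_pos`, `n_neg`.
#' @export
evaluate_ranking <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels) == "biased"
  }
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("evaluate_ranking needs at least one site of each label")
  }
  ord <- order(scores)
  s <- scores[ord]; y <- labels[ord]
  # group tied scores: one operating point per distinct threshold
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  tpr <- c(0, tp / n_pos); fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  rec <- c(0, recall); prec <- c(precision[1], precision)
  auprc <- sum(diff(rec) * (utils::head(prec, -1) + utils::tail(prec, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc,
       pr = data.frame(recall = rec, precision = prec), auprc = auprc,
       n_pos = n_pos, n_neg = n_neg)
}

#' Transfer per-site labels onto another site table
#'
#' Joins labels (e.g. simulate-mode categories, collapsed to binary) onto
#' predictions for the same HET sites by chromosome and position — the way
#' simulation-derived ground truth is transferred to real-read rankings.
#'
#' @param predictions data.frame with `chrom`, `pos`.
#' @param labelled data.frame with `chrom`, `pos` and a `label` column.
#' @return `predictions` with a `label` column (NA where unmatched).
#' @export
transfer_labels <- function(predictions, labelled) {
  key_p <- paste(predictions$chrom, predictions$pos)
  key_l <- paste(labelled$chrom, labelled$pos)
  predictions$label <- labelled$label[match(key_p, key_l)]
  predictions
}
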