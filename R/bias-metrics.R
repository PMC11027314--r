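# SB/MB/AB allelic balance, the NMB/NAB plane, per-site bias categorization
# (balanced / loss / flux / local / outlier) and bias-by-allele-length
# summaries.

#' Classifier configuration for the NMB-NAB plane
#'
#' @param balanced_radius radius of the balanced circle at the origin.
#' @param wedge_slope upper slope of the loss wedge (lower slope is its
#'   reciprocal).
#' @param mismap_threshold sites with *more than* this many mismapped reads
#'   in the flux/local region are called flux.
#' @param blue_axis which normalized balance the flux/local region is keyed
#'   on; `"NAB"` (the reading consistent with the Results text and the
#'   vertical flux/local clusters) or `"NMB"` (the figure-caption reading).
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(balanced_radius = 0.1, wedge_slope = 2,
                              mismap_threshold = 5L,
                              blue_axis = c("NAB", "NMB")) {
  stopifnot(balanced_radius > 0, balanced_radius < 1, wedge_slope > 1)
  structure(list(balanced_radius = balanced_radius,
                 wedge_slope = wedge_slope,
                 mismap_threshold = as.integer(mismap_threshold),
                 blue_axis = match.arg(blue_axis)),
            class = "classifier_config")
}

#' Simulation balance (SB) per site
#'
#' REF/(REF+ALT) over reads that truly originated overlapping each site,
#' counted from truth tags; the simulator's view, before any alignment.
#'
#' @param sites prepared site table.
#' @param truth_reads data.frame with truth columns `hap`, `true_chrom`,
#'   `true_start`, `true_end` (e.g. the oracle-aligned read set *before* any
#'   bias injection).
#' @return numeric vector of SB values (NA where no reads overlap).
#' @export
simulation_balance <- function(sites, truth_reads) {
  per_site_hap_fraction(sites, truth_reads, use_alignment = FALSE,
                        require_truth_overlap = TRUE)
}

#' Mapping balance (MB) per site
#'
#' The REF fraction over reads that both truly originated overlapping the
#' site and aligned overlapping it; mismapped (foreign) reads are excluded.
#'
#' @param sites prepared site table.
#' @param aligned truth-tagged alignment data.frame (post alignment, post
#'   any injection).
#' @return numeric vector of MB values (NA where the denominator is zero).
#' @export
mapping_balance <- function(sites, aligned) {
  per_site_hap_fraction(sites, aligned, use_alignment = TRUE,
                        require_truth_overlap = TRUE)
}

per_site_hap_fraction <- function(sites, reads, use_alignment,
                                  require_truth_overlap) {
  n <- nrow(sites)
  out <- rep(NA_real_, n)
  for (chr in unique(sites$chrom)) {
    sidx <- which(sites$chrom == chr)
    ridx <- which((if (require_truth_overlap) reads$true_chrom else reads$chrom) == chr)
    if (!length(ridx)) next
    ir_sites <- IRanges::IRanges(sites$pos[sidx], sites$end[sidx])
    ok <- rep(TRUE, length(ridx))
    if (require_truth_overlap) {
      ir_truth <- IRanges::IRanges(reads$true_start[ridx], reads$true_end[ridx])
      ov_t <- IRanges::findOverlaps(ir_sites, ir_truth)
    }
    if (use_alignment) {
      ir_aln <- IRanges::IRanges(reads$pos[ridx], reads$ref_end[ridx])
      ov_a <- IRanges::findOverlaps(ir_sites, ir_aln)
      same_chrom <- reads$chrom[ridx[S4Vectors::subjectHits(ov_a)]] == chr
      ov_a <- ov_a[same_chrom]
      key_a <- paste(S4Vectors::queryHits(ov_a), S4Vectors::subjectHits(ov_a))
      key_t <- paste(S4Vectors::queryHits(ov_t), S4Vectors::subjectHits(ov_t))
      keep <- key_t %in% key_a
      q <- S4Vectors::queryHits(ov_t)[keep]; s <- S4Vectors::subjectHits(ov_t)[keep]
    } else {
      q <- S4Vectors::queryHits(ov_t); s <- S4Vectors::subjectHits(ov_t)
    }
    if (!length(q)) next
    hap <- reads$hap[ridx[s]]
    ref_hap <- sites$ref_hap[sidx[q]]
    tot <- tapply(rep(1L, length(q)), q, sum)
    refn <- tapply(as.integer(hap == ref_hap), q, sum)
    out[sidx[as.integer(names(tot))]] <- as.numeric(refn) / as.numeric(tot)
  }
  out
}

#' Assignment balance (AB) from tallied evidence
#'
#' AB = n_ref / (n_ref + n_alt); `BOTH` and `OTHER` reads are excluded.
#' NA (undefined) when no read was assigned to either allele.
#'
#' @param evidence output of [tally_sites()].
#' @return numeric vector of AB values.
#' @export
assignment_balance <- function(evidence) {
  den <- evidence$n_ref + evidence$n_alt
  ifelse(den > 0, evidence$n_ref / den, NA_real_)
}

#' Categorize sites on the NMB-NAB plane
#'
#' Geometry of the bias categories: sites within `balanced_radius` of the
#' origin are `balanced`; sites in the diagonal wedge (NMB and NAB sharing
#' sign, `|NMB|/s <= |NAB| <= s|NMB|` with slope `s = 2`), outside the
#' circle, are `loss` (both the upper-right and the rare lower-left
#' quadrant); remaining sites with `|NAB|` beyond the radius are `flux` when
#' more than `mismap_threshold` reads were mismapped to the site, else
#' `local`; everything else is an `outlier`. Sites with any required measure
#' undefined are `unclassifiable`. Boundary ties resolve toward the earlier
#' rule (circle, then wedge), so the classification is deterministic and the
#' categories partition the plane.
#'
#' @param nmb,nab normalized mapping / assignment balance (MB - SB, AB - SB).
#' @param n_mismapped mismapped-read counts.
#' @param config a [classifier_config()].
#' @return character vector of categories.
#' @export
categorize_site <- function(nmb, nab, n_mismapped,
                            config = classifier_config()) {
  n <- length(nmb)
  stopifnot(length(nab) == n, length(n_mismapped) %in% c(1L, n))
  if (length(n_mismapped) == 1L) n_mismapped <- rep(n_mismapped, n)
  out <- rep("unclassifiable", n)
  ok <- !is.na(nmb) & !is.na(nab)
  r <- sqrt(nmb^2 + nab^2)
  s <- config$wedge_slope
  balanced <- ok & r <= config$balanced_radius
  wedge <- ok & !balanced & (sign(nmb) == sign(nab)) & nmb != 0 &
    abs(nab) >= abs(nmb) / s & abs(nab) <= abs(nmb) * s
  blue_val <- if (config$blue_axis == "NAB") abs(nab) else abs(nmb)
  blue <- ok & !balanced & !wedge & blue_val > config$balanced_radius
  out[balanced] <- "balanced"
  out[wedge] <- "loss"
  out[blue & n_mismapped > config$mismap_threshold] <- "flux"
  out[blue & n_mismapped <= config$mismap_threshold] <- "local"
  out[ok & !balanced & !wedge & !blue] <- "outlier"
  out
}

#' Collapse categories to balanced vs biased
#'
#' @param category character vector of categories.
#' @return `"balanced"`, `"biased"`, or NA for unclassifiable sites (these
#'   are excluded from binary evaluations).
#' @export
collapse_to_binary <- function(category) {
  ifelse(category == "balanced", "balanced",
         ifelse(category %in% c("loss", "flux", "local", "outlier"),
                "biased", NA_character_))
}

#' Full per-site balance/bias table
#'
#' Convenience wrapper computing SB, MB, AB (context-aware by default),
#' NMB/NAB, mismap counts and the bias category for every prepared site.
#'
#' @param sites prepared site table.
#' @param truth_reads pre-injection truth-tagged reads (SB source).
#' @param aligned post-alignment (possibly bias-injected) reads.
#' @param config an [assignment_config()].
#' @param method assignment method for AB.
#' @param cohorts cohort table for cohort-first matching.
#' @param classifier a [classifier_config()].
#' @return `sites` with appended columns `SB`, `MB`, `AB`, `NMB`, `NAB`,
#'   evidence counts, `mean_mapq`, `category`.
#' @export
balance_table <- function(sites, truth_reads, aligned,
                          config = assignment_config(),
                          method = c("context", "naive"), cohorts = NULL,
                          classifier = classifier_config()) {
  method <- match.arg(method)
  ev <- tally_sites(sites, aligned, config, method = method, cohorts = cohorts)
  sites$SB <- simulation_balance(sites, truth_reads)
  sites$MB <- mapping_balance(sites, aligned)
  sites$AB <- assignment_balance(ev)
  sites$n_ref <- ev$n_ref; sites$n_alt <- ev$n_alt
  sites$n_both <- ev$n_both; sites$n_other <- ev$n_other
  sites$n_overlap <- ev$n_overlap
  sites$n_mismapped <- ev$n_mismapped
  sites$mean_mapq <- ev$mean_mapq
  sites$NMB <- sites$MB - sites$SB
  sites$NAB <- sites$AB - sites$SB
  sites$category <- categorize_site(sites$NMB, sites$NAB, sites$n_mismapped,
                                    classifier)
  sites$category[sites$disregarded] <- "unclassifiable"
  sites
}

#' Bias-by-allele-length summary
#'
#' ALT-allele fractions (`ALT/(ALT+REF)`, the orientation used in
#' bias-by-allele-length plots) stratified by variant length: negative for
#' deletions, positive for insertions, 0 for SNVs; lengths beyond 25 bp are
#' collapsed into the -25 / +25 strata. Reports median and quartiles per
#' measure and stratum; empty strata are omitted.
#'
#' @param records output of [balance_table()].
#' @param measures which balance columns to summarize.
#' @param normalize subtract the per-stratum median SB-based ALT fraction
#'   from the other measures.
#' @return data.frame with `stratum`, `measure`, `median`, `q1`, `q3`, `n`.
#' @export
bias_by_length <- function(records, measures = c("SB", "MB", "AB"),
                           normalize = FALSE) {
  stratum <- pmax(pmin(records$length_delta, 25L), -25L)
  out <- list()
  for (m in measures) {
    alt_frac <- 1 - records[[m]]
    ok <- !is.na(alt_frac)
    if (!any(ok)) next
    sp <- split(alt_frac[ok], stratum[ok])
    base <- NULL
    if (normalize && "SB" %in% names(records)) {
      sb_alt <- 1 - records$SB
      base <- vapply(split(sb_alt[ok & !is.na(sb_alt)],
                           stratum[ok & !is.na(sb_alt)]),
                     median, numeric(1))
    }
    out[[m]] <- data.frame(
      stratum = as.integer(names(sp)),
      measure = m,
      median = vapply(sp, median, numeric(1)) -
        if (is.null(base)) 0 else base[names(sp)],
      q1 = vapply(sp, function(x) unname(quantile(x, 0.25)), numeric(1)) -
        if (is.null(base)) 0 else base[names(sp)],
      q3 = vapply(sp, function(x) unname(quantile(x, 0.75)), numeric(1)) -
        if (is.null(base)) 0 else base[names(sp)],
      n = vapply(sp, length, integer(1)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
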