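# Read-to-haplotype assignment at HET sites: the naive pileup-trusting
# algorithm and the context-aware exact-matching algorithm with left/right
# anchoring, cohort-first matching and partial (prefix/suffix) matches.

#' Naive assignment of one read at one site
#'
#' Trusts the aligner: extracts the read bases placed at the variant's exact
#' reference coordinates via a CIGAR walk and tallies the read only if that
#' sequence exactly matches the REF or the ALT allele; anything else —
#' sequencing errors, or a gap placed differently from the VCF — is `OTHER`.
#' The naive method never returns `BOTH`.
#'
#' @param site one row of a prepared site table.
#' @param read one row of an alignment data.frame.
#' @return `"REF"`, `"ALT"` or `"OTHER"`.
#' @export
assign_read_naive <- function(site, read) {
  obs <- extract_footprint_seq(read$pos, read$cigar, read$seq,
                               site$pos, site$end)
  if (is.na(obs)) return("OTHER")
  if (obs == site$ref) return("REF")
  if (obs == site$alt) return("ALT")
  "OTHER"
}

# Anchored partial match of a read against one context string.
# ctx_ref_start/ctx_ref_end are the reference coordinates of the context
# boundaries (shared between REF and ALT contexts because the outer flanks
# are outside the effective variant). A partial (prefix/suffix) match counts
# only when the overlap reaches at least one base beyond the anchored-side
# flank into the effective allele — the discrimination against the other
# allele comes from it being tested against both contexts: a window matching
# both (tandem repeats) yields BOTH, not a call.
anchored_match <- function(seq, pos, cigar, ref_end, ctx, ctx_ref_start,
                           ctx_ref_end, flank_l, flank_r) {
  L <- nchar(ctx)
  # left anchor: a flank position present in both read and context
  a <- max(pos, ctx_ref_start)
  if (a < ctx_ref_start + flank_l) {       # anchor inside the left flank
    q <- qpos_at_ref(pos, cigar, a)
    if (!is.na(q)) {
      k <- a - ctx_ref_start + 1L          # context offset of the anchor
      cl <- min(nchar(seq) - q + 1L, L - k + 1L)
      if (k + cl - 1L > flank_l &&         # reaches into the allele
          substr(seq, q, q + cl - 1L) == substr(ctx, k, k + cl - 1L)) {
        return(TRUE)
      }
    }
  }
  # right anchor
  b <- min(ref_end, ctx_ref_end)
  if (b > ctx_ref_end - flank_r) {         # anchor inside the right flank
    q <- qpos_at_ref(pos, cigar, b)
    if (!is.na(q)) {
      m <- ctx_ref_end - b                 # context chars truncated on the right
      cl <- min(q, L - m)
      j1 <- (L - m) - cl + 1L
      if (j1 <= L - flank_r &&             # reaches into the allele
          substr(seq, q - cl + 1L, q) == substr(ctx, j1, L - m)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# clip-aware aligned span: soft-clipped prefixes/suffixes may still cover
# the effective variant (e.g. reads starting inside an insertion)
clip_extended_span <- function(pos, cigar, ref_end) {
  lead <- ifelse(grepl("^[0-9]+S", cigar),
                 as.integer(sub("^([0-9]+)S.*$", "\\1", cigar)), 0L)
  trail <- ifelse(grepl("[0-9]+S$", cigar),
                  as.integer(sub("^.*?([0-9]+)S$", "\\1", cigar)), 0L)
  list(start = pos - lead, end = ref_end + trail)
}

#' Context-aware assignment of one read at one site
#'
#' The read sequence is scanned for the REF and ALT allelic context sequences
#' (exact matching, no mismatches tolerated). If the full context of exactly
#' one allele appears, the read is assigned to it; failing that, the expected
#' window is anchored at the left context boundary and, if that fails, at the
#' right boundary, accepting prefix/suffix partial matches that still cover
#' the whole effective allele. Reads that do not cover the entire effective
#' variant, or that match both contexts, are `BOTH`; reads matching neither
#' are `OTHER`.
#'
#' @inheritParams assign_read_naive
#' @param config an [assignment_config()].
#' @return `"REF"`, `"ALT"`, `"BOTH"` or `"OTHER"`.
#' @export
assign_read_context <- function(site, read, config = assignment_config()) {
  span <- clip_extended_span(read$pos, read$cigar, read$ref_end)
  if (span$start > site$eff_start || span$end < site$eff_end) {
    return("BOTH")                         # effective variant not fully covered
  }
  rm_ <- grepl(site$ref_context, read$seq, fixed = TRUE)
  am_ <- grepl(site$alt_context, read$seq, fixed = TRUE)
  if (!rm_ && !am_) {
    rm_ <- anchored_match(read$seq, read$pos, read$cigar, read$ref_end,
                          site$ref_context, site$ctx_ref_start,
                          site$ctx_ref_end, site$flank_l, site$flank_r)
    am_ <- anchored_match(read$seq, read$pos, read$cigar, read$ref_end,
                          site$alt_context, site$ctx_ref_start,
                          site$ctx_ref_end, site$flank_l, site$flank_r)
  }
  if (rm_ && am_) return("BOTH")
  if (rm_) return("REF")
  if (am_) return("ALT")
  "OTHER"
}

# vectorized-over-reads context assignment for one site
assign_context_site <- function(site, reads, config) {
  n <- nrow(reads)
  calls <- character(n)
  span <- clip_extended_span(reads$pos, reads$cigar, reads$ref_end)
  covers <- span$start <= site$eff_start & span$end >= site$eff_end
  calls[!covers] <- "BOTH"
  idx <- which(covers)
  if (length(idx)) {
    rm_ <- grepl(site$ref_context, reads$seq[idx], fixed = TRUE)
    am_ <- grepl(site$alt_context, reads$seq[idx], fixed = TRUE)
    need <- which(!rm_ & !am_)
    for (j in need) {
      i <- idx[j]
      rm_[j] <- anchored_match(reads$seq[i], reads$pos[i], reads$cigar[i],
                               reads$ref_end[i], site$ref_context,
                               site$ctx_ref_start, site$ctx_ref_end,
                               site$flank_l, site$flank_r)
      am_[j] <- anchored_match(reads$seq[i], reads$pos[i], reads$cigar[i],
                               reads$ref_end[i], site$alt_context,
                               site$ctx_ref_start, site$ctx_ref_end,
                               site$flank_l, site$flank_r)
    }
    calls[idx] <- ifelse(rm_ & am_, "BOTH",
                         ifelse(rm_, "REF", ifelse(am_, "ALT", "OTHER")))
  }
  calls
}

#' Tally per-site evidence from overlapping reads
#'
#' For each non-disregarded site, all alignments overlapping its effective
#' interval are assigned (naive or context-aware) and tallied. With the
#' context method, cohort-level matching runs first: the combined haplotype
#' strings of each multi-variant cohort are searched in the overlapping
#' reads, and a read matched at cohort level is tallied for every member
#' site; unmatched reads fall back to variant-by-variant assignment.
#' `n_mismapped` counts overlapping reads whose truth interval lies elsewhere
#' (available only for truth-tagged alignments); `mean_mapq` averages over
#' all overlapping reads regardless of call.
#'
#' @param sites prepared site table (see [prepare_het_sites()]).
#' @param reads alignment data.frame.
#' @param config an [assignment_config()].
#' @param method `"context"` or `"naive"`.
#' @param cohorts cohort table (context method; NULL disables cohort-first).
#' @return data.frame with one row per site: `n_ref`, `n_alt`, `n_both`,
#'   `n_other`, `n_overlap`, `n_mismapped`, `mean_mapq`.
#' @export
tally_sites <- function(sites, reads, config = assignment_config(),
                        method = c("context", "naive"), cohorts = NULL) {
  method <- match.arg(method)
  n <- nrow(sites)
  ev <- data.frame(n_ref = integer(n), n_alt = integer(n), n_both = integer(n),
                   n_other = integer(n), n_overlap = integer(n),
                   n_mismapped = integer(n), mean_mapq = rep(NA_real_, n))
  truth_avail <- any(!is.na(reads$true_start))

  # cohort-level assignment: read index -> matched haplotype (1/2), per cohort
  cohort_calls <- list()
  if (method == "context" && !is.null(cohorts) && NROW(cohorts)) {
    for (k in seq_len(nrow(cohorts))) {
      ci <- cohorts[k, ]
      ridx <- which(reads$chrom == ci$chrom & reads$pos <= ci$end &
                      reads$ref_end >= ci$start)
      if (!length(ridx)) next
      h1 <- grepl(ci$hap1_string, reads$seq[ridx], fixed = TRUE)
      h2 <- grepl(ci$hap2_string, reads$seq[ridx], fixed = TRUE)
      hap <- ifelse(h1 & !h2, 1L, ifelse(h2 & !h1, 2L, NA_integer_))
      cohort_calls[[as.character(ci$cohort_id)]] <-
        list(ridx = ridx, hap = hap)
    }
  }

  for (chr in unique(sites$chrom)) {
    sidx <- which(sites$chrom == chr)
    ridx_all <- which(reads$chrom == chr)
    if (!length(ridx_all)) next
    ir_reads <- IRanges::IRanges(reads$pos[ridx_all], reads$ref_end[ridx_all])
    ir_sites <- IRanges::IRanges(sites$eff_start[sidx], sites$eff_end[sidx])
    ov <- IRanges::findOverlaps(ir_sites, ir_reads)
    by_site <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
    for (key in names(by_site)) {
      i <- sidx[as.integer(key)]
      ridx <- ridx_all[by_site[[key]]]
      ev$n_overlap[i] <- length(ridx)
      ev$mean_mapq[i] <- mean(reads$mapq[ridx])
      if (truth_avail) {
        mis <- is.na(reads$true_start[ridx]) |
          reads$true_chrom[ridx] != sites$chrom[i] |
          reads$true_start[ridx] > sites$end[i] |
          reads$true_end[ridx] < sites$pos[i]
        ev$n_mismapped[i] <- sum(mis)
      }
      if (isTRUE(sites$disregarded[i])) next
      site <- sites[i, ]
      if (method == "naive") {
        calls <- vapply(ridx, function(r) assign_read_naive(site, reads[r, ]),
                        character(1))
      } else {
        cc <- NULL
        if (!is.na(site$cohort_id)) {
          cc <- cohort_calls[[as.character(site$cohort_id)]]
        }
        if (!is.null(cc)) {
          decided <- cc$ridx[!is.na(cc$hap)]
          dec_hap <- cc$hap[!is.na(cc$hap)]
          site_allele <- if (site$ref_hap == 1L) c("REF", "ALT") else c("ALT", "REF")
          dec_calls <- site_allele[dec_hap]
          undecided <- setdiff(ridx, decided)
          und_calls <- if (length(undecided)) {
            assign_context_site(site, reads[undecided, , drop = FALSE], config)
          } else character(0)
          calls <- c(dec_calls, und_calls)
        } else {
          calls <- assign_context_site(site, reads[ridx, , drop = FALSE], config)
        }
      }
      ev$n_ref[i] <- sum(calls == "REF")
      ev$n_alt[i] <- sum(calls == "ALT")
      ev$n_both[i] <- sum(calls == "BOTH")
      ev$n_other[i] <- sum(calls == "OTHER")
    }
  }
  ev
}
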