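# HET-site preparation for read-to-haplotype assignment: overlap filtering,
# phased allelic context sequences, tandem-repeat "effective variant"
# extension, and cohort clustering of nearby variants.

#' Assignment configuration
#'
#' @param flank_len flanking sequence length for allelic contexts (bp).
#' @param cohort_distance maximum end-to-start gap chaining variants into a
#'   cohort (bp).
#' @param effective_len_limit effective variants spanning more than this many
#'   bp are disregarded.
#' @param mapq_max maximum MAPQ the aligner can report (42 for BWA-MEM /
#'   Bowtie 2 scoring, 60 for Giraffe).
#' @return an `assignment_config` list.
#' @export
assignment_config <- function(flank_len = 5L, cohort_distance = 25L,
                              effective_len_limit = 70L, mapq_max = 42L) {
  stopifnot(flank_len > 0, cohort_distance > 0, effective_len_limit > 0,
            mapq_max > 0)
  structure(list(flank_len = as.integer(flank_len),
                 cohort_distance = as.integer(cohort_distance),
                 effective_len_limit = as.integer(effective_len_limit),
                 mapq_max = as.integer(mapq_max)),
            class = "assignment_config")
}

#' Keep only heterozygous, usable variants
#'
#' Hom-alt and hom-ref genotypes are dropped; unphased or missing genotypes
#' were already flagged unusable by [read_phased_vcf()] and are dropped here
#' (their footprints should have been routed through [remove_overlapping()]
#' beforehand).
#'
#' @param variants variant data.frame.
#' @return the HET subset.
#' @export
select_het_sites <- function(variants) {
  out <- variants[variants$usable & variants$is_het, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove groups of overlapping variants
#'
#' Interdependent variants (e.g. a deletion extending through an SNV) cannot
#' vary independently; any group of variants whose reference footprints
#' intersect is removed in its entirety. The reference footprint is
#' `[pos, pos + nchar(ref) - 1]`; insertions occupy their single anchor base.
#'
#' @param variants variant data.frame sorted by position (single chromosome
#'   groups are handled independently).
#' @return list with `kept` and `removed` data.frames.
#' @export
remove_overlapping <- function(variants) {
  if (!nrow(variants)) return(list(kept = variants, removed = variants))
  ord <- order(variants$chrom, variants$pos)
  v <- variants[ord, , drop = FALSE]
  drop <- logical(nrow(v))
  run_max_end <- -Inf
  prev_chrom <- ""
  for (i in seq_len(nrow(v))) {
    if (v$chrom[i] != prev_chrom) {
      run_max_end <- -Inf
      prev_chrom <- v$chrom[i]
    }
    if (v$pos[i] <= run_max_end) drop[i] <- TRUE
    run_max_end <- max(run_max_end, v$end[i])
  }
  # overlap is symmetric, so expanding from the detected later members marks
  # every partner; iterate to a fixed point for clashes involving > 2 variants
  repeat {
    changed <- FALSE
    for (i in which(drop)) {
      hit <- v$chrom == v$chrom[i] & v$pos <= v$end[i] & v$end >= v$pos[i] & !drop
      if (any(hit)) { drop[hit] <- TRUE; changed <- TRUE }
    }
    if (!changed) break
  }
  kept <- v[!drop, , drop = FALSE]; removed <- v[drop, , drop = FALSE]
  rownames(kept) <- NULL; rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}

#' Build the two phased haplotypes for context construction
#'
#' @param ref_seq reference sequence (one chromosome).
#' @param variants non-overlapping usable variants on that chromosome.
#' @return list of two `list(seq, map)` elements (see [build_consensus()]).
#' @export
phased_haplotypes <- function(ref_seq, variants) {
  list(build_consensus(ref_seq, variants, 1L),
       build_consensus(ref_seq, variants, 2L))
}

# relation of the two context strings: "none" when neither is a prefix,
# suffix or substring of the other; "right" / "left" / "both" name the
# extension direction(s) that can break the relation.
context_relation <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    return(if (a == b) "both" else "none")
  }
  s <- if (nchar(a) < nchar(b)) a else b
  l <- if (nchar(a) < nchar(b)) b else a
  pre <- startsWith(l, s)
  suf <- endsWith(l, s)
  if (pre && suf) return("both")
  if (pre) return("right")
  if (suf) return("left")
  if (grepl(s, l, fixed = TRUE)) return("both")
  "none"
}

#' Build allelic context sequences for HET sites
#'
#' The context of each allele is the allele plus `flank_len` bases of
#' flanking sequence drawn from the haplotype carrying that allele, so phased
#' neighbouring variants appear — phased appropriately — in each other's
#' flanks. Sites too close to a contig end get truncated flanks and are
#' flagged `clipped`.
#'
#' @param sites HET variant data.frame (see [select_het_sites()]).
#' @param haps output of [phased_haplotypes()].
#' @param config an [assignment_config()].
#' @return `sites` with added columns `ref_hap`, `alt_hap`, `ref_context`,
#'   `alt_context`, `ctx_ref_start`, `ctx_ref_end`, `flank_l`, `flank_r`,
#'   `clipped`.
#' @export
build_context <- function(sites, haps, config = assignment_config()) {
  fl <- config$flank_len
  n <- nrow(sites)
  sites$ref_hap <- ifelse(sites$gt1 == 0L, 1L, 2L)
  sites$alt_hap <- 3L - sites$ref_hap
  sites$ref_context <- character(n); sites$alt_context <- character(n)
  sites$flank_l <- integer(n); sites$flank_r <- integer(n)
  sites$clipped <- logical(n)
  sites$ctx_ref_start <- integer(n); sites$ctx_ref_end <- integer(n)
  for (i in seq_len(n)) {
    rh <- sites$ref_hap[i]; ah <- sites$alt_hap[i]
    hp_r <- map_ref_to_hap(haps[[rh]]$map, sites$pos[i])
    hp_a <- map_ref_to_hap(haps[[ah]]$map, sites$pos[i])
    if (is.na(hp_r) || is.na(hp_a)) {
      sites$clipped[i] <- TRUE
      next
    }
    len_r <- nchar(sites$ref[i]); len_a <- nchar(sites$alt[i])
    fla <- min(fl, hp_r - 1L, hp_a - 1L)
    flb <- min(fl,
               nchar(haps[[rh]]$seq) - (hp_r + len_r - 1L),
               nchar(haps[[ah]]$seq) - (hp_a + len_a - 1L))
    sites$clipped[i] <- fla < fl || flb < fl
    sites$flank_l[i] <- fla; sites$flank_r[i] <- flb
    sites$ref_context[i] <- substr(haps[[rh]]$seq, hp_r - fla, hp_r + len_r - 1L + flb)
    sites$alt_context[i] <- substr(haps[[ah]]$seq, hp_a - fla, hp_a + len_a - 1L + flb)
    sites$ctx_ref_start[i] <- sites$pos[i] - fla
    sites$ctx_ref_end[i] <- sites$end[i] + flb
  }
  sites
}

#' Extend effective variants across tandem repeats
#'
#' While one context sequence is a prefix of the other, the variant is
#' extended to the right until the first difference between the two
#' haplotypes is encountered; while a suffix, to the left; when one is a
#' substring of the other (repetitiveness on both sides) the side with the
#' shorter extension is chosen. Sites whose effective span exceeds
#' `effective_len_limit` are disregarded.
#'
#' @param sites output of [build_context()].
#' @param haps output of [phased_haplotypes()].
#' @param config an [assignment_config()].
#' @return `sites` with added columns `eff_start`, `eff_end` (effective
#'   reference footprint), `eff_len` (longer effective allele length),
#'   `extended_side`, `disregarded`, and updated contexts.
#' @export
extend_effective <- function(sites, haps, config = assignment_config()) {
  fl <- config$flank_len
  lim <- config$effective_len_limit
  n <- nrow(sites)
  sites$eff_start <- sites$pos; sites$eff_end <- sites$end
  sites$extended_side <- rep("none", n)
  sites$disregarded <- logical(n)
  sites$eff_len <- pmax(nchar(sites$ref), nchar(sites$alt))
  max_ext <- lim + 2L * fl + 8L
  for (i in seq_len(n)) {
    if (sites$clipped[i] && !nzchar(sites$ref_context[i])) {
      sites$disregarded[i] <- TRUE
      next
    }
    rc <- sites$ref_context[i]; ac <- sites$alt_context[i]
    rel <- context_relation(rc, ac)
    if (rel == "none") next
    rh <- sites$ref_hap[i]; ah <- sites$alt_hap[i]
    hseq_r <- haps[[rh]]$seq; hseq_a <- haps[[ah]]$seq
    hp_r <- map_ref_to_hap(haps[[rh]]$map, sites$pos[i])
    hp_a <- map_ref_to_hap(haps[[ah]]$map, sites$pos[i])
    # current haplotype coordinates of the context boundaries
    rs_r <- hp_r - sites$flank_l[i]; re_r <- rs_r + nchar(rc) - 1L
    rs_a <- hp_a - sites$flank_l[i]; re_a <- rs_a + nchar(ac) - 1L
    extend_one <- function(dir) {
      # returns list(rc, ac, k, ok) after extending in `dir` until the
      # relation breaks; ok = FALSE if a contig end or the scan bound stopped it
      rc2 <- rc; ac2 <- ac; k <- 0L
      b_r <- if (dir == "right") re_r else rs_r
      b_a <- if (dir == "right") re_a else rs_a
      repeat {
        if (context_relation(rc2, ac2) == "none") return(list(rc = rc2, ac = ac2, k = k, ok = TRUE))
        if (k >= max_ext) return(list(rc = rc2, ac = ac2, k = k, ok = FALSE))
        if (dir == "right") {
          pr <- b_r + k + 1L; pa <- b_a + k + 1L
          if (pr > nchar(hseq_r) || pa > nchar(hseq_a)) {
            return(list(rc = rc2, ac = ac2, k = k, ok = FALSE))
          }
          rc2 <- paste0(rc2, substr(hseq_r, pr, pr))
          ac2 <- paste0(ac2, substr(hseq_a, pa, pa))
        } else {
          pr <- b_r - k - 1L; pa <- b_a - k - 1L
          if (pr < 1L || pa < 1L) return(list(rc = rc2, ac = ac2, k = k, ok = FALSE))
          rc2 <- paste0(substr(hseq_r, pr, pr), rc2)
          ac2 <- paste0(substr(hseq_a, pa, pa), ac2)
        }
        k <- k + 1L
      }
    }
    if (rel == "right") {
      res <- extend_one("right"); side <- "right"
    } else if (rel == "left") {
      res <- extend_one("left"); side <- "left"
    } else {
      r1 <- extend_one("right"); r2 <- extend_one("left")
      if (r1$ok && (!r2$ok || r1$k <= r2$k)) { res <- r1; side <- "right" }
      else { res <- r2; side <- "left" }
    }
    sites$ref_context[i] <- res$rc; sites$alt_context[i] <- res$ac
    sites$extended_side[i] <- side
    if (side == "right") {
      sites$eff_end[i] <- sites$end[i] + res$k
      sites$ctx_ref_end[i] <- sites$ctx_ref_end[i] + res$k
    } else {
      sites$eff_start[i] <- sites$pos[i] - res$k
      sites$ctx_ref_start[i] <- sites$ctx_ref_start[i] - res$k
    }
    sites$eff_len[i] <- max(nchar(res$rc), nchar(res$ac)) -
      sites$flank_l[i] - sites$flank_r[i]
    if (!res$ok || sites$eff_len[i] > lim) sites$disregarded[i] <- TRUE
  }
  sites
}

#' Cluster nearby HET sites into cohorts
#'
#' Variants within `cohort_distance` (end-to-start) chain transitively into a
#' cohort, which extends in either direction until no further variant can be
#' reached. Each cohort carries combined per-haplotype strings spanning the
#' cohort's reference interval plus `flank_len` on each side, used for
#' cohort-first assignment.
#'
#' @param sites output of [extend_effective()] (sorted by position).
#' @param haps output of [phased_haplotypes()].
#' @param config an [assignment_config()].
#' @return list with `sites` (cohort_id column added; NA for singletons) and
#'   `cohorts` data.frame (`cohort_id`, `chrom`, `start`, `end`,
#'   `hap1_string`, `hap2_string`, `n_members`).
#' @export
build_cohorts <- function(sites, haps, config = assignment_config()) {
  n <- nrow(sites)
  sites$cohort_id <- rep(NA_integer_, n)
  if (n == 0L) {
    return(list(sites = sites,
                cohorts = data.frame(cohort_id = integer(0), chrom = character(0),
                                     start = integer(0), end = integer(0),
                                     hap1_string = character(0),
                                     hap2_string = character(0),
                                     n_members = integer(0))))
  }
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  grp <- integer(n); g <- 1L; grp[1] <- 1L
  for (i in seq_len(n)[-1]) {
    gap <- sites$pos[i] - sites$end[i - 1L]
    if (sites$chrom[i] != sites$chrom[i - 1L] || gap > config$cohort_distance) {
      g <- g + 1L
    }
    grp[i] <- g
  }
  tab <- table(grp)
  multi <- as.integer(names(tab)[tab >= 2L])
  cohorts <- vector("list", length(multi))
  for (k in seq_along(multi)) {
    idx <- which(grp == multi[k])
    sites$cohort_id[idx] <- k
    cstart <- min(sites$pos[idx]); cend <- max(sites$end[idx])
    strs <- character(2)
    for (h in 1:2) {
      a <- map_ref_to_hap(haps[[h]]$map, cstart - config$flank_len)
      b <- map_ref_to_hap(haps[[h]]$map, cend + config$flank_len)
      if (is.na(a)) a <- max(1L, map_ref_to_hap(haps[[h]]$map, cstart) - config$flank_len)
      if (is.na(b)) b <- map_ref_to_hap(haps[[h]]$map, cend) # degenerate fallback
      strs[h] <- substr(haps[[h]]$seq, a, b)
    }
    cohorts[[k]] <- data.frame(cohort_id = k, chrom = sites$chrom[idx[1]],
                               start = cstart, end = cend,
                               hap1_string = strs[1], hap2_string = strs[2],
                               n_members = length(idx), stringsAsFactors = FALSE)
  }
  list(sites = sites, cohorts = do.call(rbind, cohorts))
}

#' Prepare HET sites for assignment
#'
#' End-to-end site preparation for one chromosome: overlap removal, HET
#' selection, haplotype construction, context building, effective-variant
#' extension and cohort clustering.
#'
#' @param variants all variants on the chromosome (usable and not).
#' @param ref_seq the chromosome sequence.
#' @param config an [assignment_config()].
#' @return list with `sites`, `cohorts`, `haps`, `removed` (variants dropped
#'   by overlap removal).
#' @export
prepare_het_sites <- function(variants, ref_seq, config = assignment_config()) {
  rm <- remove_overlapping(variants)
  usable <- rm$kept[rm$kept$usable, , drop = FALSE]
  haps <- phased_haplotypes(ref_seq, usable)
  sites <- select_het_sites(usable)
  sites <- build_context(sites, haps, config)
  sites <- extend_effective(sites, haps, config)
  co <- build_cohorts(sites, haps, config)
  list(sites = co$sites, cohorts = co$cohorts, haps = haps,
       removed = rm$removed)
}
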