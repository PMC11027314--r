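# Diploid synthetic-data generator: personalized haplotypes from a reference
# plus phased variants, truth-tagged Illumina-like reads, a truth-preserving
# oracle aligner, and controlled bias injection (loss / flux / gap shift).

#' Simulation parameters
#'
#' Defaults are the package's study conditions: 150 bp single-end reads at
#' 15x coverage per haplotype (~30x total) with a 0.002 per-base substitution
#' error rate, and distinct random seeds for the two haplotypes so their
#' coverage profiles are uncorrelated.
#'
#' @param read_length read length in bp.
#' @param coverage per-haplotype mean coverage (x).
#' @param error_rate per-base substitution error rate in `[0, 1)`.
#' @param paired simulate fixed-fragment read pairs instead of single ends.
#' @param fragment_len fragment length when `paired = TRUE`.
#' @param seeds integer seeds, one per haplotype; must differ.
#' @return a `sim_params` list.
#' @export
sim_params <- function(read_length = 150L, coverage = 15, error_rate = 0.002,
                       paired = FALSE, fragment_len = 450L, seeds = c(101L, 202L)) {
  stopifnot(coverage > 0, error_rate >= 0, error_rate < 1,
            length(seeds) == 2L, seeds[1] != seeds[2], read_length >= 1)
  structure(list(read_length = as.integer(read_length), coverage = coverage,
                 error_rate = error_rate, paired = paired,
                 fragment_len = as.integer(fragment_len),
                 seeds = as.integer(seeds)),
            class = "sim_params")
}

#' Build a personalized haplotype from a reference and phased variants
#'
#' Applies each variant's allele on the chosen haplotype (allele index from
#' `gt1`/`gt2`) and records the piecewise coordinate correspondence between
#' haplotype and reference positions. Variants must be non-overlapping (use
#' [remove_overlapping()]) and sorted by position.
#'
#' @param ref_seq reference sequence (single chromosome).
#' @param variants variant data.frame (see [read_phased_vcf()]).
#' @param hap_index 1 or 2.
#' @return list with `seq` (haplotype sequence) and `map`, a data.frame of
#'   aligned blocks (`ref_start`, `hap_start`, `len`) usable with
#'   [map_hap_to_ref()] / [map_ref_to_hap()].
#' @export
build_consensus <- function(ref_seq, variants, hap_index) {
  stopifnot(hap_index %in% c(1L, 2L))
  v <- variants[variants$usable, , drop = FALSE]
  v <- v[order(v$pos), , drop = FALSE]
  allele_idx <- if (hap_index == 1L) v$gt1 else v$gt2
  pieces <- character(0)
  blocks_ref <- integer(0); blocks_hap <- integer(0); blocks_len <- integer(0)
  cur_ref <- 1L; cur_hap <- 1L
  L <- nchar(ref_seq)
  add_block <- function(rs, hs, len) {
    n <- length(blocks_ref)
    if (n && blocks_ref[n] + blocks_len[n] == rs && blocks_hap[n] + blocks_len[n] == hs) {
      blocks_len[n] <<- blocks_len[n] + len        # merge contiguous blocks
    } else {
      blocks_ref <<- c(blocks_ref, rs); blocks_hap <<- c(blocks_hap, hs)
      blocks_len <<- c(blocks_len, len)
    }
  }
  for (i in seq_len(nrow(v))) {
    pos <- v$pos[i]; ref_a <- v$ref[i]
    if (pos < cur_ref) stop("overlapping variants at ", v$chrom[i], ":", pos,
                            " — run remove_overlapping() first")
    obs <- substr(ref_seq, pos, pos + nchar(ref_a) - 1L)
    if (obs != ref_a) {
      stop("REF allele mismatch at ", v$chrom[i], ":", pos, " (VCF ", ref_a,
           ", reference ", obs, ") — wrong reference build?")
    }
    allele <- if (allele_idx[i] == 0L) ref_a else v$alt[i]
    # untouched chunk before the variant
    if (pos > cur_ref) {
      len <- pos - cur_ref
      pieces <- c(pieces, substr(ref_seq, cur_ref, pos - 1L))
      add_block(cur_ref, cur_hap, len)
      cur_hap <- cur_hap + len
      cur_ref <- pos
    }
    nr <- nchar(ref_a); na <- nchar(allele)
    pieces <- c(pieces, allele)
    m <- min(nr, na)
    if (m > 0L) add_block(cur_ref, cur_hap, m)
    cur_ref <- cur_ref + nr
    cur_hap <- cur_hap + na
  }
  if (cur_ref <= L) {
    len <- L - cur_ref + 1L
    pieces <- c(pieces, substr(ref_seq, cur_ref, L))
    add_block(cur_ref, cur_hap, len)
  }
  list(seq = paste(pieces, collapse = ""),
       map = data.frame(ref_start = blocks_ref, hap_start = blocks_hap,
                        len = blocks_len))
}

#' Project a haplotype interval onto the reference
#'
#' Returns the reference coordinates of the first and last *anchored*
#' (block-aligned) bases of the interval; positions falling inside inserted
#' haplotype sequence are skipped. `c(NA, NA)` if nothing anchors.
#'
#' @param map coordinate map from [build_consensus()].
#' @param start,end 1-based haplotype interval.
#' @return integer vector `c(ref_start, ref_end)`.
#' @export
map_hap_to_ref <- function(map, start, end = start) {
  he <- map$hap_start + map$len - 1L
  hit <- which(map$hap_start <= end & he >= start)
  if (!length(hit)) return(c(NA_integer_, NA_integer_))
  first <- hit[1]; last <- hit[length(hit)]
  rs <- map$ref_start[first] + max(start - map$hap_start[first], 0L)
  re <- map$ref_start[last] + min(end - map$hap_start[last], map$len[last] - 1L)
  c(rs, re)
}

#' Project a reference position onto a haplotype
#'
#' @param map coordinate map from [build_consensus()].
#' @param pos reference position; must be block-aligned (variant anchor bases
#'   always are).
#' @return haplotype position, or NA if `pos` was deleted on this haplotype.
#' @export
map_ref_to_hap <- function(map, pos) {
  re <- map$ref_start + map$len - 1L
  i <- which(map$ref_start <= pos & re >= pos)
  if (!length(i)) return(NA_integer_)
  map$hap_start[i[1]] + (pos - map$ref_start[i[1]])
}

#' Simulate truth-tagged reads from two haplotypes
#'
#' Poisson read counts (expectation `coverage * hap_length / read_length`),
#' uniform start positions, i.i.d. substitution errors at the configured
#' rate. Each haplotype uses its own seed; runs are fully reproducible.
#'
#' @param hap_seqs list of two haplotype sequences.
#' @param params a [sim_params()] object.
#' @return data.frame of simulated reads: `read_id`, `hap`, `hap_start`,
#'   `hap_end`, `seq`, `n_err`.
#' @export
simulate_reads <- function(hap_seqs, params) {
  stopifnot(length(hap_seqs) == 2L, inherits(params, "sim_params"))
  rl <- params$read_length
  out <- vector("list", 2L)
  for (h in 1:2) {
    hs <- hap_seqs[[h]]
    L <- nchar(hs)
    if (rl > L) stop("read length exceeds haplotype length")
    set.seed(params$seeds[h])
    n <- rpois(1L, params$coverage * L / rl)
    if (params$paired) n <- ceiling(n / 2)
    starts <- sample.int(L - (if (params$paired) params$fragment_len else rl) + 1L,
                         n, replace = TRUE)
    if (params$paired) {
      starts <- c(starts, starts + params$fragment_len - rl)
    }
    seqs <- substring(hs, starts, starts + rl - 1L)
    nerr <- rbinom(length(starts), rl, params$error_rate)
    idx <- which(nerr > 0L)
    for (k in idx) {
      offs <- sample.int(rl, nerr[k])
      s <- strsplit(seqs[k], "")[[1]]
      for (o in offs) {
        s[o] <- sample(setdiff(c("A", "C", "G", "T"), s[o]), 1L)
      }
      seqs[k] <- paste(s, collapse = "")
    }
    out[[h]] <- data.frame(
      read_id = sprintf("h%d_%06d", h, seq_along(starts)),
      hap = h, hap_start = as.integer(starts),
      hap_end = as.integer(starts + rl - 1L),
      seq = seqs, n_err = nerr, stringsAsFactors = FALSE)
  }
  rbind(out[[1]], out[[2]])
}

# CIGAR + reference position for a haplotype interval, walking the block map.
# Unanchored inserted prefixes/suffixes are soft-clipped; interior insertions
# become I, skipped reference becomes D. NULL if no base anchors.
interval_alignment <- function(map, hs, he) {
  h_end <- map$hap_start + map$len - 1L
  hit <- which(map$hap_start <= he & h_end >= hs)
  if (!length(hit)) return(NULL)
  ops <- character(0); lens <- integer(0)
  first <- TRUE
  pos <- NA_integer_
  prev_block <- NA_integer_
  for (b in hit) {
    bh_start <- map$hap_start[b]; bh_end <- h_end[b]
    if (first) {
      lead <- bh_start - hs            # inserted prefix -> soft clip
      if (lead > 0L) { ops <- c(ops, "S"); lens <- c(lens, lead) }
      pos <- map$ref_start[b] + max(hs - bh_start, 0L)
      first <- FALSE
    } else {
      # gap between consecutive blocks: hap gap -> I, ref gap -> D
      hap_gap <- bh_start - (h_end[prev_block] + 1L)
      ref_gap <- map$ref_start[b] - (map$ref_start[prev_block] + map$len[prev_block])
      if (hap_gap > 0L) { ops <- c(ops, "I"); lens <- c(lens, hap_gap) }
      if (ref_gap > 0L) { ops <- c(ops, "D"); lens <- c(lens, ref_gap) }
    }
    mlen <- min(he, bh_end) - max(hs, bh_start) + 1L
    ops <- c(ops, "M"); lens <- c(lens, mlen)
    prev_block <- b
  }
  trail <- he - h_end[hit[length(hit)]]
  if (trail > 0L) { ops <- c(ops, "S"); lens <- c(lens, trail) }
  list(pos = pos, cigar = cigar_string(ops, lens))
}

#' Place simulated reads at their true origin (oracle alignment)
#'
#' A perfect aligner: every read is placed at its true reference interval,
#' with the CIGAR derived from the haplotype coordinate map (I for inserted
#' haplotype bases, D for deleted reference bases, soft clips for inserted
#' sequence unanchored at a read end) and MAPQ set to `mapq_max`. Truth tags
#' (haplotype, true interval) are attached. Reads lying entirely within
#' inserted sequence cannot be anchored and are dropped.
#'
#' @param sim_reads output of [simulate_reads()].
#' @param coord_maps list of the two coordinate maps from [build_consensus()].
#' @param chrom chromosome name.
#' @param mapq_max MAPQ to assign (42 by default).
#' @return alignment data.frame (see [read_alignments()] for columns).
#' @export
oracle_align <- function(sim_reads, coord_maps, chrom, mapq_max = 42L) {
  n <- nrow(sim_reads)
  pos <- integer(n); cig <- character(n); ts <- integer(n); te <- integer(n)
  keep <- logical(n)
  for (h in 1:2) {
    map <- coord_maps[[h]]
    idx <- which(sim_reads$hap == h)
    single <- nrow(map) == 1L
    for (i in idx) {
      hs <- sim_reads$hap_start[i]; he <- sim_reads$hap_end[i]
      if (single) {
        off <- map$ref_start[1] - map$hap_start[1]
        pos[i] <- hs + off; cig[i] <- paste0(he - hs + 1L, "M")
        ts[i] <- hs + off; te[i] <- he + off
        keep[i] <- TRUE
        next
      }
      al <- interval_alignment(map, hs, he)
      if (is.null(al)) next
      pos[i] <- al$pos
      cig[i] <- al$cigar
      rr <- map_hap_to_ref(map, hs, he)
      ts[i] <- rr[1]; te[i] <- rr[2]
      keep[i] <- TRUE
    }
  }
  out <- data.frame(
    read_id = sim_reads$read_id[keep], chrom = chrom, pos = pos[keep],
    cigar = cig[keep], mapq = as.integer(mapq_max), seq = sim_reads$seq[keep],
    hap = sim_reads$hap[keep], true_chrom = chrom,
    true_start = ts[keep], true_end = te[keep], stringsAsFactors = FALSE)
  out$ref_end <- out$pos + cigar_ref_len(out$cigar) - 1L
  out[order(out$pos), , drop = FALSE]
}

#' Describe a bias injection
#'
#' Exactly one mode per spec: `loss` removes ALT-haplotype reads over target
#' sites with probability `fraction`; `flux` adds `count` foreign reads (true
#' origin elsewhere) carrying the local reference sequence at the given MAPQ;
#' `gap_shift` re-places alignment gaps of reads spanning tandem repeats at
#' their leftmost/rightmost score-equivalent position, leaving sequences
#' untouched.
#'
#' @param mode `"loss"`, `"flux"` or `"gap_shift"`.
#' @param sites data.frame of target sites (`chrom`, `pos`, `end`, and for
#'   loss the ALT haplotype index column `alt_hap` or genotype columns).
#' @param fraction loss fraction f in `[0, 1]` (loss only).
#' @param count number of foreign reads per site (flux only).
#' @param mapq MAPQ of injected foreign reads (flux only).
#' @param origin_offset displacement of the foreign reads' recorded true
#'   origin (flux only).
#' @param policy `"leftmost"` or `"rightmost"` gap placement (gap_shift only).
#' @return a `bias_spec` list.
#' @export
bias_spec <- function(mode = c("loss", "flux", "gap_shift"), sites = NULL,
                      fraction = NULL, count = NULL, mapq = 0L,
                      origin_offset = 1000000L,
                      policy = c("rightmost", "leftmost")) {
  mode <- match.arg(mode)
  if (mode == "loss") stopifnot(!is.null(fraction), fraction >= 0, fraction <= 1)
  if (mode == "flux") stopifnot(!is.null(count), count >= 0)
  structure(list(mode = mode, sites = sites, fraction = fraction,
                 count = count, mapq = as.integer(mapq),
                 origin_offset = as.integer(origin_offset),
                 policy = match.arg(policy)),
            class = "bias_spec")
}

#' Inject a controlled bias event into alignments
#'
#' @param reads alignment data.frame with truth tags (loss/flux targeting).
#' @param spec a [bias_spec()].
#' @param seed RNG seed (loss and flux sampling).
#' @param ref_seqs named character vector of reference sequences (required
#'   for flux sequences and gap_shift re-placement).
#' @param read_length length of injected flux reads (default 150).
#' @return modified alignment data.frame.
#' @export
inject_bias <- function(reads, spec, seed = 1L, ref_seqs = NULL,
                        read_length = 150L) {
  stopifnot(inherits(spec, "bias_spec"))
  set.seed(seed)
  switch(spec$mode,
    loss = inject_loss(reads, spec),
    flux = inject_flux(reads, spec, ref_seqs, read_length),
    gap_shift = inject_gap_shift(reads, spec, ref_seqs)
  )
}

site_alt_hap <- function(sites) {
  if (!is.null(sites$alt_hap)) return(sites$alt_hap)
  ifelse(sites$gt1 != 0L, 1L, 2L)
}

inject_loss <- function(reads, spec) {
  if (is.na(spec$fraction) || spec$fraction == 0) return(reads)
  sites <- spec$sites
  alt_hap <- site_alt_hap(sites)
  drop <- logical(nrow(reads))
  for (i in seq_len(nrow(sites))) {
    cand <- which(!drop &
                    reads$true_chrom == sites$chrom[i] &
                    reads$hap == alt_hap[i] &
                    reads$true_start <= sites$end[i] &
                    reads$true_end >= sites$pos[i])
    if (length(cand)) {
      hit <- cand[runif(length(cand)) < spec$fraction]
      drop[hit] <- TRUE
    }
  }
  reads[!drop, , drop = FALSE]
}

inject_flux <- function(reads, spec, ref_seqs, read_length) {
  stopifnot(!is.null(ref_seqs))
  sites <- spec$sites
  new <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    ch <- sites$chrom[i]
    if (!ch %in% names(ref_seqs)) stop("flux target on unknown chromosome: ", ch)
    L <- nchar(ref_seqs[[ch]])
    n <- spec$count
    if (n == 0L) { new[[i]] <- NULL; next }
    lo <- max(1L, sites$pos[i] - read_length + 1L)
    hi <- min(sites$pos[i], L - read_length + 1L)
    starts <- sample(seq.int(lo, hi), n, replace = TRUE)
    new[[i]] <- data.frame(
      read_id = sprintf("flux_%s_%d_%03d", ch, sites$pos[i], seq_len(n)),
      chrom = ch, pos = starts, cigar = paste0(read_length, "M"),
      mapq = spec$mapq,
      seq = substring(ref_seqs[[ch]], starts, starts + read_length - 1L),
      hap = 1L, true_chrom = ch,
      true_start = starts + spec$origin_offset,
      true_end = starts + spec$origin_offset + read_length - 1L,
      stringsAsFactors = FALSE)
    new[[i]]$ref_end <- new[[i]]$pos + read_length - 1L
  }
  out <- rbind(reads, do.call(rbind, new))
  out[order(out$chrom, out$pos), , drop = FALSE]
}

# Enumerate score-equivalent placements of a single-gap alignment and return
# the leftmost/rightmost. Score equivalence = same number of matching M bases
# against the reference, same total gap length.
shift_gap_read <- function(pos, cigar, seq, ref_seq, policy) {
  cg <- parse_cigar(cigar)
  gap_idx <- which(cg$op %in% c("D", "I"))
  if (length(gap_idx) != 1L || !all(cg$op %in% c("M", "D", "I"))) {
    return(NULL)  # only single-gap, unclipped reads are re-placed
  }
  gop <- cg$op[gap_idx]; glen <- cg$len[gap_idx]
  a <- sum(cg$len[cg$op == "M"][seq_len(gap_idx - 1L)])
  total_m <- sum(cg$len[cg$op == "M"])
  score <- function(split) {
    # split = length of leading M
    if (gop == "D") {
      left_ref <- substr(ref_seq, pos, pos + split - 1L)
      right_ref <- substr(ref_seq, pos + split + glen, pos + total_m + glen - 1L)
      sum(strsplit(paste0(left_ref, right_ref), "")[[1]] ==
            strsplit(seq, "")[[1]])
    } else {
      left_ref <- substr(ref_seq, pos, pos + split - 1L)
      right_ref <- substr(ref_seq, pos + split, pos + total_m - 1L)
      qs <- strsplit(seq, "")[[1]]
      sum(c(qs[seq_len(split)],
            if (split + glen < length(qs)) qs[(split + glen + 1L):length(qs)]) ==
            strsplit(paste0(left_ref, right_ref), "")[[1]])
    }
  }
  base_score <- score(a)
  splits <- seq.int(1L, total_m - 1L)
  scores <- vapply(splits, score, numeric(1))
  eq <- splits[scores == max(scores)]
  eq <- eq[vapply(eq, score, numeric(1)) >= base_score]
  if (!length(eq)) return(NULL)
  pick <- if (policy == "leftmost") min(eq) else max(eq)
  if (pick == a) return(NULL)  # unchanged
  list(pos = pos,
       cigar = cigar_string(c("M", gop, "M"),
                            c(pick, glen, total_m - pick)))
}

inject_gap_shift <- function(reads, spec, ref_seqs) {
  stopifnot(!is.null(ref_seqs))
  has_gap <- grepl("[DI]", reads$cigar)
  for (i in which(has_gap)) {
    rs <- ref_seqs[[reads$chrom[i]]]
    res <- shift_gap_read(reads$pos[i], reads$cigar[i], reads$seq[i], rs,
                          spec$policy)
    if (!is.null(res)) {
      reads$pos[i] <- res$pos
      reads$cigar[i] <- res$cigar
      reads$ref_end[i] <- res$pos + cigar_ref_len(res$cigar) - 1L
    }
  }
  reads
}

#' Generate a random reference sequence
#'
#' @param length sequence length (bp).
#' @param seed RNG seed.
#' @param gc GC content.
#' @return a character string of A/C/G/T.
#' @export
synth_reference <- function(length, seed = 1L, gc = 0.41) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a panel of phased heterozygous SNVs
#'
#' Sites are placed with at least `min_spacing` bp between them; the ALT
#' allele differs from the reference base and the carrying haplotype is
#' random (phased genotypes `0|1` or `1|0`).
#'
#' @param ref_seq reference sequence.
#' @param n number of HET SNVs.
#' @param seed RNG seed.
#' @param chrom chromosome name.
#' @param min_spacing minimum distance between sites (bp).
#' @return variant data.frame in [read_phased_vcf()] layout.
#' @export
synth_het_snvs <- function(ref_seq, n, seed = 1L, chrom = "chrS",
                           min_spacing = 300L) {
  set.seed(seed)
  L <- nchar(ref_seq)
  lo <- 100L; hi <- L - 100L
  if ((hi - lo) %/% min_spacing < n) stop("reference too short for ", n, " sites")
  slots <- seq.int(lo, hi - min_spacing, by = min_spacing)
  pos <- sort(sample(slots, n) + sample.int(min_spacing %/% 2L, n, replace = TRUE))
  refb <- substring(ref_seq, pos, pos)
  altb <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                 character(1), USE.NAMES = FALSE)
  swap <- runif(n) < 0.5
  data.frame(chrom = chrom, pos = as.integer(pos), end = as.integer(pos),
             ref = refb, alt = altb,
             gt1 = ifelse(swap, 1L, 0L), gt2 = ifelse(swap, 0L, 1L),
             phased = TRUE, is_het = TRUE, usable = TRUE,
             length_delta = 0L, stringsAsFactors = FALSE)
}
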