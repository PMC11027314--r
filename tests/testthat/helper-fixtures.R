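# Shared fixture builders; all fixtures are generated in code at test time.

# one variant row in the read_phased_vcf() layout
variant_row <- function(chrom, pos, ref, alt, gt = c(0L, 1L), phased = TRUE,
                        usable = NULL) {
  if (is.null(usable)) usable <- phased && !anyNA(gt)
  data.frame(chrom = chrom, pos = as.integer(pos),
             end = as.integer(pos + nchar(ref) - 1L),
             ref = ref, alt = alt, gt1 = gt[1], gt2 = gt[2],
             phased = phased,
             is_het = !anyNA(gt) && gt[1] != gt[2],
             usable = usable,
             length_delta = nchar(alt) - nchar(ref),
             stringsAsFactors = FALSE)
}

# a reference with an embedded tandem repeat: left + anchor + unit^n + right
repeat_reference <- function(unit, n_units, left_seed = 3, right_seed = 4,
                             left_len = 300, right_len = 300, anchor = "G",
                             terminator = "T") {
  left <- synth_reference(left_len, seed = left_seed)
  right <- synth_reference(right_len, seed = right_seed)
  list(seq = paste0(left, anchor, strrep(unit, n_units), terminator, right),
       anchor_pos = left_len + 1L,
       tract_start = left_len + 2L,
       tract_end = left_len + 1L + nchar(unit) * n_units)
}

# full null pipeline on a small synthetic diploid: returns prep, truth-tagged
# oracle alignments and the per-site balance table
null_pipeline <- function(ref_len = 60000, n_sites = 40, seed = 7,
                          coverage = 15, error_rate = 0, chrom = "chrN",
                          min_spacing = 600) {
  ref <- synth_reference(ref_len, seed = seed)
  v <- synth_het_snvs(ref, n_sites, seed = seed + 1, chrom = chrom,
                      min_spacing = min_spacing)
  prep <- prepare_het_sites(v, ref)
  params <- sim_params(coverage = coverage, error_rate = error_rate,
                       seeds = c(seed + 10, seed + 20))
  sim <- simulate_reads(list(prep$haps[[1]]$seq, prep$haps[[2]]$seq), params)
  aligned <- oracle_align(sim, list(prep$haps[[1]]$map, prep$haps[[2]]$map),
                          chrom)
  list(ref = ref, variants = v, prep = prep, sim = sim, aligned = aligned)
}

# sites where a rightmost gap shift straddles the naive footprint: a
# deletion of d bases in a repeat run shorter than 2d
short_run_deletion_ref <- function(n_sites = 6, spacing = 400, seed = 9) {
  base <- synth_reference(spacing * (n_sites + 1), seed = seed)
  vars <- list()
  seqs <- character(n_sites + 1)
  seqs[1] <- substr(base, 1, spacing)
  offset <- spacing
  for (i in seq_len(n_sites)) {
    # G + ATATAT + C : deletion of ATAT (d = 4), run of 3 units (r = 6 < 2d)
    motif <- "GATATATC"
    pos <- offset + 1L
    vars[[i]] <- variant_row("chrD", pos, "GATAT", "G",
                             gt = if (i %% 2) c(0L, 1L) else c(1L, 0L))
    seqs[i + 1] <- paste0(motif,
                          substr(base, offset + 1, offset + spacing - nchar(motif)))
    offset <- offset + spacing
  }
  list(seq = paste(seqs, collapse = ""), variants = do.call(rbind, vars))
}

# constant-depth diploid null pileup: exact 50/50 HET columns jitter-spaced
# about every `het_spacing` bp, sequencing errors below the allele threshold
null_scan_pileup <- function(len = 200000, depth = 60, het_spacing = 1200,
                             seed = 5, chrom = "chrP") {
  set.seed(seed)
  ref <- strsplit(synth_reference(len, seed = seed + 1), "")[[1]]
  p <- data.frame(chrom = chrom, pos = seq_len(len), ref = ref,
                  depth = depth, A = 0L, C = 0L, G = 0L, T = 0L,
                  stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  ri <- match(ref, bases)
  p[cbind(seq_len(len), 4L + ri)] <- depth
  # scattered exact 50/50 HET columns
  anchors <- seq(200, len - 200 - het_spacing %/% 3L, by = het_spacing)
  het_pos <- anchors + sample.int(het_spacing %/% 3L, length(anchors),
                                  replace = TRUE)
  for (pos in het_pos) {
    alt <- sample(setdiff(bases, ref[pos]), 1)
    p[pos, 4L + match(ref[pos], bases)] <- depth %/% 2L
    p[pos, 4L + match(alt, bases)] <- depth - depth %/% 2L
  }
  # sprinkle sequencing errors well below the 15% allele threshold
  err_pos <- sample(seq_len(len), len %/% 50L)
  err_pos <- setdiff(err_pos, het_pos)
  for (pos in err_pos) {
    alt <- sample(setdiff(bases, ref[pos]), 1)
    p[pos, 4L + match(ref[pos], bases)] <- depth - 2L
    p[pos, 4L + match(alt, bases)] <- 2L
  }
  attr(p, "het_pos") <- het_pos
  p
}

# the null pileup with a collapsed segmental duplication injected: doubled
# depth plus tri-allelic and dominance-skewed columns across the segment
duplication_scan_pileup <- function(len = 200000, depth = 60,
                                    dup_start = 50001, dup_len = 5000,
                                    seed = 5) {
  p <- null_scan_pileup(len = len, depth = depth, seed = seed)
  bases <- c("A", "C", "G", "T")
  set.seed(seed + 100)
  span <- dup_start:(dup_start + dup_len - 1L)
  ri <- match(p$ref[span], bases)
  p$depth[span] <- 2L * depth
  p[cbind(span, 4L + ri)] <- 2L * depth
  # paralog-divergence columns: tri-allelic or strongly unbalanced
  div <- span[seq(1, dup_len, by = 50)]
  for (pos in div) {
    others <- setdiff(bases, p$ref[pos])
    p[pos, 4L + match(p$ref[pos], bases)] <- depth          # 50%
    p[pos, 4L + match(others[1], bases)] <- depth %/% 3L * 2L  # ~33%
    p[pos, 4L + match(others[2], bases)] <- 2L * depth - depth - depth %/% 3L * 2L
  }
  attr(p, "dup_span") <- c(dup_start, dup_start + dup_len - 1L)
  p
}
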