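# Naive and context-aware read assignment, tallies, and their robustness
# properties.

snv_site <- function(seed = 91) {
  ref <- synth_reference(400, seed = seed)
  pos <- 200L
  r <- substr(ref, pos, pos)
  v <- variant_row("c", pos, r, setdiff(c("A", "C", "G", "T"), r)[1])
  prep <- prepare_het_sites(v, ref)
  list(ref = ref, prep = prep, site = prep$sites[1, ], pos = pos)
}

read_row <- function(pos, cigar, seq, chrom = "c", mapq = 42L) {
  data.frame(read_id = "r", chrom = chrom, pos = as.integer(pos),
             cigar = cigar, mapq = mapq, seq = seq,
             hap = NA_integer_, true_chrom = NA_character_,
             true_start = NA_integer_, true_end = NA_integer_,
             ref_end = as.integer(pos) + cigar_ref_len(cigar) - 1L,
             stringsAsFactors = FALSE)
}

test_that("naive assignment reads bases at the exact variant coordinates", {
  ss <- snv_site()
  site <- ss$site
  refseq <- substr(ss$ref, ss$pos - 50, ss$pos + 49)
  r_ref <- read_row(ss$pos - 50, "100M", refseq)
  expect_equal(assign_read_naive(site, r_ref), "REF")

  alt_seq <- refseq
  substr(alt_seq, 51, 51) <- site$alt
  expect_equal(assign_read_naive(site, read_row(ss$pos - 50, "100M", alt_seq)),
               "ALT")

  err_seq <- refseq
  substr(err_seq, 51, 51) <- setdiff(c("A", "C", "G", "T"),
                                     c(site$ref, site$alt))[1]
  expect_equal(assign_read_naive(site, read_row(ss$pos - 50, "100M", err_seq)),
               "OTHER")
})

test_that("naive assignment calls OTHER when a gap is placed off the VCF spot", {
  # deletion of ATAT in a 3-unit AT tract; a rightmost-shifted gap straddles
  # the variant footprint
  srd <- short_run_deletion_ref(n_sites = 1)
  prep <- prepare_het_sites(srd$variants, srd$seq)
  site <- prep$sites[1, ]
  alt_hap_idx <- site$alt_hap
  hmap <- prep$haps[[alt_hap_idx]]$map
  hs <- map_ref_to_hap(hmap, site$pos - 40L)
  sim <- data.frame(read_id = "r", hap = alt_hap_idx, hap_start = hs,
                    hap_end = hs + 99L,
                    seq = substr(prep$haps[[alt_hap_idx]]$seq, hs, hs + 99L),
                    n_err = 0L, stringsAsFactors = FALSE)
  al <- oracle_align(sim, list(prep$haps[[1]]$map, prep$haps[[2]]$map), "chrD")
  expect_equal(assign_read_naive(site, al[1, ]), "ALT")  # gap at VCF spot
  shifted <- inject_bias(al, bias_spec("gap_shift", policy = "rightmost"),
                         ref_seqs = c(chrD = srd$seq))
  expect_true(shifted$cigar[1] != al$cigar[1])
  expect_equal(assign_read_naive(site, shifted[1, ]), "OTHER")
})

test_that("context-aware assignment matches full and partial contexts", {
  ss <- snv_site()
  site <- ss$site
  alt_full <- gsub(site$ref_context, site$alt_context,
                   substr(ss$ref, ss$pos - 50, ss$pos + 49), fixed = TRUE)
  # full ALT context inside the read
  expect_equal(assign_read_context(site, read_row(ss$pos - 50, "100M", alt_full)),
               "ALT")
  # full REF context
  expect_equal(assign_read_context(
    site, read_row(ss$pos - 50, "100M", substr(ss$ref, ss$pos - 50, ss$pos + 49))),
    "REF")
  # read truncated mid-flank: only a prefix of the REF context is present
  trunc_seq <- substr(ss$ref, ss$pos - 80, ss$pos + 2)
  expect_equal(assign_read_context(site, read_row(ss$pos - 80, "83M", trunc_seq)),
               "REF")
  # read with the variant base altered to a third allele matches neither
  neither <- substr(ss$ref, ss$pos - 50, ss$pos + 49)
  substr(neither, 51, 51) <- setdiff(c("A", "C", "G", "T"),
                                     c(site$ref, site$alt))[1]
  expect_equal(assign_read_context(site, read_row(ss$pos - 50, "100M", neither)),
               "OTHER")
})

test_that("reads not spanning the effective variant are BOTH", {
  rr <- repeat_reference("ATTC", 7)
  v <- variant_row("chrR", rr$anchor_pos, "GATTC", "G")
  prep <- prepare_het_sites(v, rr$seq)
  site <- prep$sites[1, ]
  # a read wholly inside the repeat tract matches both haplotypes
  inner <- read_row(rr$tract_start + 2L, "20M",
                    substr(rr$seq, rr$tract_start + 2L, rr$tract_start + 21L),
                    chrom = "chrR")
  expect_equal(assign_read_context(site, inner), "BOTH")
})

test_that("right-side anchoring recovers reads with unanchored left context", {
  # insertion variant; a read starting inside the inserted sequence has its
  # left side unanchored (soft-clipped) but right-anchored matching works
  ref <- synth_reference(600, seed = 93)
  pos <- 300L
  ins <- "TTGACTTGCA"
  v <- variant_row("c", pos, substr(ref, pos, pos),
                   paste0(substr(ref, pos, pos), ins))
  prep <- prepare_het_sites(v, ref)
  site <- prep$sites[1, ]
  h2 <- prep$haps[[site$alt_hap]]
  hp <- map_ref_to_hap(h2$map, pos)
  hs <- hp + 4L                       # 4 bases into the insertion
  sim <- data.frame(read_id = "r", hap = site$alt_hap, hap_start = hs,
                    hap_end = hs + 79L, seq = substr(h2$seq, hs, hs + 79L),
                    n_err = 0L, stringsAsFactors = FALSE)
  maps <- list(prep$haps[[1]]$map, prep$haps[[2]]$map)
  if (site$alt_hap == 1L) maps <- maps else maps <- maps
  al <- oracle_align(sim, maps, "c")
  expect_match(al$cigar, "^[0-9]+S")
  expect_equal(assign_read_context(site, al[1, ]), "ALT")
})

test_that("tally counts calls, mismapped reads and mean MAPQ", {
  np <- null_pipeline(ref_len = 30000, n_sites = 6, seed = 94)
  ev <- tally_sites(np$prep$sites, np$aligned)
  expect_true(all(ev$n_ref + ev$n_alt + ev$n_both + ev$n_other == ev$n_overlap))
  expect_true(all(ev$mean_mapq == 42))
  expect_true(all(ev$n_mismapped == 0L))
  # zero overlapping reads: all-zero evidence, AB undefined
  far_site <- np$prep$sites[1, ]
  far_site$pos <- far_site$pos  # same site, empty read set
  ev0 <- tally_sites(np$prep$sites, np$aligned[0, ])
  expect_true(all(ev0$n_overlap == 0L))
  expect_true(all(is.na(assignment_balance(ev0))))
})

test_that("context calls recover the truth haplotype exactly on clean reads", {
  np <- null_pipeline(ref_len = 40000, n_sites = 25, seed = 95)
  sites <- np$prep$sites
  reads <- np$aligned
  for (i in sample(nrow(sites), 8)) {
    site <- sites[i, ]
    if (site$disregarded) next
    over <- which(reads$pos <= site$eff_start & reads$ref_end >= site$eff_end)
    calls <- vapply(over, function(r) assign_read_context(site, reads[r, ]),
                    character(1))
    want <- ifelse(reads$hap[over] == site$ref_hap, "REF", "ALT")
    expect_equal(calls, want)
  }
})

test_that("gap shifts change naive calls but leave context calls unchanged", {
  srd <- short_run_deletion_ref(n_sites = 6)
  prep <- prepare_het_sites(srd$variants, srd$seq)
  sim <- simulate_reads(list(prep$haps[[1]]$seq, prep$haps[[2]]$seq),
                        sim_params(error_rate = 0, coverage = 25,
                                   seeds = c(96L, 97L)))
  al <- oracle_align(sim, list(prep$haps[[1]]$map, prep$haps[[2]]$map), "chrD")
  shifted <- inject_bias(al, bias_spec("gap_shift", policy = "rightmost"),
                         ref_seqs = c(chrD = srd$seq))
  ev_ctx0 <- tally_sites(prep$sites, al, cohorts = prep$cohorts)
  ev_ctx1 <- tally_sites(prep$sites, shifted, cohorts = prep$cohorts)
  expect_equal(ev_ctx1[, c("n_ref", "n_alt", "n_both", "n_other")],
               ev_ctx0[, c("n_ref", "n_alt", "n_both", "n_other")])
  # exact recovery: every read covering the full context window is called
  # according to its truth haplotype; no read is OTHER
  for (i in seq_len(nrow(prep$sites))) {
    s <- prep$sites[i, ]
    cov <- which(shifted$pos <= s$ctx_ref_start &
                   shifted$ref_end >= s$ctx_ref_end)
    calls <- vapply(cov, function(r) assign_read_context(s, shifted[r, ]),
                    character(1))
    expect_equal(calls, ifelse(shifted$hap[cov] == s$ref_hap, "REF", "ALT"))
    expect_equal(ev_ctx1$n_other[i], 0L)
  }
  # naive loses ALT reads at every site (misattributed or OTHER)
  ev_n0 <- tally_sites(prep$sites, al, method = "naive")
  ev_n1 <- tally_sites(prep$sites, shifted, method = "naive")
  expect_true(all(ev_n1$n_alt < ev_n0$n_alt))
  expect_true(all(ev_n1$n_other > ev_n0$n_other))
})

test_that("swapping REF and ALT alleles swaps the tallies exactly", {
  np <- null_pipeline(ref_len = 30000, n_sites = 10, seed = 98)
  sites <- np$prep$sites
  swapped <- sites
  swapped$ref_context <- sites$alt_context
  swapped$alt_context <- sites$ref_context
  swapped$ref_hap <- sites$alt_hap
  swapped$alt_hap <- sites$ref_hap
  ev <- tally_sites(sites, np$aligned)
  ev_sw <- tally_sites(swapped, np$aligned)
  expect_equal(ev_sw$n_ref, ev$n_alt)
  expect_equal(ev_sw$n_alt, ev$n_ref)
  expect_equal(ev_sw$n_both, ev$n_both)
  expect_equal(ev_sw$n_other, ev$n_other)
})

test_that("cohort-matched reads are tallied for all member sites", {
  ref <- synth_reference(1000, seed = 99)
  mkv <- function(pos) {
    r <- substr(ref, pos, pos)
    variant_row("c", pos, r, setdiff(c("A", "C", "G", "T"), r)[1],
                gt = c(0L, 1L))
  }
  v <- rbind(mkv(480), mkv(492), mkv(505))
  prep <- prepare_het_sites(v, ref)
  expect_equal(prep$cohorts$n_members, 3L)
  # one hap2 (ALT) read spanning the whole cohort
  h2 <- prep$haps[[2]]
  r <- read_row(430L, "150M", substr(h2$seq, 430L, 579L))
  ev <- tally_sites(prep$sites, r, cohorts = prep$cohorts)
  expect_equal(ev$n_alt, c(1L, 1L, 1L))
  expect_equal(ev$n_ref, c(0L, 0L, 0L))
})
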