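# HET selection, overlap removal, allelic contexts, effective-variant
# extension and cohort clustering.

test_that("select_het_sites keeps HETs and drops hom / unusable genotypes", {
  v <- rbind(variant_row("c", 100, "A", "T", gt = c(0L, 1L)),
             variant_row("c", 200, "A", "T", gt = c(1L, 1L)),
             variant_row("c", 300, "A", "T", gt = c(NA, NA), phased = FALSE))
  out <- select_het_sites(v)
  expect_equal(out$pos, 100L)
})

test_that("remove_overlapping removes whole clash groups", {
  # deletion covering an SNV: both removed
  v <- rbind(variant_row("c", 10, "AAAAA", "A"),
             variant_row("c", 12, "A", "G"))
  rm <- remove_overlapping(v)
  expect_equal(nrow(rm$kept), 0L)
  expect_equal(sort(rm$removed$pos), c(10L, 12L))

  # adjacent but not overlapping SNVs are kept
  v2 <- rbind(variant_row("c", 10, "A", "G"), variant_row("c", 11, "C", "T"))
  expect_equal(nrow(remove_overlapping(v2)$kept), 2L)

  # three mutually overlapping variants all go
  v3 <- rbind(variant_row("c", 10, "AAAAAAAAAA", "A"),
              variant_row("c", 14, "AAAAA", "A"),
              variant_row("c", 18, "A", "C"))
  expect_equal(nrow(remove_overlapping(v3)$kept), 0L)

  # idempotence, and kept footprints are pairwise disjoint
  v4 <- rbind(v, v2, variant_row("c", 50, "ATT", "A"))
  k1 <- remove_overlapping(v4)$kept
  expect_identical(remove_overlapping(k1)$kept, k1)
  if (nrow(k1) > 1) {
    expect_true(all(k1$pos[-1] > k1$end[-nrow(k1)]))
  }
})

test_that("allelic contexts carry the allele with phased flanks", {
  ref <- "AAAAACGGGGG"
  v <- variant_row("c", 6, "C", "G")
  prep <- prepare_het_sites(v, ref)
  s <- prep$sites
  expect_equal(s$ref_context, "AAAAACGGGGG")
  expect_equal(s$alt_context, "AAAAAGGGGGG")
})

test_that("phased neighbours appear in each other's flanking sequence", {
  ref <- paste0(synth_reference(50, seed = 71), "ACGTACGTACGT",
                synth_reference(50, seed = 72))
  # site at 55 with a phased neighbour SNV 3 bp to its left on the ALT hap
  site <- variant_row("c", 55, substr(ref, 55, 55), "A", gt = c(0L, 1L))
  if (site$alt == substr(ref, 55, 55)) site$alt <- "C"
  nb <- variant_row("c", 52, substr(ref, 52, 52), "T", gt = c(0L, 1L))
  if (nb$alt == substr(ref, 52, 52)) nb$alt <- "G"
  prep <- prepare_het_sites(rbind(nb, site), ref)
  s <- prep$sites[prep$sites$pos == 55, ]
  # ALT-hap flank carries the neighbour's ALT allele, REF-hap flank the REF base
  expect_equal(substr(s$alt_context, 3, 3), nb$alt)
  expect_equal(substr(s$ref_context, 3, 3), nb$ref)
})

test_that("insertion contexts have flank+allele lengths on each haplotype", {
  ref <- synth_reference(200, seed = 73)
  v <- variant_row("c", 100, substr(ref, 100, 100),
                   paste0(substr(ref, 100, 100), "TT"))
  prep <- prepare_het_sites(v, ref)
  s <- prep$sites
  if (!s$disregarded) {
    expect_equal(nchar(s$ref_context), 11L)  # 5 + 1 + 5
    expect_equal(nchar(s$alt_context), 13L)  # 5 + 3 + 5
  }
})

# independent oracle: smallest k such that appending k bases (from the two
# haplotypes) in the given direction breaks the prefix/suffix/substring
# relation between the contexts
min_extension_oracle <- function(rc, ac, hap_r, hap_a, rs_r, re_r, rs_a, re_a,
                                 dir, kmax = 200) {
  rel <- function(a, b) {
    s <- if (nchar(a) < nchar(b)) a else b
    l <- if (nchar(a) < nchar(b)) b else a
    nchar(a) == nchar(b) && a == b ||
      startsWith(l, s) || endsWith(l, s) || grepl(s, l, fixed = TRUE)
  }
  for (k in 0:kmax) {
    if (dir == "right") {
      rc2 <- substr(hap_r, rs_r, re_r + k)
      ac2 <- substr(hap_a, rs_a, re_a + k)
    } else {
      rc2 <- substr(hap_r, rs_r - k, re_r)
      ac2 <- substr(hap_a, rs_a - k, re_a)
    }
    if (!rel(rc2, ac2)) return(list(k = k, rc = rc2, ac = ac2))
  }
  NULL
}

test_that("a one-unit repeat deletion extends across the whole tract", {
  rr <- repeat_reference("ATTC", 7)
  v <- variant_row("chrR", rr$anchor_pos, "GATTC", "G")
  prep <- prepare_het_sites(v, rr$seq)
  s <- prep$sites
  expect_equal(s$extended_side, "right")
  expect_false(s$disregarded)
  # the extended context spans the whole repetitive region, through to the
  # terminator where the two haplotypes first differ
  expect_gt(s$ctx_ref_end, rr$tract_end)
  expect_gt(s$eff_end, s$end)
  # neither context is a prefix/suffix/substring of the other afterwards
  expect_equal(refbias:::context_relation(s$ref_context, s$alt_context), "none")
  # and the extension length matches the independent minimal-extension oracle
  h1 <- prep$haps[[1]]; h2 <- prep$haps[[2]]
  fl <- 5L
  or <- min_extension_oracle(
    substr(h1$seq, rr$anchor_pos - fl, rr$anchor_pos + 4L + fl), # flank+GATTC+flank
    substr(h2$seq, map_ref_to_hap(h2$map, rr$anchor_pos) - fl,
           map_ref_to_hap(h2$map, rr$anchor_pos) + fl),          # flank+G+flank
    h1$seq, h2$seq,
    rr$anchor_pos - fl, rr$anchor_pos + 4L + fl,
    map_ref_to_hap(h2$map, rr$anchor_pos) - fl,
    map_ref_to_hap(h2$map, rr$anchor_pos) + fl,
    "right")
  expect_equal(s$eff_end - s$end, or$k)
  expect_equal(s$ref_context, or$rc)
  expect_equal(s$alt_context, or$ac)
})

test_that("substring contexts extend on the side with the shorter extension", {
  # deletion spanning the junction of two homopolymer runs: the ALT context
  # is an interior substring of the REF context, so both extension
  # directions can resolve it and the shorter one must be chosen
  junction_site <- function(n_a, n_g) {
    L <- synth_reference(200, seed = 81); R <- synth_reference(200, seed = 82)
    ref <- paste0(L, strrep("A", n_a), strrep("G", n_g), R)
    pos <- nchar(L) + n_a - 1L      # anchor A; REF "AAG" deletes A+G
    v <- variant_row("c", pos, substr(ref, pos, pos + 2), substr(ref, pos, pos))
    prep <- prepare_het_sites(v, ref)
    list(prep = prep, pos = pos)
  }
  for (cfg in list(list(n_a = 8, n_g = 14, side = "left"),
                   list(n_a = 14, n_g = 8, side = "right"))) {
    js <- junction_site(cfg$n_a, cfg$n_g)
    s <- js$prep$sites
    expect_false(s$disregarded)
    expect_equal(s$extended_side, cfg$side)
    expect_equal(refbias:::context_relation(s$ref_context, s$alt_context),
                 "none")
    # the chosen extension is the minimal one per the independent oracle
    h1s <- js$prep$haps[[1]]$seq; h2s <- js$prep$haps[[2]]$seq
    fl <- 5L; pos <- js$pos
    hp2 <- map_ref_to_hap(js$prep$haps[[2]]$map, pos)
    oR <- min_extension_oracle(NULL, NULL, h1s, h2s, pos - fl, pos + 2L + fl,
                               hp2 - fl, hp2 + fl, "right")
    oL <- min_extension_oracle(NULL, NULL, h1s, h2s, pos - fl, pos + 2L + fl,
                               hp2 - fl, hp2 + fl, "left")
    expect_equal(s$extended_side, if (oL$k <= oR$k) "left" else "right")
    expect_equal(max(s$pos - s$eff_start, s$eff_end - s$end), min(oL$k, oR$k))
  }
})

test_that("fully periodic mid-tract deletions are disregarded as unresolvable", {
  # a non-left-aligned deletion deep inside a tandem repeat keeps one
  # context a prefix (and the other a suffix) of the other under any
  # single-side extension; the site must be flagged rather than mis-scored
  L <- synth_reference(200, seed = 74)
  ref <- paste0(L, strrep("AT", 12), synth_reference(200, seed = 75))
  pos <- nchar(L) + 7L
  v <- variant_row("c", pos, substr(ref, pos, pos + 2), substr(ref, pos, pos))
  s <- prepare_het_sites(v, ref)$sites
  expect_true(s$disregarded)
})

test_that("effective variants beyond the length limit are disregarded", {
  # one-unit deletions in long tracts: the effective span grows with the
  # tract; a 73 bp span is disregarded, a 69 bp one kept
  rr <- repeat_reference("ATTC", 19)
  v <- variant_row("chrR", rr$anchor_pos, "GATTC", "G")
  s19 <- prepare_het_sites(v, rr$seq)$sites
  expect_true(s19$disregarded)
  expect_gt(s19$eff_len, 70L)

  rr2 <- repeat_reference("ATTC", 18)
  v2 <- variant_row("chrR", rr2$anchor_pos, "GATTC", "G")
  s18 <- prepare_het_sites(v2, rr2$seq)$sites
  expect_false(s18$disregarded)
  expect_lte(s18$eff_len, 70L)

  # an AT tract of 37 units puts the effective span at exactly 71 bp,
  # one past the limit
  rr3 <- repeat_reference("AT", 37)
  v3 <- variant_row("chrR", rr3$anchor_pos, "GAT", "G")
  s37 <- prepare_het_sites(v3, rr3$seq)$sites
  expect_equal(s37$eff_len, 71L)
  expect_true(s37$disregarded)
})

test_that("cohorts chain transitively within the clustering distance", {
  ref <- synth_reference(1000, seed = 76)
  mkv <- function(pos) {
    r <- substr(ref, pos, pos)
    variant_row("c", pos, r, setdiff(c("A", "C", "G", "T"), r)[1])
  }
  # gaps of 10 and 20 chain into one cohort of three
  v <- rbind(mkv(100), mkv(110), mkv(130), mkv(400), mkv(500))
  prep <- prepare_het_sites(v, ref)
  s <- prep$sites
  expect_equal(sum(!is.na(s$cohort_id)), 3L)
  expect_length(unique(na.omit(s$cohort_id)), 1L)
  expect_equal(prep$cohorts$n_members, 3L)
  # 400 and 500 are singletons (no cohort id)
  expect_true(all(is.na(s$cohort_id[s$pos %in% c(400, 500)])))
})

test_that("cohort strings reproduce the consensus haplotype substrings", {
  ref <- synth_reference(600, seed = 77)
  p1 <- 300L; p2 <- 310L
  r1 <- substr(ref, p1, p1)
  v1 <- variant_row("c", p1, r1, setdiff(c("A", "C", "G", "T"), r1)[1],
                    gt = c(0L, 1L))
  v2 <- variant_row("c", p2, substr(ref, p2, p2),
                    paste0(substr(ref, p2, p2), "GG"), gt = c(0L, 1L))
  prep <- prepare_het_sites(rbind(v1, v2), ref)
  co <- prep$cohorts
  expect_equal(nrow(co), 1L)
  for (h in 1:2) {
    hp_a <- map_ref_to_hap(prep$haps[[h]]$map, co$start - 5L)
    hp_b <- map_ref_to_hap(prep$haps[[h]]$map, co$end + 5L)
    expect_equal(co[[paste0("hap", h, "_string")]],
                 substr(prep$haps[[h]]$seq, hp_a, hp_b))
  }
  # the hap2 string contains both phased ALT alleles
  expect_true(grepl(v1$alt, co$hap2_string, fixed = TRUE))
  expect_true(grepl("GG", co$hap2_string, fixed = TRUE))
  expect_false(grepl(paste0(r1), substr(co$hap1_string, 6, 6), fixed = TRUE) == FALSE)
})

test_that("extension leaves no prefix/suffix/substring relation (property)", {
  set.seed(99)
  for (trial in 1:20) {
    unit <- paste(sample(c("A", "C", "G", "T"), sample(2:5, 1), replace = TRUE),
                  collapse = "")
    n <- sample(3:8, 1)
    rr <- repeat_reference(unit, n, left_seed = trial, right_seed = trial + 50)
    v <- variant_row("chrR", rr$anchor_pos,
                     paste0("G", strrep(unit, 1)), "G")
    s <- prepare_het_sites(v, rr$seq)$sites
    if (!s$disregarded) {
      expect_equal(refbias:::context_relation(s$ref_context, s$alt_context),
                   "none", info = paste("unit", unit, "n", n))
    }
  }
})
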