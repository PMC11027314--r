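---
title: "Measuring and diagnosing reference bias with refbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and diagnosing reference bias with refbias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refbias)
```

## The problem

Read aligners tend to miss or misplace reads carrying non-reference
alleles. At a heterozygous (HET) site of a diploid donor this *reference
bias* shows up as an excess of REF-supporting over ALT-supporting reads,
which confounds allele-specific analyses and the evaluation of
variant-aware (pangenome) aligners. `refbias` measures this bias per site,
attributes individual bias events to their cause, ranks likely-biased sites
on real data, and scans pileups for biased regions when the donor's
variants are unknown.

## Three levels of allelic balance

All three measures are REF fractions at a HET site; plots that follow the
field convention put ALT in the numerator (`1 - balance`).

* **Simulation balance (SB)** — among reads that *truly originated*
  overlapping the site (truth tags from the simulator), the fraction from
  the REF-carrying haplotype. The pre-alignment baseline.
* **Mapping balance (MB)** — the same fraction restricted to reads that
  both originated *and aligned* overlapping the site. Reads lost by the
  aligner move MB away from SB; mismapped (foreign) reads are excluded.
* **Assignment balance (AB)** — `n_REF / (n_REF + n_ALT)` after per-read
  allele assignment. AB needs no truth information, so it is the only
  measure available on real reads. Reads assigned BOTH or OTHER are
  excluded.

With no loss and perfect assignment, SB = MB = AB exactly — the package's
end-to-end null test asserts this identity on an error-free synthetic run.

## Categorizing bias events

Let NMB = MB − SB and NAB = AB − SB. Each site is a point on the NMB–NAB
plane and the categories are regions of that plane
(see `categorize_site()`):

| category | region | interpretation |
|---|---|---|
| balanced | distance from origin ≤ 0.1 | no meaningful bias |
| loss | diagonal wedge between slopes 2 and 1/2, NMB and NAB sharing sign | ALT (rarely REF) reads failed to align |
| flux | remaining \|NAB\| > 0.1, more than 5 mismapped reads | evidence imported from elsewhere |
| local | remaining \|NAB\| > 0.1, ≤ 5 mismapped reads | assignment confused locally (gaps, repeats, errors) |
| outlier | everything else | mixtures of causes |

Boundaries resolve toward the earlier rule (circle, then wedge), making the
classification a deterministic partition; a 41×41×2 grid is checked against
an independently written region-membership oracle in the test suite. One
published description states the flux/local region as `|NMB| > 0.1`, which
contradicts the accompanying prose and the visibly *vertical* flux/local
clusters; the package adopts `|NAB| > 0.1` and exposes the other reading
via `classifier_config(blue_axis = "NMB")`. The mismap rule is strict
(*more than* 5), and counts reads overlapping the site whose truth interval
lies elsewhere.

## Context-aware assignment

The naive method trusts the aligner: it reads the bases placed at the
variant's exact reference coordinates and requires an exact allele match —
anything else is OTHER. Gap-placement ambiguity in tandem repeats therefore
corrupts it: a score-equivalent gap shift makes the footprint read as REF
(misattribution) or as neither allele (OTHER).

The context-aware method instead scans the *read sequence* for the two
**allelic context sequences** — each allele plus 5 bp of flanking sequence
drawn from the haplotype carrying it, so phased neighbours appear, phased
appropriately, in each other's flanks. Matching is exact (no mismatches
tolerated); a read matching exactly one context is assigned to it, both →
BOTH, neither → OTHER. Since contexts are plain strings, the aligner's gap
placement is irrelevant — the package's gap-shift robustness test moves
every movable gap to its rightmost score-equivalent placement and asserts
context tallies are unchanged while naive tallies degrade.

Details that matter:

* **Anchoring.** When the full context is absent (read ends mid-window, or
  an insertion is unanchored on one side), the expected window is anchored
  at the left context boundary via the alignment, then at the right
  boundary. A partial (prefix/suffix) match counts only if it reaches at
  least one base past the anchored-side flank into the effective allele;
  discrimination comes from testing both contexts — a window matching both
  (as inside a repeat tract) yields BOTH, never a call. Soft-clipped bases
  participate, so a read starting inside an insertion can still be rescued
  by its right anchor.
* **Cohorts.** Variants within 25 bp (end-to-start) chain transitively
  into a cohort; the combined per-haplotype strings over the cohort span
  (±5 bp) are searched first, and a read matched at cohort level is tallied
  for *all* member sites (as specified — including members the read does
  not physically overlap; the per-site evidence of rarely-covered members
  should be read with that in mind). Unmatched reads fall back to
  variant-by-variant assignment.
* **Effective variants.** In a tandem repeat one context can be a prefix,
  suffix or substring of the other, making short windows uninformative.
  The window is extended — rightward while a prefix relation holds,
  leftward while a suffix holds, each one base at a time on both
  haplotypes until the first difference breaks the relation. For the
  substring case (repeat content on both sides, e.g. a deletion spanning
  the junction of two homopolymer runs) both directions are tried and the
  shorter extension wins. The effective span is the longer effective
  allele (context minus both flanks); spans over 70 bp are disregarded.
  Reads that do not cover the whole effective variant are BOTH.
  A non-left-aligned deletion deep inside a periodic tract keeps one
  context a prefix (and the other a suffix) of the other under *any*
  single-side extension; such sites are flagged disregarded rather than
  mis-scored. Extension scans are bounded at the 70 bp limit plus context
  overhead so degenerate repeats (poly-A to a contig end) terminate.

## The synthetic-data generator

The simulator is deliberately simpler than a full Illumina error model; the
analyses need truth tags and an error knob, not sequencer realism.

* Two personalized haplotypes are built from the reference and phased
  variants (`build_consensus()`), with a piecewise coordinate map between
  haplotype and reference coordinates.
* Reads: 150 bp single-end by default, Poisson read counts at 15× per
  haplotype (≈30× total), uniform starts, i.i.d. substitutions at rate
  0.002, no indel errors and no quality model. Each haplotype has its own
  seed so the two coverage profiles are uncorrelated. Paired-end is
  available as a fixed-fragment option.
* The **oracle aligner** places every read at its true interval with the
  CIGAR implied by the coordinate map (insertions unanchored at a read end
  are soft-clipped) and MAPQ at the configured maximum. It isolates
  assignment and classification from aligner idiosyncrasies; it does not
  model strand (the whole framework is strand-agnostic) or mapping
  ambiguity.
* **Bias injection** realizes the three causes: *loss* removes each
  ALT-haplotype read over a target site with probability *f*; *flux* adds
  foreign reads (true origin displaced) carrying the local reference
  sequence at a chosen MAPQ; *gap_shift* re-places single gaps at their
  leftmost/rightmost score-equivalent position, leaving sequences intact.

Consequences for interpretation: passing tests show the measurement and
classification machinery is correct under controlled conditions; they do
not show robustness to real error profiles, strand effects, quality-biased
errors, or aligner-specific MAPQ landscapes.

With SB = 0.5 and loss fraction *f*, MB settles at 1/(2−f); the site exits
the balanced circle along the diagonal once 1/(2−f) − 0.5 > 0.1/√2, i.e.
*f* above ≈ 0.26 — so the loss-injection test asserts `loss` at *f* = 0.5
and 0.8 and `balanced` at *f* = 0.2, with per-site evidence of 200+ reads
to keep sampling noise far from the boundary.

## Predicting biased sites on real data

Without truth tags only AB and the mean MAPQ of overlapping reads are
available. Sites likely affected by incomplete phasing are removed first:
more than 90% OTHER reads, or one allele absent with more than 40% OTHER.
The two combined scores are

```
mul: (mean_MAPQ - q_max)/q_max * AB
add: (mean_MAPQ - q_max)/q_max * 1.5 + AB
```

with `q_max` = 42 (60 for aligners that score up to 60). Lower scores rank
as more likely biased; `flip = TRUE` reverses the orientation for ALT-skew
investigations. The 1.5 weight is exposed as configuration. Rankings are
evaluated with threshold-swept ROC and precision–recall curves
(trapezoidal areas; tied scores cross thresholds together), cross-checked
against an independent ROC implementation in the tests.

The two-feature model presumes that bias co-occurs with depressed MAPQ, as
it does in repeat-driven regions of real genomes. Under the oracle aligner
MAPQ is uniformly maximal, so the labelled synthetic fixture injects loss
*together with* MAPQ-0 foreign reads (about 60% of local depth — modest
next to the several-fold pileups of real collapsed duplications). With
foreign reads alone the additive score's two terms can cancel
arithmetically; that is a property of the printed equation, not of the
implementation.

## Scan mode

Scan mode needs no variant calls. Per pileup column, any nucleotide above
15% of counted bases is an allele (strict inequality; N and ambiguity
codes are excluded from the denominator); two or more alleles make an SNV
column; a column is non-diploid if more than two alleles are present or if
the top allele exceeds twice the second (strict; the rule applies only
when at least two alleles pass the threshold, since a pure homozygous
column carries no non-diploid evidence). Deletion placeholders count
toward depth but not base counts.

Sliding 400 bp windows (stride 100 bp — a quarter window, balancing
boundary resolution against cost; region extents are unions of qualifying
windows) compute mean depth (RD) and the *fractions* of SNV (VD) and
non-diploid (ND) columns — fractions make the values depth- and
window-length-invariant. Each becomes a Z-score against a sampled
baseline, and

```
bias_score = trunc(z_RD, 1) + trunc(z_VD, 0) + trunc(z_ND, 0)
```

where `trunc(x, t)` zeroes values below `t`: only depth *excesses* beyond
one standard deviation count, and negative density scores are truncated.
Windows at or above 5 are biased, `[3, 5)` suspicious (the half-open
interval, so the labels partition); same-label regions within 1 kbp chain
into one. The baseline samples random *windows* covering ~1/1000 of the
input (a floor of 200 sampled windows keeps desk-scale fixtures stable;
genome-scale inputs are governed by the 1/1000 rule), with standard
deviations floored at a machine-epsilon scale so constant inputs give
Z = 0 rather than division by zero. Pre-computed moments can be supplied.

To compare two alignment workflows fairly, one *joint* baseline is drawn
half from each; a region biased in one workflow is *improved* by the other
when at least 25% of its bases are simultaneously well covered (depth
above one fifth of the overall mean) and outside the other's biased
regions, with near-zero-depth regions excluded from verdicts.

The null-calibration fixture takes "homogeneous coverage" literally:
constant depth, exact 50/50 HET columns jitter-spaced about every 1.2 kbp
(a HG002-like density), sequencing errors below the allele threshold. This
isolates the variant-density channel — the depth and non-diploidy channels
are exercised by the collapsed-duplication fixture, which doubles depth
over a 5 kbp segment and injects tri-allelic and dominance-skewed columns,
and must be recovered over at least 80% of the segment.

## Problem sizes and runtime choices

The acceptance workload is a 1 Mbp diploid fixture with 1,000 HET SNVs at
15× per haplotype (~200,000 reads) — large enough for the median ALT
fraction at SNV sites to be estimated to well under the ±0.02 band, small
enough to run in seconds. Unit fixtures use 20–150 kbp references; the
loss-analytics fixture uses 100× per haplotype so each site carries 200+
reads of evidence. These sizes are the package's chosen study conditions,
stated here so results are reproducible.

## Known limitations

* Biallelic variants only; multi-allelic records should be split upstream,
  and star alleles are not handled.
* The simulator has no quality model, no indel sequencing errors, and no
  strand; MAPQ comes from the oracle, so MAPQ-dependent behavior on real
  aligners is out of reach of the bundled fixtures.
* Cohort tallies follow the specified all-members rule, which can credit a
  site with reads that do not overlap it.
* The mpileup reader targets the common samtools/bcftools dialect and
  rejects nonconforming tokens rather than guessing.
* CRAM, tabix indexing, and VCF INFO/FORMAT semantics beyond GT and FILTER
  are out of scope.
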