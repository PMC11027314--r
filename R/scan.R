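# Variant-blind scanning of pileups for biased regions: per-column allele
# profiles, sliding-window read-depth (RD), variant-density (VD) and
# non-diploidy (ND) Z-scores, region calling with chaining, baseline
# sampling, and two-workflow comparison.

#' Scan configuration
#'
#' @param window_len sliding-window length (bp).
#' @param stride window stride (bp).
#' @param allele_freq_threshold a nucleotide above this frequency among
#'   counted bases is an allele.
#' @param dominance_ratio a two-or-more-allele column whose top allele is
#'   more than this many times the second is non-diploid.
#' @param biased_threshold combined score calling a window biased.
#' @param suspicious_threshold combined score calling a window suspicious
#'   (suspicious = `[suspicious, biased)`).
#' @param chain_distance same-label regions closer than this are chained.
#' @param sample_fraction fraction of the genome sampled (as windows) when
#'   estimating the baseline.
#' @param min_baseline_windows lower bound on sampled windows so small
#'   inputs still get stable moments (capped at what the input offers).
#' @return a `scan_config` list.
#' @export
scan_config <- function(window_len = 400L, stride = 100L,
                        allele_freq_threshold = 0.15, dominance_ratio = 2,
                        biased_threshold = 5, suspicious_threshold = 3,
                        chain_distance = 1000L, sample_fraction = 1 / 1000,
                        min_baseline_windows = 200L) {
  stopifnot(stride <= window_len, suspicious_threshold > 0,
            suspicious_threshold < biased_threshold,
            allele_freq_threshold > 0, allele_freq_threshold < 1)
  structure(list(window_len = as.integer(window_len),
                 stride = as.integer(stride),
                 allele_freq_threshold = allele_freq_threshold,
                 dominance_ratio = dominance_ratio,
                 biased_threshold = biased_threshold,
                 suspicious_threshold = suspicious_threshold,
                 chain_distance = as.integer(chain_distance),
                 sample_fraction = sample_fraction,
                 min_baseline_windows = as.integer(min_baseline_windows)),
            class = "scan_config")
}

#' Per-column allele profile
#'
#' A nucleotide with frequency above the 15% threshold among counted bases
#' is an allele. Columns with at least two alleles are SNV columns. A column
#' is non-diploid when more than two alleles are present, or when (with at
#' least two alleles) the top allele's frequency is more than
#' `dominance_ratio` times the second's — a single-allele column carries no
#' non-diploid evidence. Zero-coverage columns get no alleles and both flags
#' FALSE.
#'
#' @param pileup pileup data.frame (see [pileup_from_alignments()]).
#' @param config a [scan_config()].
#' @return `pileup` with added columns `n_alleles`, `is_snv`,
#'   `is_nondiploid`.
#' @export
profile_pileup <- function(pileup, config = scan_config()) {
  m <- as.matrix(pileup[, c("A", "C", "G", "T")])
  tot <- rowSums(m)
  freq <- m / pmax(tot, 1L)
  is_allele <- freq > config$allele_freq_threshold & tot > 0L
  n_alleles <- rowSums(is_allele)
  # top and second allele counts (vectorized; ties give second == top)
  x <- m * is_allele
  top <- pmax(x[, 1], x[, 2], x[, 3], x[, 4])
  first_max <- max.col(x, ties.method = "first")
  x[cbind(seq_len(nrow(x)), first_max)] <- -1L
  second <- pmax(x[, 1], x[, 2], x[, 3], x[, 4])
  pileup$n_alleles <- as.integer(n_alleles)
  pileup$is_snv <- n_alleles >= 2L
  pileup$is_nondiploid <- n_alleles > 2L |
    (n_alleles >= 2L & top > config$dominance_ratio * second)
  pileup
}

# RD/VD/ND means for windows starting at `starts` (cumulative sums, O(1) per
# window)
window_raw_values <- function(profile, starts, config) {
  w <- config$window_len
  cs_d <- c(0, cumsum(profile$depth))
  cs_v <- c(0, cumsum(as.integer(profile$is_snv)))
  cs_n <- c(0, cumsum(as.integer(profile$is_nondiploid)))
  npos <- nrow(profile)
  ends <- pmin(starts + w - 1L, npos)
  len <- ends - starts + 1L
  data.frame(
    start = profile$pos[starts], end = profile$pos[ends],
    truncated = ends - starts + 1L < w,
    RD = (cs_d[ends + 1L] - cs_d[starts]) / len,
    VD = (cs_v[ends + 1L] - cs_v[starts]) / len,
    ND = (cs_n[ends + 1L] - cs_n[starts]) / len)
}

#' Estimate the RD/VD/ND baseline by window sampling
#'
#' Samples random windows covering roughly `sample_fraction` of the input
#' (at least `min_baseline_windows` where the input allows) and records the
#' mean and standard deviation of the three window measures. With two pileup
#' sources (two alignment workflows) half the sample is drawn from each, so
#' both workflows are scored against one joint baseline. Standard deviations
#' are floored at a machine-epsilon scale so degenerate (constant) inputs
#' yield Z-scores of 0 rather than divisions by zero. Pre-computed moments
#' can be supplied to skip sampling.
#'
#' @param profiles a profiled pileup data.frame, or a list of one or two.
#' @param config a [scan_config()].
#' @param seed RNG seed for window sampling.
#' @param means,sds optional named vectors (`RD`, `VD`, `ND`) of
#'   user-supplied moments; both given = no sampling.
#' @return a `scan_baseline` list: `means`, `sds`, `provenance`, `n_windows`.
#' @export
estimate_baseline <- function(profiles, config = scan_config(), seed = 1L,
                              means = NULL, sds = NULL) {
  if (!is.null(means) && !is.null(sds)) {
    return(structure(list(means = means[c("RD", "VD", "ND")],
                          sds = floor_sds(sds[c("RD", "VD", "ND")],
                                          means[c("RD", "VD", "ND")]),
                          provenance = "user-supplied", n_windows = NA_integer_),
                     class = "scan_baseline"))
  }
  if (is.data.frame(profiles)) profiles <- list(profiles)
  stopifnot(length(profiles) %in% c(1L, 2L))
  set.seed(seed)
  vals <- vector("list", length(profiles))
  for (j in seq_along(profiles)) {
    p <- profiles[[j]]
    npos <- nrow(p)
    if (npos < config$window_len) stop("pileup shorter than one window")
    max_start <- npos - config$window_len + 1L
    want <- max(config$min_baseline_windows,
                ceiling(npos * config$sample_fraction / config$window_len))
    want <- ceiling(want / length(profiles))
    want <- min(want, max_start)
    if (want < 1L) stop("no windows available for baseline sampling")
    starts <- sample.int(max_start, want, replace = max_start < want)
    vals[[j]] <- window_raw_values(p, sort(starts), config)
  }
  v <- do.call(rbind, vals)
  means <- c(RD = mean(v$RD), VD = mean(v$VD), ND = mean(v$ND))
  sds <- c(RD = sd(v$RD), VD = sd(v$VD), ND = sd(v$ND))
  structure(list(means = means, sds = floor_sds(sds, means),
                 provenance = if (length(profiles) == 2L) "joint-sampled" else "sampled",
                 n_windows = nrow(v)),
            class = "scan_baseline")
}

floor_sds <- function(sds, means) {
  eps <- sqrt(.Machine$double.eps)
  pmax(sds, eps * pmax(abs(means), 1), na.rm = TRUE)
}

trunc_z <- function(z, t) ifelse(z >= t, z, 0)

#' Sliding-window bias scores
#'
#' For each window: RD = mean depth, VD = fraction of SNV columns, ND =
#' fraction of non-diploid columns; each is turned into a Z-score against
#' the sampled baseline, and the combined score is
#' `trunc(z_RD, 1) + trunc(z_VD, 0) + trunc(z_ND, 0)` where `trunc(x, t)`
#' zeroes values below `t` — only depth *excesses* beyond one standard
#' deviation count, and negative density Z-scores are truncated to 0.
#'
#' @param profile profiled pileup (contiguous, sorted positions).
#' @param baseline a `scan_baseline`.
#' @param config a [scan_config()].
#' @return data.frame of windows: `start`, `end`, `truncated`, `RD`, `VD`,
#'   `ND`, `z_rd`, `z_vd`, `z_nd`, `bias_score`.
#' @export
window_scores <- function(profile, baseline, config = scan_config()) {
  stopifnot(inherits(baseline, "scan_baseline"))
  npos <- nrow(profile)
  if (npos < 1L) stop("empty profile")
  starts <- seq.int(1L, max(npos - config$window_len + 1L, 1L),
                    by = config$stride)
  # keep one (flagged) truncated final window if the stride overshoots
  if (npos >= config$window_len &&
      utils::tail(starts, 1L) + config$window_len - 1L < npos) {
    starts <- c(starts, npos - config$window_len + 1L)
  }
  w <- window_raw_values(profile, starts, config)
  w$z_rd <- (w$RD - baseline$means["RD"]) / baseline$sds["RD"]
  w$z_vd <- (w$VD - baseline$means["VD"]) / baseline$sds["VD"]
  w$z_nd <- (w$ND - baseline$means["ND"]) / baseline$sds["ND"]
  w$bias_score <- trunc_z(w$z_rd, 1) + trunc_z(w$z_vd, 0) + trunc_z(w$z_nd, 0)
  rownames(w) <- NULL
  w
}

#' Call biased and suspicious regions from scored windows
#'
#' Windows with combined score at or above the biased threshold are biased;
#' windows in `[suspicious, biased)` are suspicious. Overlapping or adjacent
#' qualifying windows of the same label merge, and same-label regions within
#' `chain_distance` chain into one. The region score is the maximum window
#' score.
#'
#' @param windows output of [window_scores()].
#' @param config a [scan_config()].
#' @param chrom chromosome name for the output.
#' @return data.frame of regions: `chrom`, `start`, `end`, `label`, `score`.
#' @export
call_regions <- function(windows, config = scan_config(), chrom = "ref") {
  lab <- ifelse(windows$bias_score >= config$biased_threshold, "biased",
                ifelse(windows$bias_score >= config$suspicious_threshold,
                       "suspicious", "none"))
  out <- list()
  for (lb in c("biased", "suspicious")) {
    idx <- which(lab == lb)
    if (!length(idx)) next
    st <- windows$start[idx]; en <- windows$end[idx]; sc <- windows$bias_score[idx]
    ord <- order(st)
    st <- st[ord]; en <- en[ord]; sc <- sc[ord]
    merged <- data.frame(start = st[1], end = en[1], score = sc[1])
    for (i in seq_along(st)[-1]) {
      k <- nrow(merged)
      if (st[i] - merged$end[k] <= config$chain_distance) {
        merged$end[k] <- max(merged$end[k], en[i])
        merged$score[k] <- max(merged$score[k], sc[i])
      } else {
        merged <- rbind(merged, data.frame(start = st[i], end = en[i],
                                           score = sc[i]))
      }
    }
    merged$label <- lb
    out[[lb]] <- merged
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), label = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  res <- data.frame(chrom = chrom, res[order(res$start),
                                       c("start", "end", "label", "score")],
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Scan a pileup for biased regions
#'
#' Profile, score and call in one step; the baseline is estimated from the
#' pileup itself unless supplied.
#'
#' @param pileup pileup data.frame.
#' @param config a [scan_config()].
#' @param baseline optional `scan_baseline`.
#' @param seed seed for baseline sampling.
#' @return list with `profile`, `baseline`, `windows`, `regions`.
#' @export
scan_pileup <- function(pileup, config = scan_config(), baseline = NULL,
                        seed = 1L) {
  profile <- profile_pileup(pileup, config)
  if (is.null(baseline)) {
    baseline <- estimate_baseline(profile, config, seed = seed)
  }
  windows <- window_scores(profile, baseline, config)
  regions <- call_regions(windows, config, chrom = pileup$chrom[1])
  list(profile = profile, baseline = baseline, windows = windows,
       regions = regions)
}

#' Compare biased regions between two alignment workflows
#'
#' Both workflows must have been scanned against the same joint baseline. A
#' region called biased in workflow A is "improved" by workflow B when at
#' least 25% of its bases are, in B, simultaneously well covered (depth
#' above one fifth of B's overall mean depth) and outside B's biased
#' regions. Regions with essentially no coverage in B are excluded from the
#' verdicts.
#'
#' @param regions_a biased/suspicious regions of workflow A (only `biased`
#'   rows are judged).
#' @param regions_b regions of workflow B.
#' @param depth_b integer vector of per-position depth in workflow B
#'   (position i = coordinate i).
#' @param mean_depth_b overall mean read depth of workflow B.
#' @param config a [scan_config()].
#' @param improved_frac fraction of qualifying bases required.
#' @param low_depth_frac regions whose mean depth in B falls below this
#'   fraction of `mean_depth_b` are excluded.
#' @return `regions_a` (biased rows) with `frac_improved` and `verdict`
#'   (`improved` / `unimproved` / `excluded_low_depth`).
#' @export
compare_workflows <- function(regions_a, regions_b, depth_b, mean_depth_b,
                              config = scan_config(), improved_frac = 0.25,
                              low_depth_frac = 0.05) {
  ra <- regions_a[regions_a$label == "biased", , drop = FALSE]
  if (!nrow(ra)) {
    ra$frac_improved <- numeric(0); ra$verdict <- character(0)
    return(ra)
  }
  rb <- regions_b[regions_b$label == "biased", , drop = FALSE]
  biased_b <- logical(length(depth_b))
  for (i in seq_len(nrow(rb))) {
    biased_b[max(1L, rb$start[i]):min(length(depth_b), rb$end[i])] <- TRUE
  }
  ra$frac_improved <- NA_real_
  ra$verdict <- NA_character_
  for (i in seq_len(nrow(ra))) {
    span <- ra$start[i]:min(ra$end[i], length(depth_b))
    d <- depth_b[span]
    if (mean(d) < low_depth_frac * mean_depth_b) {
      ra$verdict[i] <- "excluded_low_depth"
      next
    }
    good <- d > mean_depth_b / 5 & !biased_b[span]
    ra$frac_improved[i] <- mean(good)
    ra$verdict[i] <- if (mean(good) >= improved_frac) "improved" else "unimproved"
  }
  rownames(ra) <- NULL
  ra
}
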