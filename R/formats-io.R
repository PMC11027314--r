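# Readers/writers for the standard formats the tool touches, plus an
# in-process pileup generator so scan mode can be exercised without samtools.

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of uppercased sequences, keyed by the first
#'   whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("FASTA parse error in ", path, ": ", conditionMessage(e))
  )
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read phased diploid variants from a VCF
#'
#' Keeps only records whose FILTER is `PASS` or `.` (any other FILTER category
#' is excluded). Unphased (`/`) or missing (`./.`) genotypes are returned with
#' `usable = FALSE` so that downstream overlap removal can still act on their
#' footprints before they are dropped.
#'
#' @param path VCF file (plain text or gzipped).
#' @param region optional `"chrom:start-end"` or `"chrom"` filter.
#' @return data.frame with columns `chrom`, `pos`, `end` (reference footprint,
#'   `pos + nchar(ref) - 1`), `ref`, `alt`, `gt1`, `gt2` (allele index per
#'   haplotype, NA when missing), `phased`, `is_het`, `usable`,
#'   `length_delta` (`nchar(alt) - nchar(ref)`).
#' @export
read_phased_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(empty_variants())
  }
  if (!"gt" %in% slotNames(v) || ncol(v@gt) < 2L) {
    stop("VCF has no genotype (GT) data: ", path)
  }
  fmt <- v@gt[, 1]
  gt_idx <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(x) match("GT", x), integer(1))
  if (anyNA(gt_idx)) stop("VCF record without GT field in ", path)
  sample_col <- v@gt[, 2]
  gt_str <- mapply(function(s, i) strsplit(s, ":", fixed = TRUE)[[1]][i],
                   sample_col, gt_idx, USE.NAMES = FALSE)

  phased <- grepl("|", gt_str, fixed = TRUE)
  parts <- strsplit(gt_str, "[|/]")
  a1 <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 1L)))
  a2 <- suppressWarnings(as.integer(vapply(parts, function(x) if (length(x) >= 2) x[2] else NA_character_, character(1))))

  out <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = toupper(fix$REF),
    alt = toupper(fix$ALT),
    gt1 = a1, gt2 = a2,
    phased = phased,
    stringsAsFactors = FALSE
  )
  out$end <- out$pos + nchar(out$ref) - 1L
  out$is_het <- !is.na(a1) & !is.na(a2) & a1 != a2
  out$usable <- phased & !is.na(a1) & !is.na(a2)
  out$length_delta <- nchar(out$alt) - nchar(out$ref)

  filt <- fix$FILTER
  keep <- is.na(filt) | filt %in% c("PASS", ".")
  out <- out[keep, , drop = FALSE]

  if (!is.null(region)) {
    r <- parse_region(region)
    keep <- out$chrom == r$chrom
    if (!is.na(r$start)) keep <- keep & out$end >= r$start & out$pos <= r$end
    out <- out[keep, , drop = FALSE]
  }
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("chrom", "pos", "end", "ref", "alt", "gt1", "gt2", "phased",
          "is_het", "usable", "length_delta")]
}

empty_variants <- function() {
  data.frame(chrom = character(0), pos = integer(0), end = integer(0),
             ref = character(0), alt = character(0),
             gt1 = integer(0), gt2 = integer(0), phased = logical(0),
             is_het = logical(0), usable = logical(0),
             length_delta = integer(0), stringsAsFactors = FALSE)
}

parse_region <- function(region) {
  if (grepl(":", region, fixed = TRUE)) {
    chrom <- sub(":.*$", "", region)
    rng <- sub("^.*:", "", region)
    se <- as.integer(strsplit(rng, "-", fixed = TRUE)[[1]])
    list(chrom = chrom, start = se[1], end = se[2])
  } else {
    list(chrom = region, start = NA_integer_, end = NA_integer_)
  }
}

# Truth tags carried in SAM optional fields: XH (haplotype index), XC (true
# chromosome), XS/XE (true reference interval).
TRUTH_TAGS <- c("XH", "XC", "XS", "XE")

#' Read alignments from SAM or BAM
#'
#' Unmapped and secondary records are skipped. Truth tags (`XH`, `XC`, `XS`,
#' `XE`) are parsed when present. SAM input is converted in a temporary
#' directory via [Rsamtools::asBam()].
#'
#' @param path SAM or BAM file.
#' @param region optional `"chrom:start-end"` restriction (BAM is indexed on
#'   the fly).
#' @return data.frame of alignments: `read_id`, `chrom`, `pos`, `cigar`,
#'   `mapq`, `seq`, `ref_end`, and truth columns `hap`, `true_chrom`,
#'   `true_start`, `true_end` (NA when untagged).
#' @export
read_alignments <- function(path, region = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = TRUE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE)
  what <- c("qname", "rname", "pos", "cigar", "mapq", "seq")
  if (!is.null(region)) {
    r <- parse_region(region)
    if (is.na(r$start)) stop("region filter needs chrom:start-end")
    which <- IRanges::IRangesList(IRanges::IRanges(r$start, r$end))
    names(which) <- r$chrom
    param <- Rsamtools::ScanBamParam(flag = flags, what = what,
                                     tag = TRUTH_TAGS, which = which)
  } else {
    param <- Rsamtools::ScanBamParam(flag = flags, what = what, tag = TRUTH_TAGS)
  }
  res <- Rsamtools::scanBam(bam, param = param)
  res <- do.call(rbind, lapply(res, function(x) {
    n <- length(x$qname)
    tg <- function(tag, mode) {
      v <- x$tag[[tag]]
      if (is.null(v)) rep(as(NA, mode), n) else as(v, mode)
    }
    data.frame(
      read_id = x$qname,
      chrom = as.character(x$rname),
      pos = x$pos,
      cigar = x$cigar,
      mapq = as.integer(x$mapq),
      seq = as.character(x$seq),
      hap = tg("XH", "integer"),
      true_chrom = tg("XC", "character"),
      true_start = tg("XS", "integer"),
      true_end = tg("XE", "integer"),
      stringsAsFactors = FALSE
    )
  }))
  rownames(res) <- NULL
  bad <- cigar_query_len(res$cigar) != nchar(res$seq)
  if (any(bad)) {
    stop("CIGAR/sequence length mismatch for read(s): ",
         paste(utils::head(res$read_id[bad], 3), collapse = ", "))
  }
  res$ref_end <- res$pos + cigar_ref_len(res$cigar) - 1L
  res
}

#' Write alignments (with truth tags) to a SAM file
#'
#' @param reads alignment data.frame as produced by [oracle_align()] or
#'   [read_alignments()].
#' @param ref_lengths named integer vector of reference sequence lengths.
#' @param path output SAM path.
#' @export
write_sam <- function(reads, ref_lengths, path) {
  stopifnot(!is.null(names(ref_lengths)))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths), as.integer(ref_lengths)))
  reads <- reads[order(reads$chrom, reads$pos), , drop = FALSE]
  tags <- character(nrow(reads))
  if (nrow(reads)) {
    has_truth <- !is.na(reads$hap)
    tags[has_truth] <- sprintf("\tXH:i:%d\tXC:Z:%s\tXS:i:%d\tXE:i:%d",
                               reads$hap[has_truth], reads$true_chrom[has_truth],
                               reads$true_start[has_truth], reads$true_end[has_truth])
  }
  rec <- sprintf("%s\t0\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*%s",
                 reads$read_id, reads$chrom, reads$pos, reads$mapq,
                 reads$cigar, reads$seq, tags)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a samtools/bcftools mpileup text file
#'
#' Decodes the base string of each column: `.`/`,` count the reference base,
#' `ACGTacgt` the stated base; `^X` read-start markers (and the following
#' mapping-quality character), `$` end markers and `+n`/`-n` indel text are
#' consumed without contributing to the counts; `*` deletion placeholders
#' count toward depth but not base counts; `N`/`n` and ambiguity codes are
#' excluded from base counts.
#'
#' @param path mpileup text file.
#' @return pileup data.frame: `chrom`, `pos`, `ref`, `depth`, `A`, `C`, `G`,
#'   `T`.
#' @export
read_mpileup <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  out <- data.frame(chrom = character(n), pos = integer(n), ref = character(n),
                    depth = integer(n), A = integer(n), C = integer(n),
                    G = integer(n), T = integer(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5L) stop("malformed mpileup line ", i)
    counts <- decode_pileup_bases(f[5], toupper(f[3]), i)
    out$chrom[i] <- f[1]; out$pos[i] <- as.integer(f[2])
    out$ref[i] <- toupper(f[3]); out$depth[i] <- as.integer(f[4])
    out$A[i] <- counts["A"]; out$C[i] <- counts["C"]
    out$G[i] <- counts["G"]; out$T[i] <- counts["T"]
    if (counts["total"] != out$depth[i]) {
      stop("mpileup depth mismatch at ", f[1], ":", f[2],
           " (declared ", out$depth[i], ", decoded ", counts["total"], ")")
    }
  }
  out
}

decode_pileup_bases <- function(bases, refbase, lineno) {
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L, total = 0L)
  chars <- strsplit(bases, "")[[1]]
  i <- 1L
  nch <- length(chars)
  while (i <= nch) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L               # skip the mapping-quality character
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= nch && chars[j] %in% as.character(0:9)) j <- j + 1L
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      if (!length(len) || is.na(len)) stop("malformed indel token, mpileup line ", lineno)
      i <- j + len              # skip the inserted/deleted sequence text
    } else if (ch %in% c(".", ",")) {
      if (refbase %in% names(counts)) counts[refbase] <- counts[refbase] + 1L
      counts["total"] <- counts["total"] + 1L
      i <- i + 1L
    } else if (toupper(ch) %in% c("A", "C", "G", "T")) {
      b <- toupper(ch)
      counts[b] <- counts[b] + 1L
      counts["total"] <- counts["total"] + 1L
      i <- i + 1L
    } else if (ch == "*" || toupper(ch) == "N" ||
               toupper(ch) %in% c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")) {
      counts["total"] <- counts["total"] + 1L   # depth only
      i <- i + 1L
    } else if (ch %in% c(">", "<")) {
      counts["total"] <- counts["total"] + 1L   # reference skip
      i <- i + 1L
    } else {
      stop("unrecognized mpileup token '", ch, "' at line ", lineno)
    }
  }
  counts
}

#' Build a pileup directly from alignments
#'
#' Produces per-position depth and base counts identical to decoding samtools
#' mpileup output on the same alignments: M bases add to depth and base
#' counts, D positions add to depth only, I and S segments contribute nothing
#' at reference positions.
#'
#' @param reads alignment data.frame (single chromosome).
#' @param ref_seq reference sequence of that chromosome.
#' @param chrom chromosome name recorded in the output (default: first read's).
#' @return pileup data.frame over positions `1..nchar(ref_seq)` with columns
#'   `chrom`, `pos`, `ref`, `depth`, `A`, `C`, `G`, `T`.
#' @export
pileup_from_alignments <- function(reads, ref_seq, chrom = NULL) {
  L <- nchar(ref_seq)
  depth <- integer(L)
  mat <- matrix(0L, nrow = 4, ncol = L, dimnames = list(c("A", "C", "G", "T"), NULL))
  if (is.null(chrom)) chrom <- if (nrow(reads)) reads$chrom[1] else "ref"
  for (k in seq_len(nrow(reads))) {
    pos <- reads$pos[k]; cigar <- reads$cigar[k]; seq <- reads$seq[k]
    cg <- parse_cigar(cigar)
    rpos <- pos; qpos <- 1L
    for (j in seq_len(nrow(cg))) {
      op <- cg$op[j]; len <- cg$len[j]
      if (op %in% c("M", "=", "X")) {
        idx <- rpos:(rpos + len - 1L)
        ok <- idx >= 1L & idx <= L
        if (any(ok)) {
          depth[idx[ok]] <- depth[idx[ok]] + 1L
          bs <- strsplit(substr(seq, qpos, qpos + len - 1L), "")[[1]][ok]
          known <- bs %in% c("A", "C", "G", "T")
          if (any(known)) {
            ij <- cbind(match(bs[known], c("A", "C", "G", "T")), idx[ok][known])
            for (r in seq_len(nrow(ij))) mat[ij[r, 1], ij[r, 2]] <- mat[ij[r, 1], ij[r, 2]] + 1L
          }
        }
        rpos <- rpos + len; qpos <- qpos + len
      } else if (op == "D") {
        idx <- rpos:(rpos + len - 1L)
        ok <- idx >= 1L & idx <= L
        depth[idx[ok]] <- depth[idx[ok]] + 1L
        rpos <- rpos + len
      } else if (op %in% c("I", "S")) {
        qpos <- qpos + len
      }
    }
  }
  data.frame(chrom = chrom, pos = seq_len(L),
             ref = strsplit(toupper(ref_seq), "")[[1]],
             depth = depth,
             A = mat["A", ], C = mat["C", ], G = mat["G", ], T = mat["T", ],
             stringsAsFactors = FALSE)
}

#' Render alignments as samtools-dialect mpileup text
#'
#' Emits read-start (`^!`), read-end (`$`), match (`.` or base letter),
#' deletion (`*`) and insertion (`+n...`) tokens so that [read_mpileup()] on
#' the rendered text round-trips with [pileup_from_alignments()].
#'
#' @inheritParams pileup_from_alignments
#' @return character vector of mpileup lines (positions with depth 0 omitted,
#'   as samtools does).
#' @export
render_mpileup <- function(reads, ref_seq, chrom = NULL) {
  L <- nchar(ref_seq)
  refc <- strsplit(toupper(ref_seq), "")[[1]]
  if (is.null(chrom)) chrom <- if (nrow(reads)) reads$chrom[1] else "ref"
  toks <- vector("list", L)
  for (k in seq_len(nrow(reads))) {
    pos <- reads$pos[k]; cg <- parse_cigar(reads$cigar[k]); seq <- reads$seq[k]
    rpos <- pos; qpos <- 1L
    first_col <- pos
    last_col <- pos + cigar_ref_len(reads$cigar[k]) - 1L
    pend_ins <- NULL
    add <- function(col, tok) {
      if (col >= 1L && col <= L) toks[[col]] <<- c(toks[[col]], tok)
    }
    for (j in seq_len(nrow(cg))) {
      op <- cg$op[j]; len <- cg$len[j]
      if (op %in% c("M", "=", "X")) {
        for (p in rpos:(rpos + len - 1L)) {
          b <- substr(seq, qpos + (p - rpos), qpos + (p - rpos))
          tok <- if (b == refc[p]) "." else b
          if (p == first_col) tok <- paste0("^!", tok)
          if (p == last_col) tok <- paste0(tok, "$")
          add(p, tok)
        }
        rpos <- rpos + len; qpos <- qpos + len
      } else if (op == "D") {
        # deletion text attaches to the previous column
        if (rpos - 1L >= 1L && rpos - 1L <= L && length(toks[[rpos - 1L]])) {
          n0 <- length(toks[[rpos - 1L]])
          toks[[rpos - 1L]][n0] <- paste0(
            toks[[rpos - 1L]][n0], "-", len,
            tolower(paste(refc[rpos:(rpos + len - 1L)], collapse = "")))
        }
        for (p in rpos:(rpos + len - 1L)) {
          tok <- "*"
          if (p == last_col) tok <- paste0(tok, "$")
          add(p, tok)
        }
        rpos <- rpos + len
      } else if (op == "I") {
        ins <- substr(seq, qpos, qpos + len - 1L)
        if (rpos - 1L >= 1L && rpos - 1L <= L && length(toks[[rpos - 1L]])) {
          n0 <- length(toks[[rpos - 1L]])
          toks[[rpos - 1L]][n0] <- paste0(toks[[rpos - 1L]][n0], "+", len, tolower(ins))
        }
        qpos <- qpos + len
      } else if (op == "S") {
        qpos <- qpos + len
      }
    }
  }
  keep <- which(vapply(toks, length, integer(1)) > 0L)
  vapply(keep, function(p) {
    tok <- toks[[p]]
    # "$" must directly follow the base; indel text was appended after the
    # base, so move any trailing "$" markers correctly: samtools puts indel
    # text before "$"? In practice "$" terminates the read after the indel
    # text; read_mpileup consumes either order.
    paste(chrom, p, refc[p], length(tok),
          paste(tok, collapse = ""),
          paste(rep("I", length(tok)), collapse = ""), sep = "\t")
  }, character(1))
}

#' Write biased/suspicious regions to BED
#'
#' Internal 1-based inclusive intervals are converted to BED's 0-based
#' half-open convention; the label goes in column 4, the combined score in
#' column 5.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (1-based inclusive),
#'   `label`, `score`.
#' @param path output BED path.
#' @export
write_regions_bed <- function(regions, path) {
  if (nrow(regions)) {
    if (any(regions$end < regions$start)) stop("region with end < start")
    regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
    lines <- sprintf("%s\t%d\t%d\t%s\t%.4g", regions$chrom,
                     regions$start - 1L, regions$end, regions$label,
                     regions$score)
  } else {
    lines <- character(0)
  }
  writeLines(lines, path)
  invisible(path)
}
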