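# CIGAR bookkeeping. Coordinates are 1-based inclusive throughout the package;
# only BED output converts to 0-based half-open.

#' Parse a CIGAR string
#'
#' @param cigar CIGAR string, e.g. `"40M4D60M"`. `"*"` yields zero rows.
#' @return data.frame with columns `op` (character) and `len` (integer).
#' @export
parse_cigar <- function(cigar) {
  stopifnot(length(cigar) == 1L)
  if (identical(cigar, "*") || !nzchar(cigar)) {
    return(data.frame(op = character(0), len = integer(0)))
  }
  lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]]
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  if (length(lens) != length(ops) || !all(ops %in% c("M", "I", "D", "S", "H", "=", "X"))) {
    stop("malformed CIGAR: ", cigar)
  }
  data.frame(op = ops, len = as.integer(lens), stringsAsFactors = FALSE)
}

cigar_ref_len_one <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "D", "=", "X")])
}

cigar_query_len_one <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "I", "S", "=", "X")])
}

#' Reference span consumed by CIGAR strings
#'
#' Vectorized; used to compute the rightmost aligned reference coordinate
#' `pos + cigar_ref_len(cigar) - 1` of each alignment.
#'
#' @param cigars character vector of CIGAR strings.
#' @return integer vector of reference lengths.
#' @export
cigar_ref_len <- function(cigars) {
  simple <- grepl("^[0-9]+M$", cigars)
  out <- integer(length(cigars))
  out[simple] <- as.integer(sub("M$", "", cigars[simple]))
  if (any(!simple)) {
    out[!simple] <- vapply(cigars[!simple], cigar_ref_len_one, integer(1), USE.NAMES = FALSE)
  }
  out
}

#' Query length consumed by CIGAR strings
#' @inheritParams cigar_ref_len
#' @return integer vector of query (read) lengths.
#' @export
cigar_query_len <- function(cigars) {
  vapply(cigars, cigar_query_len_one, integer(1), USE.NAMES = FALSE)
}

# Query offset (1-based within the read) of the base aligned at reference
# coordinate `target`. NA if `target` falls in a deletion, a clipped segment,
# or outside the alignment.
qpos_at_ref <- function(pos, cigar, target) {
  if (grepl("^[0-9]+M$", cigar)) {
    len <- as.integer(sub("M$", "", cigar))
    if (target < pos || target > pos + len - 1L) return(NA_integer_)
    return(target - pos + 1L)
  }
  cg <- parse_cigar(cigar)
  rpos <- pos          # next reference coordinate to consume
  qpos <- 1L           # next query coordinate to consume
  for (i in seq_len(nrow(cg))) {
    op <- cg$op[i]; len <- cg$len[i]
    if (op %in% c("M", "=", "X")) {
      if (target >= rpos && target <= rpos + len - 1L) {
        return(qpos + (target - rpos))
      }
      rpos <- rpos + len
      qpos <- qpos + len
    } else if (op == "D") {
      if (target >= rpos && target <= rpos + len - 1L) return(NA_integer_)
      rpos <- rpos + len
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + len
    } # H consumes nothing
  }
  NA_integer_
}

# Sequence the read places over the reference footprint [fstart, fend]:
# M bases aligned inside the footprint plus inserted bases anchored after a
# footprint position. NA if the alignment does not span the whole footprint.
extract_footprint_seq <- function(pos, cigar, seq, fstart, fend) {
  ref_end <- pos + cigar_ref_len(cigar) - 1L
  if (pos > fstart || ref_end < fend) return(NA_character_)
  cg <- parse_cigar(cigar)
  rpos <- pos; qpos <- 1L
  out <- character(0)
  for (i in seq_len(nrow(cg))) {
    op <- cg$op[i]; len <- cg$len[i]
    if (op %in% c("M", "=", "X")) {
      lo <- max(rpos, fstart); hi <- min(rpos + len - 1L, fend)
      if (lo <= hi) {
        out <- c(out, substr(seq, qpos + (lo - rpos), qpos + (hi - rpos)))
      }
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op == "D") {
      rpos <- rpos + len
    } else if (op == "I") {
      # anchored after reference position rpos - 1
      if (rpos - 1L >= fstart && rpos - 1L <= fend) {
        out <- c(out, substr(seq, qpos, qpos + len - 1L))
      }
      qpos <- qpos + len
    } else if (op == "S") {
      qpos <- qpos + len
    }
  }
  paste(out, collapse = "")
}

# Render a CIGAR data.frame back to string, merging adjacent equal ops and
# dropping zero-length ops.
cigar_string <- function(ops, lens) {
  keep <- lens > 0L
  ops <- ops[keep]; lens <- lens[keep]
  if (!length(ops)) return("*")
  j <- 1L
  for (i in seq_along(ops)[-1]) {
    if (ops[i] == ops[j]) {
      lens[j] <- lens[j] + lens[i]
    } else {
      j <- j + 1L
      ops[j] <- ops[i]; lens[j] <- lens[i]
    }
  }
  paste0(lens[seq_len(j)], ops[seq_len(j)], collapse = "")
}
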