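# Internal helpers shared across modules.

# Reverse-complement for plain character vectors (A/C/G/T/N only).
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# Phred+33 quality string -> integer vector of Phred scores.
qual_to_int <- function(qual) {
  as.integer(charToRaw(qual)) - 33L
}

int_to_qual <- function(q) {
  rawToChar(as.raw(q + 33L))
}

# Parse a CIGAR string into (lengths, ops). Returns a list with integer
# `len` and character `op`. "*" yields zero-length vectors.
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || cigar == "") {
    return(list(len = integer(0), op = character(0)))
  }
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(len) != length(op)) {
    stop("malformed CIGAR string: ", cigar)
  }
  list(len = len, op = op)
}

cigar_read_len <- function(cigar) {
  cg <- parse_cigar(cigar)
  consumes <- cg$op %in% c("M", "I", "S", "=", "X")
  sum(cg$len[consumes])
}

cigar_ref_len <- function(cigar) {
  cg <- parse_cigar(cigar)
  consumes <- cg$op %in% c("M", "D", "N", "=", "X")
  sum(cg$len[consumes])
}

# Aligned (read position, reference position) pairs for M/=/X operations,
# plus counts of inserted/deleted and soft-clipped bases.
# Returns list(read_idx, ref_pos, n_ins, n_del, n_clip).
aligned_pairs <- function(cigar, pos) {
  cg <- parse_cigar(cigar)
  read_at <- 1L
  ref_at <- as.integer(pos)
  read_idx <- integer(0)
  ref_pos <- integer(0)
  n_ins <- 0L
  n_del <- 0L
  n_clip <- 0L
  for (i in seq_along(cg$op)) {
    op <- cg$op[i]
    l <- cg$len[i]
    if (op %in% c("M", "=", "X")) {
      read_idx <- c(read_idx, seq.int(read_at, length.out = l))
      ref_pos <- c(ref_pos, seq.int(ref_at, length.out = l))
      read_at <- read_at + l
      ref_at <- ref_at + l
    } else if (op == "I") {
      n_ins <- n_ins + l
      read_at <- read_at + l
    } else if (op == "D") {
      n_del <- n_del + l
      ref_at <- ref_at + l
    } else if (op == "N") {
      ref_at <- ref_at + l
    } else if (op == "S") {
      n_clip <- n_clip + l
      read_at <- read_at + l
    }
    # H and P consume nothing we track
  }
  list(read_idx = read_idx, ref_pos = ref_pos,
       n_ins = n_ins, n_del = n_del, n_clip = n_clip)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
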