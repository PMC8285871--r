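# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk unless a test writes it first.

# A minimal alignment table row, defaulting to a simple full-match record.
make_aln <- function(read_id = "r1", chrom = "chr1", pos = 1L, seq = "ACGT",
                     q = 20L, bs_strand = "CT", cigar = NULL, flag = 0L,
                     mate = 1L, mapped = TRUE, secondary = FALSE,
                     genome_label = "parent1", strand = "+") {
  data.frame(read_id = read_id, flag = flag, mate = mate,
             chrom = ifelse(mapped, chrom, NA_character_),
             pos = ifelse(mapped, as.integer(pos), NA_integer_),
             strand = ifelse(mapped, strand, NA_character_),
             mapq = 255L,
             cigar = ifelse(mapped, cigar %||% paste0(nchar(seq), "M"),
                            NA_character_),
             seq = seq,
             qual = vapply(nchar(seq), function(n)
               homeosort:::int_to_qual(rep(q, n)), character(1)),
             bs_strand = bs_strand, mapped = mapped, secondary = secondary,
             genome_label = genome_label, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a SAM file for an alignment table, with a default header
write_test_sam <- function(aln, genome, path = tempfile(fileext = ".sam")) {
  hdr <- attr(aln, "sam_header") %||% homeosort:::default_sam_header(genome)
  writeLines(c(hdr, homeosort:::alignments_to_sam_lines(aln)), path)
  path
}

# Independent brute-force oracle for alignment scoring: list the aligned
# base pairs by walking the CIGAR with simple cursors, then sum
# base_log_prob term by term. Kept deliberately naive and separate from the
# package's vectorised implementation.
oracle_score <- function(aln, genome, cfg) {
  ref <- strsplit(genome$seq[[aln$chrom]], "")[[1]]
  red <- strsplit(aln$seq, "")[[1]]
  q <- as.integer(charToRaw(aln$qual)) - 33L
  num <- as.integer(regmatches(aln$cigar, gregexpr("[0-9]+", aln$cigar))[[1]])
  ops <- regmatches(aln$cigar, gregexpr("[A-Z=]", aln$cigar))[[1]]
  ri <- 1L
  gi <- aln$pos
  total <- 0
  for (k in seq_along(ops)) {
    if (ops[k] %in% c("M", "=", "X")) {
      for (j in seq_len(num[k])) {
        rb <- ref[gi]
        db <- red[ri]
        if (rb != "N" && db != "N") {
          e <- 10^(-q[ri] / 10)
          ct <- cfg$bs_mode == "both" ||
            (cfg$bs_mode == "strand" && aln$bs_strand == "CT")
          ga <- cfg$bs_mode == "both" ||
            (cfg$bs_mode == "strand" && aln$bs_strand == "GA")
          hit <- rb == db ||
            (ct && ((rb == "C" && db == "T") || (rb == "T" && db == "C"))) ||
            (ga && ((rb == "G" && db == "A") || (rb == "A" && db == "G")))
          total <- total + if (hit) log(1 - e) else log(e / 3)
        }
        ri <- ri + 1L
        gi <- gi + 1L
      }
    } else if (ops[k] == "I") {
      total <- total + num[k] * cfg$indel_logpen
      ri <- ri + num[k]
    } else if (ops[k] == "D") {
      total <- total + num[k] * cfg$indel_logpen
      gi <- gi + num[k]
    } else if (ops[k] == "N") {
      gi <- gi + num[k]
    } else if (ops[k] == "S") {
      ri <- ri + num[k]
    }
  }
  total
}

# relabel an alignment table to the other parental side
transform_label <- function(aln, label) {
  hdr <- attr(aln, "sam_header")
  aln$genome_label <- label
  attr(aln, "sam_header") <- hdr
  aln
}

# random genome fragment with fixed composition
random_seq <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
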