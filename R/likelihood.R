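#' Scoring configuration for the bisulfite-aware read likelihood
#'
#' @param bs_mode How bisulfite conversion is treated when comparing read and
#'   reference bases: \code{"strand"} uses each read's conversion-strand tag
#'   (C-T scored as a match on CT reads, G-A on GA reads), \code{"both"}
#'   accepts both substitution types regardless of tag, \code{"off"} scores
#'   them as mismatches.
#' @param indel_logpen Per-base natural-log penalty for inserted or deleted
#'   bases (must be negative). Default \code{log(1e-4)}.
#' @param tie_margin Half-width of the ambiguity band on the log-odds scale:
#'   reads whose two placements differ by at most this much are called
#'   ambiguous. Default 0 (exact ties only, tested at 1e-9 tolerance).
#' @return A \code{scoring_config} object (list).
#' @export
scoring_config <- function(bs_mode = c("strand", "both", "off"),
                           indel_logpen = log(1e-4), tie_margin = 0) {
  bs_mode <- match.arg(bs_mode)
  stopifnot(indel_logpen < 0, tie_margin >= 0)
  structure(list(bs_mode = bs_mode, indel_logpen = indel_logpen,
                 tie_margin = tie_margin),
            class = "scoring_config")
}

#' Per-base log-probability under the bisulfite-aware Phred model
#'
#' Scores one aligned (reference base, read base) pair given the read base's
#' Phred quality. With error probability \eqn{e = 10^{-q/10}}, a match
#' contributes \eqn{\ln(1-e)} and a mismatch \eqn{\ln(e/3)}. Bisulfite
#' conversion artifacts are scored as matches in converted space: on reads
#' from the C-to-T converted strand (\code{bs_strand = "CT"}, or always when
#' \code{bs_mode = "both"}) the \{C,T\} base pair is treated as a match in
#' either orientation (a converted read T over a reference C, or a
#' methylation-protected read C over the other haplotype's T); \{G,A\} is
#' handled the same way for the opposite conversion strand. Pairs involving
#' N on either side contribute 0 (skipped).
#'
#' All arguments are vectorised.
#'
#' @param ref_base,read_base Single characters in A/C/G/T/N.
#' @param phred_q Phred quality score(s), non-negative.
#' @param bs_strand \code{"CT"} or \code{"GA"}; which converted template
#'   strand the read derives from.
#' @param bs_mode See \code{\link{scoring_config}}.
#' @return Numeric vector of natural-log probabilities; \code{NA} marks
#'   skipped (N-containing) pairs.
#' @examples
#' base_log_prob("A", "A", 20, "CT")            # log(0.99)
#' base_log_prob("C", "T", 20, "CT")            # log(0.99): conversion match
#' base_log_prob("C", "T", 20, "CT", "off")     # log(0.01/3)
#' @export
base_log_prob <- function(ref_base, read_base, phred_q, bs_strand = "CT",
                          bs_mode = c("strand", "both", "off")) {
  bs_mode <- match.arg(bs_mode)
  n <- max(length(ref_base), length(read_base), length(phred_q),
           length(bs_strand))
  ref_base <- rep_len(ref_base, n)
  read_base <- rep_len(read_base, n)
  phred_q <- rep_len(phred_q, n)
  bs_strand <- rep_len(bs_strand, n)
  stopifnot(all(phred_q >= 0))
  e <- 10^(-phred_q / 10)
  ct_ok <- bs_mode == "both" | (bs_mode == "strand" & bs_strand == "CT")
  ga_ok <- bs_mode == "both" | (bs_mode == "strand" & bs_strand == "GA")
  # converted-space semantics: the {C,T} pair is indistinguishable on the
  # CT strand (a reference T under a methylation-protected read C is as much
  # a bisulfite artifact as a reference C under a converted read T), and
  # {G,A} likewise on the GA strand
  ct_pair <- (ref_base == "C" & read_base == "T") |
    (ref_base == "T" & read_base == "C")
  ga_pair <- (ref_base == "G" & read_base == "A") |
    (ref_base == "A" & read_base == "G")
  match <- ref_base == read_base | (ct_pair & ct_ok) | (ga_pair & ga_ok)
  out <- ifelse(match, log1p(-e), log(e / 3))
  out[ref_base == "N" | read_base == "N"] <- NA_real_
  out
}

# Vectorised scoring core over parallel base vectors. Returns per-position
# log terms (0 for skipped), plus logical vectors describing each position.
score_base_vectors <- function(ref, read, q, bs_strand, bs_mode) {
  e <- 10^(-q / 10)
  ct_ok <- bs_mode == "both" | (bs_mode == "strand" & bs_strand == "CT")
  ga_ok <- bs_mode == "both" | (bs_mode == "strand" & bs_strand == "GA")
  skipped <- ref == "N" | read == "N"
  ct_pair <- (ref == "C" & read == "T") | (ref == "T" & read == "C")
  ga_pair <- (ref == "G" & read == "A") | (ref == "A" & read == "G")
  is_match <- !skipped & (ref == read | (ct_pair & ct_ok) |
                            (ga_pair & ga_ok))
  bs_match <- is_match & ref != read
  term <- ifelse(is_match, log1p(-e), log(e / 3))
  term[skipped] <- 0
  list(term = term, match = is_match, mismatch = !skipped & !is_match,
       skipped = skipped, bs_match = bs_match)
}

#' Score one alignment under the bisulfite-aware likelihood
#'
#' Walks the CIGAR of a mapped alignment and sums \code{\link{base_log_prob}}
#' over all M/=/X-aligned positions; inserted and deleted bases each add
#' \code{indel_logpen}; soft-clipped bases and positions with N in read or
#' reference are skipped (zero contribution).
#'
#' @param aln One-row alignment data.frame (see \code{\link{read_sam}}).
#' @param genome \code{genome_seq} the alignment refers to.
#' @param cfg A \code{\link{scoring_config}}.
#' @return A list with \code{loglik}, \code{n_match}, \code{n_mismatch},
#'   \code{n_bs_match}, \code{n_skipped}.
#' @export
score_alignment <- function(aln, genome, cfg = scoring_config()) {
  stopifnot(nrow(aln) == 1)
  res <- score_alignments(aln, genome, cfg)
  list(loglik = res$loglik, n_match = res$n_match,
       n_mismatch = res$n_mismatch, n_bs_match = res$n_bs_match,
       n_skipped = res$n_skipped)
}

#' Score a table of alignments under the bisulfite-aware likelihood
#'
#' Vectorised version of \code{\link{score_alignment}}: adds columns
#' \code{loglik}, \code{n_match}, \code{n_mismatch}, \code{n_bs_match},
#' \code{n_skipped} to the alignment table. Unmapped records get \code{NA}
#' log-likelihood. Alignments whose CIGAR is a single match run take a fast
#' vectorised path; anything else falls back to a per-record CIGAR walk.
#'
#' @inheritParams score_alignment
#' @param aln Alignment table.
#' @return The input data.frame with scoring columns appended.
#' @export
score_alignments <- function(aln, genome, cfg = scoring_config()) {
  n <- nrow(aln)
  aln$loglik <- rep(NA_real_, n)
  aln$n_match <- rep(NA_integer_, n)
  aln$n_mismatch <- rep(NA_integer_, n)
  aln$n_bs_match <- rep(NA_integer_, n)
  aln$n_skipped <- rep(NA_integer_, n)
  if (n == 0) return(aln)
  mapped <- which(aln$mapped)
  if (length(mapped) == 0) return(aln)

  # validate CIGAR vs read length
  rl <- nchar(aln$seq[mapped])
  cl <- vapply(aln$cigar[mapped], cigar_read_len, numeric(1),
               USE.NAMES = FALSE)
  if (any(rl != cl)) {
    stop("CIGAR read-consuming length disagrees with sequence length for ",
         "read ", aln$read_id[mapped[which(rl != cl)[1]]])
  }

  simple <- grepl("^[0-9]+M$", aln$cigar[mapped])
  idx_simple <- mapped[simple]
  idx_other <- mapped[!simple]

  if (length(idx_simple)) {
    len <- nchar(aln$seq[idx_simple])
    refwin <- substring(genome$seq[aln$chrom[idx_simple]],
                        aln$pos[idx_simple],
                        aln$pos[idx_simple] + len - 1L)
    ref <- strsplit(paste(refwin, collapse = ""), "")[[1]]
    red <- strsplit(paste(aln$seq[idx_simple], collapse = ""), "")[[1]]
    q <- qual_to_int(paste(aln$qual[idx_simple], collapse = ""))
    grp <- rep.int(seq_along(idx_simple), len)
    bs <- rep.int(aln$bs_strand[idx_simple], len)
    sc <- score_base_vectors(ref, red, q, bs, cfg$bs_mode)
    aln$loglik[idx_simple] <- as.numeric(rowsum(sc$term, grp))
    aln$n_match[idx_simple] <- as.integer(rowsum(as.integer(sc$match), grp))
    aln$n_mismatch[idx_simple] <- as.integer(rowsum(as.integer(sc$mismatch), grp))
    aln$n_bs_match[idx_simple] <- as.integer(rowsum(as.integer(sc$bs_match), grp))
    aln$n_skipped[idx_simple] <- as.integer(rowsum(as.integer(sc$skipped), grp))
  }

  for (i in idx_other) {
    ap <- aligned_pairs(aln$cigar[i], aln$pos[i])
    chromseq <- genome$seq[[aln$chrom[i]]]
    ref <- strsplit(paste0(substring(chromseq, ap$ref_pos, ap$ref_pos),
                           collapse = ""), "")[[1]]
    redall <- strsplit(aln$seq[i], "")[[1]]
    qall <- qual_to_int(aln$qual[i])
    red <- redall[ap$read_idx]
    q <- qall[ap$read_idx]
    sc <- score_base_vectors(ref, red, q, rep(aln$bs_strand[i], length(red)),
                             cfg$bs_mode)
    aln$loglik[i] <- sum(sc$term) + cfg$indel_logpen * (ap$n_ins + ap$n_del)
    aln$n_match[i] <- sum(sc$match)
    aln$n_mismatch[i] <- sum(sc$mismatch)
    aln$n_bs_match[i] <- sum(sc$bs_match)
    aln$n_skipped[i] <- sum(sc$skipped) + ap$n_clip + ap$n_ins
  }
  aln
}
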