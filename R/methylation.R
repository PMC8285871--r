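#' Remove duplicate alignments on one parental side
#'
#' Keeps at most one read unit per duplication key, mirroring
#' Bismark-style deduplication: for single-end records the key is
#' (chromosome, leftmost position, strand); for paired-end records the key
#' additionally includes the mate-pair outer coordinates. The first record
#' encountered per key is kept (stable).
#'
#' @param aln Alignment table for a single genome side.
#' @return The alignment table with duplicate rows removed; unmapped records
#'   pass through untouched.
#' @export
deduplicate_alignments <- function(aln) {
  if (nrow(aln) == 0) return(aln)
  if (length(unique(aln$genome_label)) > 1) {
    stop("deduplication operates on a single genome side")
  }
  mapped <- aln$mapped & !aln$secondary
  paired <- bitwAnd(aln$flag, 1L) > 0L
  end_of <- function(i) aln$pos[i] +
    vapply(aln$cigar[i], cigar_ref_len, numeric(1), USE.NAMES = FALSE) - 1L
  key <- rep(NA_character_, nrow(aln))
  se <- which(mapped & !paired)
  if (length(se)) {
    key[se] <- paste(aln$chrom[se], aln$pos[se], aln$strand[se], sep = ":")
  }
  pe <- which(mapped & paired)
  if (length(pe)) {
    # outer coordinates of the pair: min start / max end across mates
    idx <- split(pe, aln$read_id[pe])
    for (rows in idx) {
      outer_key <- paste(aln$chrom[rows[1]], min(aln$pos[rows]),
                         max(end_of(rows)), aln$strand[rows[1]], sep = ":")
      key[rows] <- outer_key
    }
  }
  # one key per read unit: drop every record of a read whose key was
  # already claimed by an earlier read
  first_of_key <- !duplicated(key, incomparables = NA)
  owner <- aln$read_id[first_of_key][match(key, key[first_of_key])]
  drop <- !is.na(key) & owner != aln$read_id
  out <- aln[!drop, , drop = FALSE]
  attr(out, "sam_header") <- attr(aln, "sam_header")
  rownames(out) <- NULL
  out
}

#' Methylation context of a cytosine
#'
#' Determines the CG/CHG/CHH context and the reference trinucleotide for a
#' cytosine at a given position and strand, reading 5'-to-3' on the
#' cytosine's strand (for minus-strand cytosines, i.e. G on the forward
#' strand, the forward triplet ending at the position is
#' reverse-complemented). Contexts: second base G gives CG; otherwise third
#' base G gives CHG; otherwise CHH (H = A, T or C). Positions whose triplet
#' runs off the chromosome end, or contains N, have undefined context
#' (\code{NA}).
#'
#' All of \code{chrom}, \code{pos}, \code{strand} are vectorised.
#'
#' @param genome A \code{genome_seq}.
#' @param chrom Chromosome id(s).
#' @param pos 1-based position(s) of the cytosine on the forward strand.
#' @param strand \code{"+"} (C on forward strand) or \code{"-"} (C on
#'   reverse strand, G on forward).
#' @return data.frame with columns \code{context} and \code{tri}.
#' @examples
#' g <- genome_seq(c(chr1 = "ACGTTCAGG"), "demo")
#' assign_context(g, "chr1", 2, "+")  # CGT -> CG
#' @export
assign_context <- function(genome, chrom, pos, strand) {
  n <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(as.integer(pos), n)
  strand <- rep_len(strand, n)
  base_at <- substring(genome$seq[chrom], pos, pos)
  expect <- ifelse(strand == "+", "C", "G")
  if (any(base_at != expect)) {
    stop("position is not a cytosine on the requested strand (first offender: ",
         chrom[base_at != expect][1], ":", pos[base_at != expect][1], ")")
  }
  len <- genome$lengths[chrom]
  tri <- rep(NA_character_, n)
  fwd <- strand == "+"
  ok_f <- fwd & pos + 2L <= len
  ok_r <- !fwd & pos - 2L >= 1L
  tri[ok_f] <- substring(genome$seq[chrom[ok_f]], pos[ok_f], pos[ok_f] + 2L)
  tri[ok_r] <- revcomp(substring(genome$seq[chrom[ok_r]], pos[ok_r] - 2L,
                                 pos[ok_r]))
  tri[!is.na(tri) & grepl("N", tri)] <- NA_character_
  if (any(is.na(tri))) {
    warning(sum(is.na(tri)),
            " cytosine(s) with undefined context (chromosome edge or N)")
  }
  b2 <- substring(tri, 2, 2)
  b3 <- substring(tri, 3, 3)
  context <- ifelse(is.na(tri), NA_character_,
                    ifelse(b2 == "G", "CG", ifelse(b3 == "G", "CHG", "CHH")))
  data.frame(context = context, tri = tri, stringsAsFactors = FALSE)
}

# Collect per-base methylation calls from a set of alignments.
# Returns data.frame(chrom, pos, strand, meth) with one row per call.
collect_meth_calls <- function(aln, genome) {
  mapped <- which(aln$mapped)
  if (length(mapped) == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), meth = logical(0),
                      stringsAsFactors = FALSE))
  }
  chrom_v <- character(0)
  pos_v <- integer(0)
  ref_v <- character(0)
  read_v <- character(0)
  bs_v <- character(0)
  unit_v <- character(0)   # read_id, to drop overlapping-mate double counts
  mate_v <- integer(0)

  simple <- grepl("^[0-9]+M$", aln$cigar[mapped])
  idx_simple <- mapped[simple]
  if (length(idx_simple)) {
    len <- nchar(aln$seq[idx_simple])
    refwin <- substring(genome$seq[aln$chrom[idx_simple]],
                        aln$pos[idx_simple], aln$pos[idx_simple] + len - 1L)
    ref_v <- strsplit(paste(refwin, collapse = ""), "")[[1]]
    read_v <- strsplit(paste(aln$seq[idx_simple], collapse = ""), "")[[1]]
    chrom_v <- rep.int(aln$chrom[idx_simple], len)
    off <- sequence(len) - 1L
    pos_v <- rep.int(aln$pos[idx_simple], len) + off
    bs_v <- rep.int(aln$bs_strand[idx_simple], len)
    unit_v <- rep.int(aln$read_id[idx_simple], len)
    mate_v <- rep.int(aln$mate[idx_simple], len)
  }
  for (i in mapped[!simple]) {
    ap <- aligned_pairs(aln$cigar[i], aln$pos[i])
    if (length(ap$ref_pos) == 0) next
    chromseq <- genome$seq[[aln$chrom[i]]]
    ref_v <- c(ref_v, substring(chromseq, ap$ref_pos, ap$ref_pos))
    read_v <- c(read_v, strsplit(aln$seq[i], "")[[1]][ap$read_idx])
    chrom_v <- c(chrom_v, rep(aln$chrom[i], length(ap$ref_pos)))
    pos_v <- c(pos_v, ap$ref_pos)
    bs_v <- c(bs_v, rep(aln$bs_strand[i], length(ap$ref_pos)))
    unit_v <- c(unit_v, rep(aln$read_id[i], length(ap$ref_pos)))
    mate_v <- c(mate_v, rep(aln$mate[i], length(ap$ref_pos)))
  }

  # overlapping mates: count each (read, position) once, mate 1 wins
  ord <- order(mate_v)
  dupkey <- paste(unit_v[ord], chrom_v[ord], pos_v[ord], sep = "\r")
  keep <- ord[!duplicated(dupkey)]
  ref_v <- ref_v[keep]; read_v <- read_v[keep]; chrom_v <- chrom_v[keep]
  pos_v <- pos_v[keep]; bs_v <- bs_v[keep]

  # CT-strand reads report forward-strand cytosines (reference C);
  # GA-strand reads report reverse-strand cytosines (reference G)
  ct <- bs_v == "CT" & ref_v == "C" & read_v %in% c("C", "T")
  ga <- bs_v == "GA" & ref_v == "G" & read_v %in% c("G", "A")
  sel <- ct | ga
  data.frame(chrom = chrom_v[sel], pos = pos_v[sel],
             strand = ifelse(ct[sel], "+", "-"),
             meth = read_v[sel] %in% c("C", "G"),
             stringsAsFactors = FALSE)
}

# Enumerate all reference cytosines of a genome with context.
all_reference_cytosines <- function(genome) {
  out <- lapply(names(genome$seq), function(ch) {
    s <- genome$seq[[ch]]
    bases <- strsplit(s, "")[[1]]
    fwd <- which(bases == "C")
    rev <- which(bases == "G")
    data.frame(chrom = ch, pos = c(fwd, rev),
               strand = rep(c("+", "-"), c(length(fwd), length(rev))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Extract per-cytosine methylation counts from classified reads
#'
#' Produces a cytosine-level methylation count table in the shape of a
#' Bismark CX report. On reads from the C-to-T converted strand, a read C
#' over a reference C is a methylated call and a read T an unmethylated call
#' (other bases are ignored); on G-to-A strand reads the same logic applies
#' to reference G positions, which are cytosines of the reverse strand.
#' Overlapping segments of mate pairs are counted once (mate 1 wins). Bases
#' over reference N and read N bases are ignored.
#'
#' @param aln Alignment table, classified to this genome side and
#'   deduplicated.
#' @param genome The \code{genome_seq} of this side.
#' @param cx_all If \code{TRUE}, emit one row for every reference cytosine,
#'   including uncovered ones (zero counts); otherwise only covered
#'   cytosines are reported.
#' @return data.frame with columns \code{chrom}, \code{pos}, \code{strand},
#'   \code{n_meth}, \code{n_unmeth}, \code{context}, \code{tri}, sorted by
#'   chromosome and position. Cytosines with undefined context (chromosome
#'   edge, N in the triplet) are dropped with a warning.
#' @export
extract_methylation <- function(aln, genome, cx_all = FALSE) {
  calls <- collect_meth_calls(aln, genome)
  if (nrow(calls)) {
    key <- paste(calls$chrom, calls$pos, calls$strand, sep = "\r")
    agg <- rowsum(cbind(meth = as.integer(calls$meth),
                        unmeth = as.integer(!calls$meth)), key)
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    tab <- data.frame(chrom = vapply(parts, `[[`, character(1), 1),
                      pos = as.integer(vapply(parts, `[[`, character(1), 2)),
                      strand = vapply(parts, `[[`, character(1), 3),
                      n_meth = as.integer(agg[, "meth"]),
                      n_unmeth = as.integer(agg[, "unmeth"]),
                      stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), n_meth = integer(0),
                      n_unmeth = integer(0), stringsAsFactors = FALSE)
  }
  if (cx_all) {
    ref <- all_reference_cytosines(genome)
    key_ref <- paste(ref$chrom, ref$pos, ref$strand, sep = "\r")
    key_tab <- paste(tab$chrom, tab$pos, tab$strand, sep = "\r")
    m <- match(key_ref, key_tab)
    tab <- data.frame(ref,
                      n_meth = ifelse(is.na(m), 0L, tab$n_meth[m]),
                      n_unmeth = ifelse(is.na(m), 0L, tab$n_unmeth[m]),
                      stringsAsFactors = FALSE)
  }
  if (nrow(tab) == 0) {
    tab$context <- character(0)
    tab$tri <- character(0)
    return(tab)
  }
  ctx <- assign_context(genome, tab$chrom, tab$pos, tab$strand)
  tab$context <- ctx$context
  tab$tri <- ctx$tri
  tab <- tab[!is.na(tab$context), , drop = FALSE]
  tab <- tab[order(tab$chrom, tab$pos, tab$strand), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write a methylation table as a Bismark-style CX report
#'
#' Tab-separated, no header: chromosome, position, strand, methylated count,
#' unmethylated count, context, trinucleotide.
#'
#' @param meth Table from \code{\link{extract_methylation}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_cx_report <- function(meth, path) {
  utils::write.table(meth[, c("chrom", "pos", "strand", "n_meth", "n_unmeth",
                              "context", "tri")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Estimate bisulfite conversion efficiency from an unmethylated control
#'
#' Aligned reads from a control genome assumed fully unmethylated (plastid
#' genome for plants, lambda phage otherwise) are reduced to cytosine calls;
#' since every cytosine is unmethylated, the fraction of calls read as
#' converted estimates the conversion efficiency. The control mapping rate —
#' the field's quick proxy, where a lower mapping rate against an
#' unconverted index indicates better conversion — is reported alongside
#' when \code{total_reads} is supplied.
#'
#' @param aln Alignment table against the control genome.
#' @param control_genome \code{genome_seq} of the control.
#' @param total_reads Optional total number of reads in the library, to
#'   compute the control mapping rate.
#' @return List with \code{conversion_rate} (in [0, 1]), \code{n_calls},
#'   \code{n_converted}, and \code{mapping_rate} (NA unless
#'   \code{total_reads} given).
#' @export
conversion_rate <- function(aln, control_genome, total_reads = NULL) {
  calls <- collect_meth_calls(aln, control_genome)
  n <- nrow(calls)
  if (n == 0) stop("no cytosine calls on the control genome; conversion rate undefined")
  conv <- sum(!calls$meth)
  mapping_rate <- NA_real_
  if (!is.null(total_reads)) {
    n_mapped <- length(unique(aln$read_id[aln$mapped]))
    mapping_rate <- n_mapped / total_reads
  }
  list(conversion_rate = conv / n, n_calls = n, n_converted = conv,
       mapping_rate = mapping_rate)
}
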