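#' Read a parental genome assembly from FASTA
#'
#' Loads a (multi-)FASTA file into a \code{genome_seq} object: a named set of
#' chromosome sequences for one parental reference. Sequences are uppercased;
#' IUPAC ambiguity codes other than N are replaced by N with a warning, so
#' that downstream scoring can skip them uniformly.
#'
#' @param path Path to a FASTA file (gzip-compressed files are accepted).
#' @param label Text label for this genome, e.g. \code{"parent1"}. Defaults to
#'   the file name without extension.
#' @return An object of class \code{genome_seq}: a list with elements
#'   \code{label}, \code{seq} (named character vector of chromosome
#'   sequences) and \code{lengths} (named integer vector).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' g <- read_genome_fasta(fa, label = "parent1")
#' g$seq[["chr1"]]
#' @export
read_genome_fasta <- function(path, label = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome id in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- nm
  has_amb <- grepl("[^ACGTN]", seqs)
  if (any(has_amb)) {
    warning("ambiguity codes other than N found in ",
            sum(has_amb), " sequence(s); replaced by N")
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  genome_seq(seqs, label = label %||% sub("\\.(fa|fasta)(\\.gz)?$", "",
                                          basename(path)))
}

#' Construct a genome_seq object from character sequences
#'
#' @param seqs Named character vector of chromosome sequences (A/C/G/T/N).
#' @param label Text label for the genome.
#' @return A \code{genome_seq} object.
#' @export
genome_seq <- function(seqs, label = "genome") {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("all sequences must be named by chromosome id")
  }
  if (anyDuplicated(names(seqs))) stop("duplicate chromosome id")
  seqs <- toupper(seqs)
  if (any(grepl("[^ACGTN]", seqs))) {
    stop("sequences contain characters outside A/C/G/T/N")
  }
  structure(list(label = label, seq = seqs, lengths = nchar(seqs)),
            class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("genome_seq '", x$label, "': ", length(x$seq), " sequence(s), ",
      sum(x$lengths), " bp total\n", sep = "")
  invisible(x)
}

#' Write a genome_seq to FASTA
#'
#' @param genome A \code{genome_seq} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read bisulfite alignments from a SAM file
#'
#' Parses a plain-text SAM file into an alignment table. The bisulfite
#' conversion strand of each read is taken from the Bismark-style
#' \code{XG:Z:CT} / \code{XG:Z:GA} tag; when the tag is absent,
#' \code{default_bs_strand} is used, and if that is \code{NULL} too, an error
#' is raised for mapped records. Records aligned to a chromosome that is not
#' present in \code{genome} are an error (reference mismatch).
#'
#' This reader is deliberately minimal: it handles the eleven mandatory SAM
#' columns plus optional tags, which is all the classifier consumes. BAM input
#' can be converted with \code{samtools view -h} beforehand.
#'
#' @param path Path to a SAM file (with header).
#' @param genome Optional \code{genome_seq} the alignments refer to; used to
#'   validate chromosome names and coordinates.
#' @param default_bs_strand \code{"CT"}, \code{"GA"} or \code{NULL}; fallback
#'   conversion strand when no XG tag is present.
#' @param bs_strand_tag Name of the SAM tag carrying the conversion strand
#'   (default \code{"XG"}).
#' @param genome_label Label recorded for these alignments; defaults to
#'   \code{genome$label} if a genome is given.
#' @return A data.frame with one row per SAM record and columns
#'   \code{read_id}, \code{flag}, \code{mate}, \code{chrom}, \code{pos},
#'   \code{strand}, \code{mapq}, \code{cigar}, \code{seq}, \code{qual},
#'   \code{bs_strand}, \code{mapped}, \code{secondary}, \code{genome_label}.
#'   The SAM header lines are kept in the \code{"sam_header"} attribute.
#' @export
read_sam <- function(path, genome = NULL, default_bs_strand = NULL,
                     bs_strand_tag = "XG", genome_label = NULL) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  rec <- lines[!startsWith(lines, "@") & nzchar(lines)]
  label <- genome_label %||% (if (!is.null(genome)) genome$label else NA_character_)
  if (length(rec) == 0) {
    out <- empty_alignments(label)
    attr(out, "sam_header") <- hdr
    return(out)
  }
  fields <- strsplit(rec, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11)) stop("SAM record with fewer than 11 fields at line ",
                         which(nf < 11)[1])
  f <- function(i) vapply(fields, `[[`, character(1), i)
  flag <- as.integer(f(2))
  mapped <- bitwAnd(flag, 4L) == 0L
  tag_re <- paste0("^", bs_strand_tag, ":Z:")
  bs <- vapply(fields, function(x) {
    hit <- grep(tag_re, x[-(1:11)], value = TRUE)
    if (length(hit)) sub(tag_re, "", hit[1]) else NA_character_
  }, character(1))
  if (any(mapped & is.na(bs))) {
    if (is.null(default_bs_strand)) {
      stop("mapped SAM record without ", bs_strand_tag,
           " conversion-strand tag and no default_bs_strand given")
    }
    bs[mapped & is.na(bs)] <- default_bs_strand
  }
  if (!all(bs[mapped] %in% c("CT", "GA"))) {
    stop("bs_strand must be CT or GA")
  }
  out <- data.frame(
    read_id = f(1),
    flag = flag,
    mate = ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L),
    chrom = ifelse(mapped, f(3), NA_character_),
    pos = ifelse(mapped, as.integer(f(4)), NA_integer_),
    strand = ifelse(mapped, ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                    NA_character_),
    mapq = as.integer(f(5)),
    cigar = ifelse(mapped, f(6), NA_character_),
    seq = f(10),
    qual = f(11),
    bs_strand = bs,
    mapped = mapped,
    secondary = bitwAnd(flag, 256L) > 0L,
    genome_label = label,
    stringsAsFactors = FALSE
  )
  if (!is.null(genome)) {
    bad <- out$mapped & !(out$chrom %in% names(genome$seq))
    if (any(bad)) {
      stop("alignment references chromosome absent from genome '",
           genome$label, "': ", paste(unique(out$chrom[bad]), collapse = ", "))
    }
    ends <- out$pos[out$mapped] +
      vapply(out$cigar[out$mapped], cigar_ref_len, numeric(1)) - 1L
    if (any(out$pos[out$mapped] < 1L) ||
        any(ends > genome$lengths[out$chrom[out$mapped]])) {
      stop("alignment extends beyond chromosome bounds")
    }
  }
  attr(out, "sam_header") <- hdr
  out
}

empty_alignments <- function(label = NA_character_) {
  data.frame(read_id = character(0), flag = integer(0), mate = integer(0),
             chrom = character(0), pos = integer(0), strand = character(0),
             mapq = integer(0), cigar = character(0), seq = character(0),
             qual = character(0), bs_strand = character(0),
             mapped = logical(0), secondary = logical(0),
             genome_label = if (length(label)) label[0] else character(0),
             stringsAsFactors = FALSE)
}

# Serialise an alignment table back to SAM lines (no header).
alignments_to_sam_lines <- function(aln) {
  if (nrow(aln) == 0) return(character(0))
  tags <- ifelse(is.na(aln$bs_strand), "", paste0("\tXG:Z:", aln$bs_strand))
  paste0(aln$read_id, "\t", aln$flag, "\t",
         ifelse(aln$mapped, aln$chrom, "*"), "\t",
         ifelse(aln$mapped, aln$pos, 0L), "\t",
         aln$mapq, "\t",
         ifelse(aln$mapped, aln$cigar, "*"), "\t*\t0\t0\t",
         aln$seq, "\t", aln$qual, tags)
}

default_sam_header <- function(genome) {
  c("@HD\tVN:1.6\tSO:unsorted",
    paste0("@SQ\tSN:", names(genome$seq), "\tLN:", genome$lengths))
}

#' Write alignments to SAM, partitioned by classification category
#'
#' Writes one SAM file per classification category for a single parental
#' side, mirroring the per-category outputs of the read-sorting step. All
#' records must share one \code{genome_label}.
#'
#' @param aln Alignment table (as from \code{\link{read_sam}}).
#' @param classification A data.frame with columns \code{read_id} and
#'   \code{category} (e.g. the \code{table} element of a
#'   \code{\link{classify_reads}} result), or \code{NULL} to write a single
#'   file.
#' @param out_dir Output directory (created if needed).
#' @param prefix File name prefix; files are named
#'   \code{<prefix>_<category>.sam}.
#' @param header Character vector of SAM header lines; defaults to the
#'   \code{"sam_header"} attribute of \code{aln} if present.
#' @param categories Categories to write; defaults to those present in
#'   \code{classification}. Empty categories produce header-only files.
#' @return Named character vector of file paths, invisibly.
#' @export
write_classified_sam <- function(aln, classification, out_dir,
                                 prefix = "reads", header = NULL,
                                 categories = NULL) {
  if (nrow(aln) > 0 && length(unique(aln$genome_label)) > 1) {
    stop("records span multiple genome labels; write one side at a time")
  }
  if (is.null(header)) header <- attr(aln, "sam_header")
  if (is.null(header) || length(header) == 0) {
    header <- "@HD\tVN:1.6\tSO:unsorted"
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(classification)) {
    path <- file.path(out_dir, paste0(prefix, ".sam"))
    writeLines(c(header, alignments_to_sam_lines(aln)), path)
    return(invisible(c(all = path)))
  }
  cat_of <- classification$category[match(aln$read_id, classification$read_id)]
  if (anyNA(cat_of) && nrow(aln) > 0) {
    stop("classification table is missing ",
         sum(is.na(cat_of)), " read id(s)")
  }
  if (is.null(categories)) categories <- sort(unique(classification$category))
  paths <- character(0)
  for (cc in categories) {
    path <- file.path(out_dir, paste0(prefix, "_", cc, ".sam"))
    writeLines(c(header, alignments_to_sam_lines(aln[which(cat_of == cc), ,
                                                     drop = FALSE])), path)
    paths[cc] <- path
  }
  invisible(paths)
}

#' Read gene annotations from GFF3
#'
#' @param path Path to a GFF3 file.
#' @param feature_type GFF3 feature type to keep (default \code{"gene"}).
#' @param id_attribute Attribute holding the gene identifier (default
#'   \code{"ID"}).
#' @return data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand} (1-based closed intervals).
#' @export
read_gene_annotation <- function(path, feature_type = "gene",
                                 id_attribute = "ID") {
  gff <- rtracklayer::readGFF(path)
  keep <- as.character(gff$type) == feature_type
  gff <- gff[keep, , drop = FALSE]
  ids <- as.character(gff[[id_attribute]])
  if (is.null(ids) || all(is.na(ids))) {
    ids <- paste0(feature_type, "_", seq_len(nrow(gff)))
  }
  data.frame(gene_id = ids,
             chrom = as.character(gff$seqid),
             start = as.integer(gff$start),
             end = as.integer(gff$end),
             strand = as.character(gff$strand),
             stringsAsFactors = FALSE)
}

#' Read a DMR table
#'
#' Reads a TSV of tested differentially methylated regions in the export
#' shape of dmrseq: columns \code{seqnames,start,end,stat,pval,qval} (a
#' \code{context} column is carried through when present). Column names can
#' be remapped via \code{col_map}.
#'
#' @param path Path to a tab-separated file with header.
#' @param col_map Named character vector mapping internal names
#'   (\code{chrom,start,end,stat,qvalue,context}) to file column names.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{stat}, \code{qvalue} and, if available, \code{context}.
#' @export
read_dmr_table <- function(path,
                           col_map = c(chrom = "seqnames", start = "start",
                                       end = "end", stat = "stat",
                                       qvalue = "qval", context = "context")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!col_map[["qvalue"]] %in% names(tab)) {
    stop("DMR table is missing the q-value column '", col_map[["qvalue"]], "'")
  }
  out <- data.frame(chrom = as.character(tab[[col_map[["chrom"]]]]),
                    start = as.integer(tab[[col_map[["start"]]]]),
                    end = as.integer(tab[[col_map[["end"]]]]),
                    qvalue = as.numeric(tab[[col_map[["qvalue"]]]]),
                    stringsAsFactors = FALSE)
  if (col_map[["stat"]] %in% names(tab)) {
    out$stat <- as.numeric(tab[[col_map[["stat"]]]])
  }
  if (col_map[["context"]] %in% names(tab)) {
    out$context <- as.character(tab[[col_map[["context"]]]])
  }
  if (any(out$start > out$end)) stop("DMR with start > end")
  if (any(out$qvalue < 0 | out$qvalue > 1, na.rm = TRUE)) {
    stop("q-values must lie in [0, 1]")
  }
  out
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with columns \code{read_id}, \code{seq},
#'   \code{qual}.
#' @param path Output FASTQ path.
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$seq,
                           "+", reads$qual))
  writeLines(lines, path)
  invisible(path)
}
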