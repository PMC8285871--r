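#' Configuration for the WGBS allopolyploid read simulator
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe a
#' small but realistic benchmark: two colinear parental genomes at 1 per-cent
#' per-site divergence (between the highly similar Arabidopsis-like regime
#' and more diverged pairs), plant-like methylation levels by context,
#' near-complete bisulfite conversion, and error-bearing 150 bp reads at a
#' constant Phred quality of 30 (a 0.1 per-cent nominal error; the injected
#' per-base error rate is set separately).
#'
#' @param genome_length Length of each chromosome in bp.
#' @param n_chroms Number of chromosomes per genome.
#' @param gc_content GC fraction of the ancestral sequence.
#' @param divergence Per-site substitution probability between the parents.
#' @param meth_levels Named numeric vector of per-context methylation
#'   probabilities (\code{CG}, \code{CHG}, \code{CHH}).
#' @param conversion Probability that an unmethylated cytosine reads as T.
#' @param meth_protection Probability that a methylated cytosine resists
#'   conversion (default 1).
#' @param read_length Read length in bp.
#' @param n_reads Number of read units: total when \code{origin} is
#'   \code{"both"}, \code{"parent1"} or \code{"parent2"}; per parent when
#'   \code{origin = "each"}.
#' @param base_error Per-base sequencing error probability, applied after
#'   conversion.
#' @param phred_q Constant Phred quality emitted for every base.
#' @param paired Paired-end reads?
#' @param insert_mean,insert_sd Fragment-size distribution for paired mode.
#' @param origin Genome of origin: \code{"both"} (50/50 allopolyploid mix),
#'   \code{"parent1"}, \code{"parent2"}, or \code{"each"} (the
#'   progenitor-benchmark design, \code{n_reads} from each parent).
#' @param site_fixed If \code{TRUE}, each cytosine's methylation state is
#'   drawn once per site and shared by all reads; otherwise states are drawn
#'   per read (cell-population heterogeneity).
#' @param seed Integer seed; identical configurations and seeds give
#'   byte-identical outputs.
#' @return A \code{sim_config} object (list).
#' @export
sim_config <- function(genome_length = 100000L, n_chroms = 1L,
                       gc_content = 0.36, divergence = 0.01,
                       meth_levels = c(CG = 0.8, CHG = 0.4, CHH = 0.05),
                       conversion = 0.99, meth_protection = 1.0,
                       read_length = 150L, n_reads = 5000L,
                       base_error = 0.01, phred_q = 30L, paired = FALSE,
                       insert_mean = 300, insert_sd = 25,
                       origin = c("both", "parent1", "parent2", "each"),
                       site_fixed = FALSE, seed = 1L) {
  origin <- match.arg(origin)
  probs <- c(gc_content, divergence, meth_levels, conversion,
             meth_protection, base_error)
  stopifnot(all(probs >= 0 & probs <= 1),
            genome_length > 0, n_chroms > 0, read_length > 0, n_reads >= 0,
            phred_q >= 0,
            all(c("CG", "CHG", "CHH") %in% names(meth_levels)))
  if (read_length > genome_length) {
    stop("read_length exceeds chromosome length")
  }
  structure(list(genome_length = as.integer(genome_length),
                 n_chroms = as.integer(n_chroms), gc_content = gc_content,
                 divergence = divergence, meth_levels = meth_levels,
                 conversion = conversion, meth_protection = meth_protection,
                 read_length = as.integer(read_length),
                 n_reads = as.integer(n_reads), base_error = base_error,
                 phred_q = as.integer(phred_q), paired = paired,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 origin = origin, site_fixed = site_fixed,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# draw bases from {A,C,G,T} with GC-controlled composition from uniforms
draw_bases <- function(u, gc) {
  br <- c(0, (1 - gc) / 2, (1 - gc) / 2 + gc / 2, 1 - (1 - gc) / 2, 1)
  c("A", "C", "G", "T")[findInterval(u, br, rightmost.closed = TRUE)]
}

#' Generate two colinear diverged parental genomes
#'
#' Samples an ancestral sequence at the configured GC content; parent 1 is
#' the ancestor, parent 2 differs at Bernoulli(\code{divergence}) sites by a
#' uniform choice among the three alternative bases. The genomes are colinear
#' (substitutions only), so cross-genome coordinates are identical.
#'
#' Sets the RNG seed from \code{cfg$seed}; called inside
#' \code{\link{simulate_reads}} with the stream already seeded.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param .seeded Internal: skip re-seeding when part of a larger simulation.
#' @return List with \code{genome1}, \code{genome2} (\code{genome_seq}) and
#'   \code{sites}: a data.frame of divergent sites (\code{chrom},
#'   \code{pos}, \code{base1}, \code{base2}).
#' @export
make_parent_genomes <- function(cfg, .seeded = FALSE) {
  if (!.seeded) set.seed(cfg$seed)
  L <- cfg$genome_length
  alt <- matrix(c("C", "G", "T",   # alternatives to A
                  "A", "G", "T",   # to C
                  "A", "C", "T",   # to G
                  "A", "C", "G"),  # to T
                nrow = 4, byrow = TRUE,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  seq1 <- character(cfg$n_chroms)
  seq2 <- character(cfg$n_chroms)
  sites <- vector("list", cfg$n_chroms)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  for (k in seq_len(cfg$n_chroms)) {
    b1 <- draw_bases(stats::runif(L), cfg$gc_content)
    u_div <- stats::runif(L)
    u_alt <- stats::runif(L)     # always drawn: keeps streams comparable
    hit <- which(u_div < cfg$divergence)
    b2 <- b1
    if (length(hit)) {
      pick <- pmin(floor(u_alt[hit] * 3) + 1, 3)
      b2[hit] <- alt[cbind(match(b1[hit], rownames(alt)), pick)]
    }
    seq1[k] <- paste(b1, collapse = "")
    seq2[k] <- paste(b2, collapse = "")
    sites[[k]] <- data.frame(chrom = rep(chroms[k], length(hit)), pos = hit,
                             base1 = b1[hit], base2 = b2[hit],
                             stringsAsFactors = FALSE)
  }
  names(seq1) <- chroms
  names(seq2) <- chroms
  list(genome1 = genome_seq(seq1, "parent1"),
       genome2 = genome_seq(seq2, "parent2"),
       sites = do.call(rbind, sites))
}

#' Build a per-cytosine methylome for one genome
#'
#' Assigns each reference cytosine (both strands) its context-specific
#' methylation parameter. In the default per-read mode the value is the
#' probability with which each read draws that cytosine methylated; in
#' site-fixed mode a 0/1 state is drawn once per site.
#'
#' @param genome A \code{genome_seq}.
#' @param cfg A \code{\link{sim_config}} (uses \code{meth_levels} and
#'   \code{site_fixed}).
#' @param .seeded Internal: skip re-seeding.
#' @return A \code{methylome} object: per chromosome, numeric vectors
#'   \code{fwd} and \code{rev} of length equal to the chromosome, holding the
#'   methylation probability (or fixed 0/1 state) at cytosine positions and
#'   \code{NA} elsewhere. The \code{table} attribute maps it back to a tidy
#'   per-cytosine data.frame.
#' @export
make_methylome <- function(genome, cfg, .seeded = FALSE) {
  if (!.seeded) set.seed(cfg$seed)
  cyt <- all_reference_cytosines(genome)
  ctx <- suppressWarnings(assign_context(genome, cyt$chrom, cyt$pos,
                                         cyt$strand))
  p <- unname(cfg$meth_levels[ctx$context])
  p[is.na(ctx$context)] <- 0   # undefined context: never methylated
  if (cfg$site_fixed) {
    p <- as.numeric(stats::runif(length(p)) < p)
  }
  maps <- lapply(names(genome$seq), function(ch) {
    L <- genome$lengths[[ch]]
    fwd <- rep(NA_real_, L)
    rev <- rep(NA_real_, L)
    sel_f <- cyt$chrom == ch & cyt$strand == "+"
    sel_r <- cyt$chrom == ch & cyt$strand == "-"
    fwd[cyt$pos[sel_f]] <- p[sel_f]
    rev[cyt$pos[sel_r]] <- p[sel_r]
    list(fwd = fwd, rev = rev)
  })
  names(maps) <- names(genome$seq)
  structure(maps,
            table = data.frame(cyt, context = ctx$context, level = p,
                               stringsAsFactors = FALSE),
            site_fixed = cfg$site_fixed, class = "methylome")
}

#' Simulate a truth-labelled WGBS read set from two parental genomes
#'
#' Generates the full synthetic fixture used throughout the package: two
#' diverged colinear parental genomes, context-specific methylomes,
#' bisulfite-converted error-bearing reads with constant Phred qualities, and
#' truth alignments of every read against both parents (coordinate-identical
#' because the genomes are colinear). Conversion is applied first, sequencing
#' error second. Reads from the C-to-T converted strand are emitted on the
#' forward strand (SAM flag 0); reads from the G-to-A strand carry flag 16
#' and report reverse-strand cytosines.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return List with \code{genome1}, \code{genome2}, \code{sites},
#'   \code{methylome1}, \code{methylome2}, \code{reads} (FASTQ-shaped
#'   data.frame), \code{sam1}, \code{sam2} (alignment tables against each
#'   parent), \code{truth} (read_id, true_label, chrom, pos, strand,
#'   bs_strand, n_meth_c, meth_states) and \code{cfg}.
#' @export
simulate_reads <- function(cfg) {
  set.seed(cfg$seed)
  g <- make_parent_genomes(cfg, .seeded = TRUE)
  meth1 <- make_methylome(g$genome1, cfg, .seeded = TRUE)
  meth2 <- make_methylome(g$genome2, cfg, .seeded = TRUE)

  n_units <- if (cfg$origin == "each") 2L * cfg$n_reads else cfg$n_reads
  rl <- cfg$read_length
  chroms <- names(g$genome1$seq)
  weights <- pmax(g$genome1$lengths - rl + 1L, 0L)
  if (all(weights == 0)) stop("read_length exceeds every chromosome length")

  # fixed-layout RNG: geometry first, then per-base draws; each block always
  # consumes the same number of uniforms for a given geometry, so read sets
  # differing only in methylation/conversion/error settings share positions
  u_origin <- stats::runif(n_units)
  u_chrom <- stats::runif(n_units)
  u_pos <- stats::runif(n_units)
  u_strand <- stats::runif(n_units)
  insert <- if (cfg$paired) {
    pmax(round(stats::rnorm(n_units, cfg$insert_mean, cfg$insert_sd)),
         rl)
  } else {
    rep(0L, n_units)
  }

  origin <- switch(cfg$origin,
                   both = ifelse(u_origin < 0.5, 1L, 2L),
                   parent1 = rep(1L, n_units),
                   parent2 = rep(2L, n_units),
                   each = rep(c(1L, 2L), each = cfg$n_reads))
  cw <- cumsum(weights / sum(weights))
  chrom_idx <- findInterval(u_chrom, c(0, cw), rightmost.closed = TRUE)
  chrom <- chroms[chrom_idx]
  span <- if (cfg$paired) insert else rl
  maxstart <- pmax(g$genome1$lengths[chrom_idx] - span + 1L, 1L)
  pos <- as.integer(pmin(floor(u_pos * maxstart) + 1, maxstart))
  bs <- ifelse(u_strand < 0.5, "CT", "GA")
  read_id <- sprintf("read%06d", seq_len(n_units))

  # expand to mates
  if (cfg$paired) {
    m_unit <- rep(seq_len(n_units), each = 2L)
    mate <- rep(c(1L, 2L), n_units)
    m_pos <- as.integer(ifelse(mate == 1L, pos[m_unit],
                               pos[m_unit] + insert[m_unit] - rl))
  } else {
    m_unit <- seq_len(n_units)
    mate <- rep(1L, n_units)
    m_pos <- pos
  }
  n_recs <- length(m_unit)
  m_chrom <- chrom[m_unit]
  m_bs <- bs[m_unit]
  m_origin <- origin[m_unit]

  # per-base vectors over all records
  tmpl_str <- ifelse(m_origin == 1L,
                     substring(g$genome1$seq[m_chrom], m_pos, m_pos + rl - 1L),
                     substring(g$genome2$seq[m_chrom], m_pos, m_pos + rl - 1L))
  tmpl <- strsplit(paste(tmpl_str, collapse = ""), "")[[1]]
  nb <- n_recs * rl
  rec_of <- rep.int(seq_len(n_recs), rep.int(rl, n_recs))
  abspos <- rep.int(m_pos, rep.int(rl, n_recs)) + (seq_len(nb) - 1L) %% rl
  bs_b <- rep.int(m_bs, rep.int(rl, n_recs))
  origin_b <- rep.int(m_origin, rep.int(rl, n_recs))
  chrom_b <- rep.int(m_chrom, rep.int(rl, n_recs))

  u_meth <- stats::runif(nb)
  u_conv <- stats::runif(nb)
  u_err <- stats::runif(nb)
  u_sub <- stats::runif(nb)

  is_c <- (bs_b == "CT" & tmpl == "C") | (bs_b == "GA" & tmpl == "G")
  p_meth <- rep(0, nb)
  for (gi in 1:2) {
    mm <- if (gi == 1) meth1 else meth2
    for (ch in chroms) {
      self <- is_c & origin_b == gi & chrom_b == ch
      if (!any(self)) next
      fsel <- self & bs_b == "CT"
      rsel <- self & bs_b == "GA"
      p_meth[fsel] <- mm[[ch]]$fwd[abspos[fsel]]
      p_meth[rsel] <- mm[[ch]]$rev[abspos[rsel]]
    }
  }
  p_meth[is.na(p_meth)] <- 0
  meth_state <- is_c & (u_meth < p_meth)
  conv_prob <- ifelse(meth_state, 1 - cfg$meth_protection, cfg$conversion)
  converted <- is_c & (u_conv < conv_prob)

  out <- tmpl
  out[converted & bs_b == "CT"] <- "T"
  out[converted & bs_b == "GA"] <- "A"

  err <- u_err < cfg$base_error
  if (any(err)) {
    alt <- matrix(c("C", "G", "T",
                    "A", "G", "T",
                    "A", "C", "T",
                    "A", "C", "G"), nrow = 4, byrow = TRUE,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    pick <- pmin(floor(u_sub[err] * 3) + 1, 3)
    out[err] <- alt[cbind(match(out[err], rownames(alt)), pick)]
  }

  seq_all <- paste(out, collapse = "")
  seqs <- substring(seq_all, (seq_len(n_recs) - 1L) * rl + 1L,
                    seq_len(n_recs) * rl)
  qual <- strrep(rawToChar(as.raw(cfg$phred_q + 33L)), rl)

  rec_id <- read_id[m_unit]
  flag <- (if (cfg$paired) 1L + ifelse(mate == 1L, 64L, 128L) else 0L) +
    ifelse(m_bs == "GA", 16L, 0L)

  # per-read true methylation states at template cytosines, as
  # "relpos:state" strings (truth for methylation-level checks)
  relpos <- (seq_len(nb) - 1L) %% rl + 1L
  ms <- rep("", n_recs)
  if (any(is_c)) {
    enc <- paste0(relpos[is_c], ":", as.integer(meth_state[is_c]))
    ms_list <- split(enc, rec_of[is_c])
    ms[as.integer(names(ms_list))] <-
      vapply(ms_list, paste, character(1), collapse = ",")
  }

  mk_sam <- function(genome) {
    aln <- data.frame(
      read_id = rec_id, flag = flag, mate = mate, chrom = m_chrom,
      pos = m_pos, strand = ifelse(m_bs == "GA", "-", "+"),
      mapq = 255L, cigar = paste0(rl, "M"), seq = seqs,
      qual = rep(qual, n_recs), bs_strand = m_bs, mapped = TRUE,
      secondary = FALSE, genome_label = genome$label,
      stringsAsFactors = FALSE
    )
    attr(aln, "sam_header") <- default_sam_header(genome)
    aln
  }

  truth <- data.frame(
    read_id = read_id,
    true_label = c("parent1", "parent2")[origin],
    chrom = chrom, pos = pos, strand = ifelse(bs == "GA", "-", "+"),
    bs_strand = bs, stringsAsFactors = FALSE
  )
  # store per-record methylation truth at unit level (mate 1 for pairs)
  truth$meth_states <- ms[match(seq_len(n_units), m_unit)]

  fq_id <- if (cfg$paired) paste0(rec_id, "/", mate) else rec_id
  reads <- data.frame(read_id = fq_id, seq = seqs,
                      qual = rep(qual, n_recs), stringsAsFactors = FALSE)

  list(genome1 = g$genome1, genome2 = g$genome2, sites = g$sites,
       methylome1 = meth1, methylome2 = meth2, reads = reads,
       sam1 = mk_sam(g$genome1), sam2 = mk_sam(g$genome2),
       truth = truth, cfg = cfg)
}

#' Write a simulation fixture to disk
#'
#' Writes \code{parent1.fa}, \code{parent2.fa}, \code{reads.fastq},
#' \code{parent1.sam}, \code{parent2.sam}, \code{truth.tsv} and
#' \code{divergent_sites.tsv} into a directory.
#'
#' @param sim Result of \code{\link{simulate_reads}}.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_sim <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    parent1_fa = file.path(out_dir, "parent1.fa"),
    parent2_fa = file.path(out_dir, "parent2.fa"),
    fastq = file.path(out_dir, "reads.fastq"),
    sam1 = file.path(out_dir, "parent1.sam"),
    sam2 = file.path(out_dir, "parent2.sam"),
    truth = file.path(out_dir, "truth.tsv"),
    sites = file.path(out_dir, "divergent_sites.tsv")
  )
  write_genome_fasta(sim$genome1, paths["parent1_fa"])
  write_genome_fasta(sim$genome2, paths["parent2_fa"])
  write_fastq(sim$reads, paths["fastq"])
  writeLines(c(attr(sim$sam1, "sam_header"),
               alignments_to_sam_lines(sim$sam1)), paths["sam1"])
  writeLines(c(attr(sim$sam2, "sam_header"),
               alignments_to_sam_lines(sim$sam2)), paths["sam2"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$sites, paths["sites"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
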