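test_that("deduplication keeps one read unit per position key", {
  a <- rbind(make_aln("r1", pos = 10), make_aln("r2", pos = 10),
             make_aln("r3", pos = 10, strand = "-", bs_strand = "GA",
                      flag = 16L),
             make_aln("r4", pos = 20), make_aln("r5", pos = 20))
  d <- deduplicate_alignments(a)
  # same (chrom,pos,strand) collapses; opposite strand survives
  expect_identical(d$read_id, c("r1", "r3", "r4"))

  # 5 reads, 3 distinct keys -> 3 kept (first one per key, stable)
  a2 <- rbind(make_aln("a", pos = 1), make_aln("b", pos = 1),
              make_aln("c", pos = 2), make_aln("d", pos = 2),
              make_aln("e", pos = 3))
  expect_identical(deduplicate_alignments(a2)$read_id, c("a", "c", "e"))
})

test_that("paired-end duplicates are keyed on outer pair coordinates", {
  pair <- function(id, p1, p2) {
    rbind(make_aln(id, pos = p1, flag = 65L, mate = 1L),
          make_aln(id, pos = p2, flag = 129L, mate = 2L))
  }
  a <- rbind(pair("x", 10, 100), pair("y", 10, 100), pair("z", 10, 90))
  d <- deduplicate_alignments(a)
  expect_setequal(unique(d$read_id), c("x", "z"))
  expect_identical(nrow(d), 4L)
})

test_that("context assignment follows the CG/CHG/CHH definition", {
  g <- genome_seq(c(chr1 = "CGTCAGCTTACG"), "p1")
  expect_identical(assign_context(g, "chr1", 1, "+")$context, "CG")
  expect_identical(assign_context(g, "chr1", 1, "+")$tri, "CGT")
  expect_identical(assign_context(g, "chr1", 4, "+")$context, "CHG")
  expect_identical(assign_context(g, "chr1", 4, "+")$tri, "CAG")
  expect_identical(assign_context(g, "chr1", 7, "+")$context, "CHH")
  expect_identical(assign_context(g, "chr1", 7, "+")$tri, "CTT")

  # reverse strand: forward "ACG" puts a minus-strand C at the G;
  # its 5'->3' triplet is the reverse complement ending there
  g2 <- genome_seq(c(chr1 = "TACGA"), "p1")
  res <- assign_context(g2, "chr1", 4, "-")
  expect_identical(res$tri, "CGT")
  expect_identical(res$context, "CG")

  # non-cytosine position is a contract violation
  expect_error(assign_context(g2, "chr1", 2, "+"), "not a cytosine")
  # triplet running off the chromosome start has undefined context
  g3 <- genome_seq(c(chr1 = "GTACGA"), "p1")
  expect_warning(res <- assign_context(g3, "chr1", 1, "-"), "undefined")
  expect_true(is.na(res$context))
})

test_that("methylation calls follow the conversion rules per strand", {
  g <- genome_seq(c(chr1 = "ACGTAGGA"), "p1")
  # CT read over the reference C: read T = unmethylated, read C = methylated
  aln_t <- make_aln(seq = "ATGTAGGA", bs_strand = "CT")
  m <- extract_methylation(aln_t, g)
  row <- m[m$pos == 2 & m$strand == "+", ]
  expect_identical(row$n_meth, 0L)
  expect_identical(row$n_unmeth, 1L)

  aln_c <- make_aln(seq = "ACGTAGGA", bs_strand = "CT")
  m <- extract_methylation(aln_c, g)
  row <- m[m$pos == 2 & m$strand == "+", ]
  expect_identical(row$n_meth, 1L)
  expect_identical(row$n_unmeth, 0L)

  # GA read reports reverse-strand cytosines at reference G positions
  aln_g <- make_aln(seq = "ACGTAAGA", bs_strand = "GA", flag = 16L,
                    strand = "-")
  m <- extract_methylation(aln_g, g)
  expect_true(all(m$strand == "-"))
  p6 <- m[m$pos == 6, ]  # read A over ref G: unmethylated
  expect_identical(p6$n_unmeth, 1L)
  p3 <- m[m$pos == 3, ]  # read G over ref G: methylated
  expect_identical(p3$n_meth, 1L)

  # CT reads never report reference-G cytosines
  m <- extract_methylation(aln_t, g)
  expect_true(all(m$strand == "+"))
})

test_that("overlapping mate segments are counted once", {
  g <- genome_seq(c(chr1 = "AACGTACGTACGTAA"), "p1")
  a <- rbind(
    make_aln("p", pos = 1, seq = "AACGTACGT", flag = 65L, mate = 1L),
    make_aln("p", pos = 5, seq = "TACGTACGT", flag = 129L, mate = 2L)
  )
  m <- extract_methylation(a, g)
  # position 7 (a C) is covered by both mates but counted once
  expect_identical(m$n_meth[m$pos == 7] + m$n_unmeth[m$pos == 7], 1L)
  # position 11 is covered by mate 2 only
  expect_identical(m$n_meth[m$pos == 11] + m$n_unmeth[m$pos == 11], 1L)
})

test_that("count conservation and context partition hold on simulated data", {
  cfg <- sim_config(genome_length = 10000, n_reads = 400, seed = 11,
                    origin = "parent1")
  sim <- simulate_reads(cfg)
  m <- extract_methylation(sim$sam1, sim$genome1)
  calls <- homeosort:::collect_meth_calls(sim$sam1, sim$genome1)
  ctx <- suppressWarnings(assign_context(sim$genome1, calls$chrom,
                                         calls$pos, calls$strand))
  expect_identical(sum(m$n_meth + m$n_unmeth), sum(!is.na(ctx$context)))
  expect_true(all(m$context %in% c("CG", "CHG", "CHH")))

  # cx_all covers every reference cytosine with defined context
  m_all <- suppressWarnings(extract_methylation(sim$sam1, sim$genome1,
                                                cx_all = TRUE))
  cyt <- homeosort:::all_reference_cytosines(sim$genome1)
  ctx_all <- suppressWarnings(assign_context(sim$genome1, cyt$chrom,
                                             cyt$pos, cyt$strand))
  expect_identical(nrow(m_all), sum(!is.na(ctx_all$context)))
})

test_that("strand symmetry: reverse-complementing the genome preserves counts", {
  cfg <- sim_config(genome_length = 4000, n_reads = 150, seed = 13,
                    origin = "parent1")
  sim <- simulate_reads(cfg)
  m <- extract_methylation(sim$sam1, sim$genome1)

  L <- sim$genome1$lengths[["chr1"]]
  g_rc <- genome_seq(c(chr1 = homeosort:::revcomp(sim$genome1$seq[["chr1"]])),
                     "parent1")
  aln_rc <- sim$sam1
  aln_rc$pos <- L - (aln_rc$pos + nchar(aln_rc$seq) - 1L) + 1L
  aln_rc$seq <- homeosort:::revcomp(aln_rc$seq)
  aln_rc$bs_strand <- ifelse(aln_rc$bs_strand == "CT", "GA", "CT")
  aln_rc$strand <- ifelse(aln_rc$strand == "+", "-", "+")
  m_rc <- extract_methylation(aln_rc, g_rc)

  tab <- function(x) sort(paste(x$context, x$n_meth, x$n_unmeth))
  expect_identical(tab(m_rc), tab(m))
})

test_that("conversion-efficiency estimation counts converted control calls", {
  g <- genome_seq(c(ctrl = "ACCGTACCGT"), "control")
  # all control cytosines read as T: conversion 1.0
  aln <- make_aln(seq = "ATTGTATTGT", chrom = "ctrl",
                  genome_label = "control")
  cr <- conversion_rate(aln, g)
  expect_equal(cr$conversion_rate, 1.0)

  # 990 converted vs 10 unconverted calls -> 0.99
  reads <- do.call(rbind, lapply(1:100, function(i) {
    s <- if (i <= 99) "ATTGTATTGT" else "ACTGTATTGT"
    make_aln(paste0("r", i), seq = s, chrom = "ctrl",
             genome_label = "control")
  }))
  cr <- conversion_rate(reads, g, total_reads = 200)
  # 99 reads fully converted (4 calls each) + 1 read with 1 C retained
  expect_equal(cr$conversion_rate, (400 - 1) / 400)
  expect_equal(cr$mapping_rate, 0.5)

  expect_error(conversion_rate(homeosort:::empty_alignments("control"), g),
               "undefined")
})
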