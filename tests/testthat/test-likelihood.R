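# Frozen expected values, computed by hand from the Phred model
# e = 10^(-q/10); match -> log(1-e); mismatch -> log(e/3).

test_that("per-base log-probabilities follow the bisulfite-aware Phred model", {
  expect_equal(base_log_prob("A", "A", 20, "CT"), log(0.99))
  # C-T on a CT-strand read is a conversion match; a mismatch with BS off
  expect_equal(base_log_prob("C", "T", 20, "CT"), log(0.99))
  expect_equal(base_log_prob("C", "T", 20, "CT", bs_mode = "off"),
               log(0.01 / 3))
  # G-A is only a match for GA reads (or in 'both' mode)
  expect_equal(base_log_prob("G", "A", 30, "CT"), log(0.001 / 3))
  expect_equal(base_log_prob("G", "A", 30, "CT", bs_mode = "both"),
               log(0.999))
  expect_equal(base_log_prob("G", "A", 30, "GA"), log(0.999))
  # N on either side is skipped
  expect_true(is.na(base_log_prob("N", "A", 20, "CT")))
  expect_true(is.na(base_log_prob("A", "N", 20, "CT")))
})

test_that("alignment scores sum per-base terms over the CIGAR", {
  g <- genome_seq(c(chr1 = "ACGTACGTAC"), "p1")
  cfg <- scoring_config()

  aln <- make_aln(seq = "ACGT", q = 20)
  s <- score_alignment(aln, g, cfg)
  expect_equal(s$loglik, 4 * log(0.99))
  expect_identical(s$n_match, 4L)
  expect_identical(s$n_mismatch, 0L)

  # one mismatch at q=30 among matches
  g2 <- genome_seq(c(chr1 = paste(rep("A", 150), collapse = "")), "p1")
  seq <- paste(c(rep("A", 75), "G", rep("A", 74)), collapse = "")
  aln <- make_aln(seq = seq, q = 30, chrom = "chr1")
  s <- score_alignment(aln, g2, cfg)
  expect_equal(s$loglik, 149 * log(0.999) + log(0.001 / 3))
  expect_identical(s$n_mismatch, 1L)

  # CIGAR/read-length inconsistency is an error
  bad <- make_aln(seq = "ACGT", cigar = "5M")
  expect_error(score_alignments(bad, g, cfg), "CIGAR")
})

test_that("fully converted reads score identically to their methylated twin", {
  # reference with cytosines; the converted read turns every C into T
  g <- genome_seq(c(chr1 = "ACGTCCGATCGA"), "p1")
  cfg <- scoring_config(bs_mode = "strand")
  meth <- make_aln(seq = "ACGTCCGATCGA", q = 25)
  conv <- make_aln(seq = gsub("C", "T", "ACGTCCGATCGA"), q = 25)
  s_meth <- score_alignment(meth, g, cfg)
  s_conv <- score_alignment(conv, g, cfg)
  expect_identical(s_conv$loglik, s_meth$loglik)
  expect_identical(s_conv$n_match, s_meth$n_match)
  expect_gt(s_conv$n_bs_match, 0L)
})

test_that("indels, soft clips and N bases are handled by the CIGAR walk", {
  g <- genome_seq(c(chr1 = "AAAACCCCGGGG"), "p1")
  cfg <- scoring_config()
  # 2 soft-clipped, 4 matched, 1 inserted, then 2 matched after a deletion
  aln <- make_aln(seq = "TTAAAAGCC", cigar = "2S4M1I1D2M", pos = 1)
  s <- score_alignment(aln, g, cfg)
  # matched pairs: AAAA vs AAAA, then CC vs CC after deleting ref C
  expect_equal(s$loglik, 6 * log(0.99) + 2 * cfg$indel_logpen)
  expect_identical(s$n_skipped, 3L)  # 2 clipped + 1 inserted

  # N in the read contributes nothing
  alnN <- make_aln(seq = "AANA", pos = 1)
  sN <- score_alignment(alnN, g, cfg)
  expect_equal(sN$loglik, 3 * log(0.99))
  expect_identical(sN$n_skipped, 1L)
})

test_that("vectorised scoring agrees with the brute-force oracle", {
  set.seed(42)
  cfg <- scoring_config()
  g <- genome_seq(c(chr1 = random_seq(5000), chr2 = random_seq(3000)), "p1")
  for (i in 1:100) {
    chrom <- sample(c("chr1", "chr2"), 1)
    len <- sample(20:80, 1)
    pos <- sample(g$lengths[[chrom]] - len, 1)
    # mutate the reference window a little to create mismatches
    window <- substring(g$seq[[chrom]], pos, pos + len - 1)
    bases <- strsplit(window, "")[[1]]
    nmut <- rpois(1, 2)
    if (nmut > 0) {
      at <- sample(len, min(nmut, len))
      bases[at] <- sample(c("A", "C", "G", "T"), length(at), replace = TRUE)
    }
    aln <- make_aln(read_id = paste0("r", i), chrom = chrom, pos = pos,
                    seq = paste(bases, collapse = ""),
                    q = sample(10:40, 1),
                    bs_strand = sample(c("CT", "GA"), 1))
    s <- score_alignment(aln, g, cfg)
    expect_equal(s$loglik, oracle_score(aln, g, cfg), tolerance = 1e-12)
  }
})

test_that("adding a mismatch strictly decreases the log-likelihood", {
  g <- genome_seq(c(chr1 = paste(rep("A", 60), collapse = "")), "p1")
  cfg <- scoring_config()
  base <- strsplit(paste(rep("A", 50), collapse = ""), "")[[1]]
  prev <- score_alignment(make_aln(seq = paste(base, collapse = "")), g,
                          cfg)$loglik
  for (k in c(5, 10, 25)) {
    mut <- base
    mut[seq_len(k)] <- "G"
    ll <- score_alignment(make_aln(seq = paste(mut, collapse = "")), g,
                          cfg)$loglik
    expect_lt(ll, prev)
    prev <- ll
  }
})

test_that("scoring is invariant under reverse-complement with strand swap", {
  set.seed(7)
  cfg <- scoring_config()
  for (i in 1:20) {
    refwin <- random_seq(40)
    g_f <- genome_seq(c(chr1 = refwin), "p")
    g_r <- genome_seq(c(chr1 = homeosort:::revcomp(refwin)), "p")
    bases <- strsplit(refwin, "")[[1]]
    at <- sample(40, 3)
    bases[at] <- sample(c("A", "C", "G", "T"), 3, replace = TRUE)
    read_f <- paste(bases, collapse = "")
    read_r <- homeosort:::revcomp(read_f)
    bs <- sample(c("CT", "GA"), 1)
    bs_swap <- ifelse(bs == "CT", "GA", "CT")
    s_f <- score_alignment(make_aln(seq = read_f, bs_strand = bs), g_f, cfg)
    s_r <- score_alignment(make_aln(seq = read_r, bs_strand = bs_swap,
                                    strand = "-"), g_r, cfg)
    expect_equal(s_r$loglik, s_f$loglik, tolerance = 1e-12)
  }
})
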