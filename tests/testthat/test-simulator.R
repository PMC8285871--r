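test_that("divergence controls the substitution count between parents", {
  g0 <- make_parent_genomes(sim_config(genome_length = 2000, divergence = 0,
                                       seed = 1))
  expect_identical(g0$genome1$seq, setNames(g0$genome2$seq,
                                            names(g0$genome1$seq)))
  expect_identical(nrow(g0$sites), 0L)

  g1 <- make_parent_genomes(sim_config(genome_length = 500, divergence = 1,
                                       seed = 1))
  expect_identical(nrow(g1$sites), 500L)
  expect_true(all(g1$sites$base1 != g1$sites$base2))

  # binomial check at the default divergence
  g <- make_parent_genomes(sim_config(genome_length = 100000,
                                      divergence = 0.01, seed = 1))
  expect_lt(abs(nrow(g$sites) - 1000), 3 * sqrt(1000 * 0.99))
  # listed sites are exactly the positions where the genomes differ
  b1 <- strsplit(g$genome1$seq[[1]], "")[[1]]
  b2 <- strsplit(g$genome2$seq[[1]], "")[[1]]
  expect_identical(which(b1 != b2), g$sites$pos)
})

test_that("methylome levels are context-specific and site-fixed mode is binary", {
  cfg <- sim_config(genome_length = 20000, seed = 2)
  g <- make_parent_genomes(cfg)
  mm <- make_methylome(g$genome1, cfg)
  tab <- attr(mm, "table")
  lv <- tapply(tab$level, tab$context, unique)
  expect_equal(lv[["CG"]], 0.8)
  expect_equal(lv[["CHG"]], 0.4)
  expect_equal(lv[["CHH"]], 0.05)

  cfg_f <- sim_config(genome_length = 20000, seed = 2, site_fixed = TRUE)
  mf <- make_methylome(g$genome1, cfg_f)
  tf <- attr(mf, "table")
  expect_true(all(tf$level %in% c(0, 1)))
  # fixed CHH states are rare, CG states common
  expect_lt(mean(tf$level[which(tf$context == "CHH")]), 0.15)
  expect_gt(mean(tf$level[which(tf$context == "CG")]), 0.6)
})

test_that("conversion and error rules compose as specified", {
  # no methylation, full conversion, no errors: every template C on a CT
  # read is read as T, every template G on a GA read as A
  cfg <- sim_config(genome_length = 5000, n_reads = 100, seed = 3,
                    meth_levels = c(CG = 0, CHG = 0, CHH = 0),
                    conversion = 1, base_error = 0)
  sim <- simulate_reads(cfg)
  tmpl_of <- function(i) {
    gn <- if (sim$truth$true_label[i] == "parent1") sim$genome1 else
      sim$genome2
    substring(gn$seq[[sim$sam1$chrom[i]]], sim$sam1$pos[i],
              sim$sam1$pos[i] + cfg$read_length - 1)
  }
  for (i in c(1, 25, 50, 100)) {
    tmpl <- tmpl_of(i)
    expected <- if (sim$sam1$bs_strand[i] == "CT") gsub("C", "T", tmpl) else
      gsub("G", "A", tmpl)
    expect_identical(sim$sam1$seq[i], expected)
  }

  # full methylation with full protection: reads equal the template
  cfg2 <- sim_config(genome_length = 5000, n_reads = 50, seed = 3,
                     meth_levels = c(CG = 1, CHG = 1, CHH = 1),
                     conversion = 1, meth_protection = 1, base_error = 0)
  sim2 <- simulate_reads(cfg2)
  for (i in c(1, 20, 50)) {
    gn <- if (sim2$truth$true_label[i] == "parent1") sim2$genome1 else
      sim2$genome2
    tmpl <- substring(gn$seq[[sim2$sam1$chrom[i]]], sim2$sam1$pos[i],
                      sim2$sam1$pos[i] + cfg2$read_length - 1)
    expect_identical(sim2$sam1$seq[i], tmpl)
  }
})

test_that("simulated fixtures are internally consistent", {
  cfg <- sim_config(genome_length = 8000, n_reads = 200, seed = 5,
                    origin = "both")
  sim <- simulate_reads(cfg)
  expect_identical(nrow(sim$truth), 200L)
  expect_identical(nrow(sim$reads), 200L)
  expect_identical(sim$sam1$read_id, sim$sam2$read_id)
  expect_identical(sim$sam1$pos, sim$sam2$pos)  # colinear coordinates
  expect_identical(sim$sam1$seq, sim$sam2$seq)
  expect_true(all(sim$truth$true_label %in% c("parent1", "parent2")))

  # paired mode: two records per unit, one truth row
  cfgp <- sim_config(genome_length = 8000, n_reads = 100, seed = 5,
                     paired = TRUE)
  simp <- simulate_reads(cfgp)
  expect_identical(nrow(simp$sam1), 200L)
  expect_identical(nrow(simp$reads), 200L)
  expect_identical(nrow(simp$truth), 100L)
  expect_identical(sum(simp$sam1$mate == 1L), 100L)

  # origin="each" emits n_reads per parent
  cfge <- sim_config(genome_length = 8000, n_reads = 50, seed = 5,
                     origin = "each")
  sime <- simulate_reads(cfge)
  expect_identical(as.vector(table(sime$truth$true_label)), c(50L, 50L))
})

test_that("identical configuration and seed give byte-identical outputs", {
  cfg <- sim_config(genome_length = 5000, n_reads = 100, seed = 7)
  d1 <- tempfile()
  d2 <- tempfile()
  write_sim(simulate_reads(cfg), d1)
  write_sim(simulate_reads(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
  # written SAM round-trips through the reader
  g1 <- read_genome_fasta(file.path(d1, "parent1.fa"), "parent1")
  aln <- read_sam(file.path(d1, "parent1.sam"), g1)
  sim <- simulate_reads(cfg)
  expect_identical(aln$read_id, sim$sam1$read_id)
  expect_identical(aln$pos, sim$sam1$pos)
  expect_identical(aln$seq, sim$sam1$seq)
  expect_identical(aln$bs_strand, sim$sam1$bs_strand)
})

test_that("truth SAM rescoring matches downstream scores (self-consistency)", {
  cfg <- sim_config(genome_length = 6000, n_reads = 100, seed = 8)
  sim <- simulate_reads(cfg)
  cfg_s <- scoring_config()
  direct <- score_alignments(sim$sam1, sim$genome1, cfg_s)
  d <- tempfile()
  write_sim(sim, d)
  reread <- score_alignments(
    read_sam(file.path(d, "parent1.sam"),
             read_genome_fasta(file.path(d, "parent1.fa"), "parent1")),
    sim$genome1, cfg_s)
  expect_identical(reread$loglik, direct$loglik)
})
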