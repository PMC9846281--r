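test_that("the genome generator is deterministic and layout-faithful", {
  s1 <- generate_mitogenome(genome_spec(seed = 5))
  s2 <- generate_mitogenome(genome_spec(seed = 5))
  expect_identical(s1$genome$seq, s2$genome$seq)
  s3 <- generate_mitogenome(genome_spec(seed = 6))
  expect_false(identical(s1$genome$seq, s3$genome$seq))
  expect_equal(s1$genome$length, 16592L)
  cls <- table(s1$genome$features$cls)
  expect_equal(cls[["PCG"]], 13L)
  expect_equal(cls[["tRNA"]], 22L)
  expect_equal(cls[["rRNA"]], 2L)
})

test_that("characterising a generated genome recovers every planted truth", {
  sim <- generate_mitogenome(genome_spec(seed = 17))
  gt <- gene_table(sim$genome)
  pcg <- gt$cls == "PCG"
  expect_identical(gt$start_codon[pcg], sim$truth$start_codon[pcg])
  expect_identical(gt$stop_codon[pcg], sim$truth$stop_codon[pcg])
  expect_identical(gt$strand, sim$truth$strand)
  expect_identical(gt$spacer_to_next, sim$truth$spacer_to_next)
  # planted overlap structure shows up in the summary
  s <- spacer_summary(sim$genome)
  expect_equal(s$n_overlaps, 10L)
  expect_equal(s$overlap_max, 7L)
  expect_equal(s$n_ign, 17L)
  # no internal stop was planted in any coding gene
  for (i in which(pcg)) {
    u <- codon_counts(feature_sequence(sim$genome, i))
    expect_equal(u$n_stops_excluded,
                 as.integer(gt$stop_codon[i] %in% c("TAA", "TAG")))
  }
})

test_that("realised base composition stays within 3 SE of expectation", {
  for (seed in c(1, 2, 3)) {
    sim <- generate_mitogenome(genome_spec(seed = seed))
    counts <- base_composition(sim$genome$seq)$counts
    z <- (counts - sim$truth$expected_counts) / sim$truth$sd_counts
    expect_true(all(abs(z) < 3), info = paste("seed", seed,
                                              paste(round(z, 2),
                                                    collapse = " ")))
  }
})

test_that("an infeasible layout raises a generation error", {
  lay <- default_genome_layout()
  bad <- lay
  bad$stop_codon[bad$name == "ND1"] <- "T--"  # length is a multiple of 3
  expect_error(genome_spec(layout = bad),
               class = "mitochar_generation_error")
  # two PCGs demanding different bases at the same position
  lay2 <- data.frame(name = c("g1", "g2"), cls = "PCG",
                     start = c(1L, 4L), end = c(9L, 12L), strand = "H",
                     start_codon = "ATG",
                     stop_codon = c("TAA", "TAA"),
                     stringsAsFactors = FALSE)
  expect_error(generate_mitogenome(genome_spec(layout = lay2,
                                               length = 30L)),
               class = "mitochar_generation_error")
})

test_that("alignment simulation is seed-deterministic with exact zero-branch case", {
  s1 <- generate_codon_alignment(alignment_spec(n_taxa = 5, n_codons = 60,
                                                omega = 0.3, seed = 9))
  s2 <- generate_codon_alignment(alignment_spec(n_taxa = 5, n_codons = 60,
                                                omega = 0.3, seed = 9))
  expect_identical(s1$alignment$seqs, s2$alignment$seqs)
  s0 <- generate_codon_alignment(alignment_spec(n_taxa = 5, n_codons = 60,
                                                branch_length = 0,
                                                seed = 9))
  expect_equal(length(unique(s0$alignment$seqs)), 1L)
  expect_equal(s0$truth$n_syn_events + s0$truth$n_nonsyn_events, 0L)
  # simulated sequences never contain a stop codon
  tab <- oracle_code_table()
  stops <- names(tab)[tab == "*"]
  for (s in s1$alignment$seqs) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(cods %in% stops))
  }
})

test_that("realised substitution classes are consistent with omega", {
  # pooled over replicates, the nonsynonymous fraction of realised events
  # should match the rate-matrix expectation to within binomial noise
  for (omega in c(0.2, 1)) {
    syn <- 0; nonsyn <- 0; expected <- NULL
    for (r in 1:20) {
      sim <- generate_codon_alignment(
        alignment_spec(n_taxa = 4, n_codons = 120, omega = omega,
                       branch_length = 0.15, seed = 100 * omega + r))
      syn <- syn + sim$truth$n_syn_events
      nonsyn <- nonsyn + sim$truth$n_nonsyn_events
      expected <- sim$truth$expected_nonsyn_fraction
    }
    n <- syn + nonsyn
    phat <- nonsyn / n
    se <- sqrt(expected * (1 - expected) / n)
    expect_lt(abs(phat - expected), 4 * se)
    # omega < 1 must depress the nonsynonymous share below neutrality
    if (omega < 1) expect_lt(phat, 0.5)
  }
})
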