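test_that("per-codon site counts match direct mutation enumeration", {
  expect_equal(ng86_sites("TTT")[["syn"]], 1 / 3)
  expect_equal(ng86_sites("GTT")[["syn"]], 1)   # fourfold third position
  tab <- oracle_code_table()
  sense <- names(tab)[tab != "*"]
  for (cd in sense) {
    s <- ng86_sites(cd)
    expect_equal(s[["syn"]], oracle_sites(cd, tab), info = cd)
    expect_equal(s[["syn"]] + s[["nonsyn"]], 3)
  }
  expect_error(ng86_sites("TAA"), class = "mitochar_input_error")
  expect_error(ng86_sites("AX"), class = "mitochar_input_error")
})

test_that("pairwise results behave on identical and near-identical pairs", {
  a <- paste(rep("ATGACACTA", 10), collapse = "")
  r <- ng86_pairwise(a, a)
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0)
  expect_false(r$ratio_defined)
  expect_true(is.na(r$ratio))
  # one synonymous third-position change: Ka = 0, Ks > 0
  b100 <- paste(rep("GTA", 100), collapse = "")
  b_mut <- paste0(substr(b100, 1, 296), "G", substr(b100, 298, 300))
  expect_identical(substr(b_mut, 295, 297), "GTG")
  r2 <- ng86_pairwise(b100, b_mut)
  expect_equal(r2$Ka, 0)
  expect_gt(r2$Ks, 0)
  expect_equal(r2$ratio, 0)
  expect_error(ng86_pairwise("ATGAAA", "ATGAAATTT"),
               class = "mitochar_input_error")
})

test_that("site conservation and argument symmetry hold on random pairs", {
  set.seed(41)
  for (rep in 1:30) {
    pr <- random_codon_pair(sample(10:40, 1), p_mut = 0.5)
    r_ab <- ng86_pairwise(pr[1], pr[2])
    r_ba <- ng86_pairwise(pr[2], pr[1])
    expect_equal(r_ab$S + r_ab$N, 3 * r_ab$n_codons)
    for (fld in c("S", "N", "Sd", "Nd", "Ka", "Ks"))
      expect_equal(r_ab[[fld]], r_ba[[fld]], info = fld)
  }
})

test_that("codons with gaps or ambiguity are skipped pairwise", {
  a <- "ATGAAACCC"
  b <- "ATGANACCC"
  r <- ng86_pairwise(a, b)
  expect_equal(r$n_codons, 2L)
  expect_equal(r$n_skipped, 1L)
})

test_that("pairwise Ka/Ks matches the pathway-enumeration oracle", {
  set.seed(42)
  tab <- oracle_code_table()
  for (rep in 1:40) {
    pr <- random_codon_pair(25, p_mut = 0.4, tab = tab)
    mine <- ng86_pairwise(pr[1], pr[2])
    ref <- oracle_ng86(pr[1], pr[2], tab)
    expect_equal(mine$S, ref$S, tolerance = 1e-12)
    expect_equal(mine$Sd, ref$Sd, tolerance = 1e-12)
    expect_equal(mine$Nd, ref$Nd, tolerance = 1e-12)
    expect_equal(mine$Ka, ref$Ka, tolerance = 1e-12)
    expect_equal(mine$Ks, ref$Ks, tolerance = 1e-12)
  }
})

test_that("codon alignments validate rows and trim stop columns", {
  expect_error(codon_alignment(c("ATGAAA", "ATG")),
               class = "mitochar_format_error")
  aln <- codon_alignment(c(t1 = "ATGAAATAA", t2 = "ATGAAGTAG"))
  expect_equal(aln$n_codons, 2L)  # stop column trimmed
  expect_equal(nchar(aln$seqs[[1]]), 6L)
  aln2 <- codon_alignment(c(t1 = "ATGAAATAA", t2 = "ATGAAGAAA"),
                          trim_stops = TRUE)
  expect_equal(aln2$n_codons, 3L)  # not all rows end in a stop: kept
})

test_that("gene aggregation pools pairs as a ratio of mean distances", {
  aln <- codon_alignment(c(a = "ATGACACTA", b = "ATGACACTA",
                           c = "ATGACACTA"), trim_stops = FALSE)
  r <- gene_kaks(aln)
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0)
  expect_false(r$ratio_defined)
  expect_equal(r$n_pairs, 3L)
  sim <- generate_codon_alignment(alignment_spec(n_taxa = 6,
                                                 n_codons = 200,
                                                 omega = 0.1, seed = 2))
  rk <- gene_kaks(sim$alignment)
  expect_lt(rk$ratio, 1)
  expect_equal(nrow(rk$pairs), choose(6, 2))
  # a faster-evolving gene under relaxed constraint ranks above a
  # strongly constrained one
  hi <- gene_kaks(generate_codon_alignment(
    alignment_spec(n_taxa = 6, n_codons = 300, omega = 0.5,
                   seed = 8))$alignment)
  lo <- gene_kaks(generate_codon_alignment(
    alignment_spec(n_taxa = 6, n_codons = 300, omega = 0.05,
                   seed = 8))$alignment)
  expect_gt(hi$ratio, lo$ratio)
})

test_that("alignment FASTA round-trips through write/read", {
  sim <- generate_codon_alignment(alignment_spec(n_taxa = 4,
                                                 n_codons = 30, seed = 4))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_codon_alignment(sim$alignment, fa)
  back <- read_codon_alignment(fa, gene = "simulated",
                               trim_stops = FALSE)
  expect_identical(back$seqs, sim$alignment$seqs)
  expect_identical(back$taxa, sim$alignment$taxa)
})
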