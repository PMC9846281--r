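test_that("feature lengths follow the circular coordinate formula", {
  expect_equal(feature_length(list(start = 2858, end = 3832), 16592), 975L)
  expect_equal(feature_length(list(start = 70, end = 1022), 16592), 953L)
  expect_equal(feature_length(list(start = 5, end = 5), 100), 1L)
  # wrap-around: (L - start + 1) + end
  expect_equal(feature_length(list(start = 16590, end = 3), 16592), 6L)
  expect_error(feature_length(list(start = 0, end = 3), 10),
               class = "mitochar_coordinate_error")
})

test_that("spacers use the gap-to-next convention with circular closure", {
  g <- published_genome()
  f <- g$features
  expect_equal(spacer_to_next(g, which(f$name == "tRNA-Ile")), -2L)
  expect_equal(spacer_to_next(g, which(f$name == "tRNA-Val")), 20L)
  expect_equal(spacer_to_next(g, which(f$name == "16S-rRNA")), 24L)
  expect_equal(spacer_to_next(g, nrow(f)), 0L)  # D-LOOP wraps to tRNA-Phe
  # contiguous features have spacer 0
  g2 <- mito_genome(data.frame(name = c("a", "b"), cls = "tRNA",
                               start = c(10L, 101L), end = c(100L, 150L),
                               strand = "H"), length = 200)
  expect_equal(spacer_to_next(g2, 1), 0L)
  # single feature: self-wrap gap
  g1 <- mito_genome(data.frame(name = "a", cls = "rRNA", start = 11L,
                               end = 40L, strand = "H"), length = 100)
  expect_equal(spacer_to_next(g1, 1), 70L)
})

test_that("codon classification covers complete and incomplete stops", {
  expect_equal(classify_codons("ATGAAATAA")[c("start_codon", "stop_codon")],
               list(start_codon = "ATG", stop_codon = "TAA"))
  gtg <- paste0("GTG", strrep("GCA", 515), "TAA")  # 1,551 bp like COX1
  expect_equal(classify_codons(gtg)$start_codon, "GTG")
  expect_equal(classify_codons(gtg)$stop_codon, "TAA")
  t_rem <- paste0("ATG", strrep("ACA", 229), "T")  # 691 bp like COX2
  expect_equal(nchar(t_rem), 691L)
  cc <- classify_codons(t_rem)
  expect_equal(cc$stop_codon, "T--")
  expect_false(cc$stop_complete)
  expect_equal(classify_codons(paste0("ATGAAAGGGTA"))$stop_codon, "TA-")
  expect_warning(out <- classify_codons("ATGAAACCCAGA"), "not TAA/TAG")
  expect_equal(out$stop_codon, "other")
  expect_warning(out2 <- classify_codons("ATGAAAG"), "not T/TA")
  expect_equal(out2$stop_codon, "other")
  expect_error(classify_codons("ATG"), class = "mitochar_input_error")
})

test_that("the gene table reproduces the published strand distribution", {
  gt <- gene_table(published_genome())
  expect_equal(nrow(gt), 39L)
  pcg <- gt[gt$cls == "PCG", ]
  expect_equal(nrow(pcg), 13L)
  expect_identical(pcg$name[pcg$strand == "L"], "ND6")
  expect_equal(sum(gt$cls == "tRNA" & gt$strand == "L"), 8L)
  # codon columns stay empty without a sequence
  expect_true(all(is.na(gt$start_codon)))
})

test_that("telescoping conservation holds on fixture and random genomes", {
  gt <- gene_table(published_genome())
  expect_equal(sum(gt$length + gt$spacer_to_next), 16592L)
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(2:12, 1)
    L <- 40L * n
    starts <- sort(sample.int(L - 30L, n))
    lens <- sample(5:30, n, replace = TRUE)
    feats <- data.frame(name = paste0("f", seq_len(n)), cls = "tRNA",
                        start = starts, end = starts + lens - 1L,
                        strand = sample(c("H", "L"), n, replace = TRUE))
    g <- mito_genome(feats, length = L)
    gt <- gene_table(g)
    expect_equal(sum(gt$length + gt$spacer_to_next), L)
  }
})

test_that("spacer summary matches the published overlap/IGN statistics", {
  s <- spacer_summary(published_genome())
  expect_equal(s$n_overlaps, 10L)
  expect_equal(s$overlap_min, 1L)
  expect_equal(s$overlap_max, 7L)
  expect_equal(s$n_ign, 17L)
  expect_equal(s$ign_total, 84L)
  expect_equal(s$ign_min, 1L)
  expect_equal(s$ign_max, 24L)
  # counting the control-region flank adds the 16 bp gap upstream of it
  s2 <- spacer_summary(published_genome(), count_dloop_flank = TRUE)
  expect_equal(s2$n_ign, 18L)
  expect_equal(s2$ign_total, 100L)
  expect_true(s$n_overlaps + s$n_ign <= nrow(published_genome()$features))
})

test_that("a perfectly tiled genome has an all-zero spacer summary", {
  g <- mito_genome(data.frame(name = c("a", "b", "c"), cls = "tRNA",
                              start = c(1L, 41L, 81L),
                              end = c(40L, 80L, 120L), strand = "H"),
                   length = 120)
  s <- spacer_summary(g)
  expect_equal(s$n_overlaps, 0L)
  expect_equal(s$n_ign, 0L)
  expect_equal(s$ign_total, 0L)
})

test_that("gene table codon columns agree with the toy genome sequence", {
  gt <- gene_table(toy_genome())
  expect_equal(gt$start_codon[1], "ATG")
  expect_equal(gt$stop_codon[1], "TAA")
  expect_true(is.na(gt$start_codon[2]))  # tRNA rows have no codons
  expect_equal(sum(gt$length + gt$spacer_to_next), 60L)
})
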