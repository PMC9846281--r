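test_that("the packaged annotation parses with the expected structure", {
  g <- published_genome()
  expect_s3_class(g, "mito_genome")
  expect_equal(nrow(g$features), 39L)
  expect_equal(g$length, 16592L)
  expect_equal(sum(g$features$cls == "PCG"), 13L)
  expect_equal(sum(g$features$cls == "tRNA"), 22L)
  expect_equal(sum(g$features$cls == "rRNA"), 2L)
  # coordinates-only genome refuses sequence operations
  expect_error(feature_sequence(g, 1), class = "mitochar_input_error")
  expect_error(partition_composition(g), class = "mitochar_input_error")
})

test_that("feature_sequence orients by strand and wraps the origin", {
  g4 <- mito_genome(data.frame(name = c("h", "l"), cls = "noncoding",
                               start = 1L, end = 4L,
                               strand = c("H", "L")), seq = "ATGC")
  expect_identical(feature_sequence(g4, 1), "ATGC")
  expect_identical(feature_sequence(g4, 2), "GCAT")
  gw <- mito_genome(data.frame(name = "w", cls = "noncoding", start = 9L,
                               end = 2L, strand = "H"),
                    seq = "AAAAATTTTT")
  expect_identical(feature_sequence(gw, 1), "TTAA")
  # brute-force index walk around the circle agrees
  chars <- strsplit(gw$seq, "")[[1]]
  idx <- c(9:10, 1:2)
  expect_identical(feature_sequence(gw, 1), paste(chars[idx],
                                                  collapse = ""))
})

test_that("L-strand extraction is an involution over random features", {
  set.seed(11)
  for (rep in 1:20) {
    L <- sample(30:90, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
    start <- sample.int(L, 1)
    end <- sample.int(L, 1)
    g <- mito_genome(data.frame(name = "f", cls = "noncoding",
                                start = start, end = end, strand = "L"),
                     seq = seq, length = NULL)
    h <- mito_genome(g$features, seq = seq)
    h$features$strand <- "H"
    sense <- feature_sequence(g, 1)
    expect_identical(mitochar:::revcomp(sense), feature_sequence(h, 1))
    expect_identical(mitochar:::revcomp(mitochar:::revcomp(sense)), sense)
  }
})

test_that("feature tables round-trip through write/read exactly", {
  g <- published_genome()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(g, tsv)
  g2 <- read_feature_table(tsv, length = g$length)
  core <- c("name", "cls", "start", "end", "strand", "anticodon")
  expect_identical(g2$features[core], g$features[core])
  expect_identical(g2$length, g$length)
})

test_that("wrap-around and degenerate feature tables are accepted", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tcls\tfrom\tto\tstrand\tanticodon",
               "CR\tnoncoding\t16590\t3\tH\t"), tsv)
  g <- read_feature_table(tsv, length = 16592)
  expect_equal(g$features$start, 16590L)
  expect_equal(g$features$end, 3L)
  expect_equal(feature_length(g$features[1, ], g$length), 6L)
  # empty table: telescoping vacuously true
  writeLines("name\tcls\tfrom\tto\tstrand\tanticodon", tsv)
  g0 <- read_feature_table(tsv, length = 100)
  expect_equal(nrow(g0$features), 0L)
  expect_equal(nrow(gene_table(g0)), 0L)
})

test_that("malformed tables raise classed errors and duplicates warn", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tcls\tfrom\tto\tstrand",
               "x\tgene\t1\t5\tH"), tsv)
  expect_error(read_feature_table(tsv), class = "mitochar_format_error")
  writeLines(c("name\tcls\tfrom\tto\tstrand",
               "x\tPCG\tone\t5\tH"), tsv)
  expect_error(read_feature_table(tsv), class = "mitochar_format_error")
  writeLines(c("name\tcls\tfrom\tto\tstrand",
               "x\ttRNA\t1\t5\tH", "x\ttRNA\t7\t11\tH"), tsv)
  expect_warning(read_feature_table(tsv), "duplicate")
})

test_that("GenBank flat files parse with strand, wrap and name mapping", {
  sim <- generate_mitogenome(genome_spec(seed = 3))
  gb <- withr::local_tempfile(fileext = ".gb")
  write_gb_fixture(sim$genome, gb)
  g <- read_genbank(gb)
  expect_equal(nrow(g$features), 39L)
  expect_equal(sum(g$features$cls == "PCG"), 13L)
  expect_identical(g$features$name, sim$genome$features$name)
  expect_identical(g$features$strand, sim$genome$features$strand)
  expect_identical(g$seq, sim$genome$seq)
  # single plus-strand CDS and a complement location
  tiny <- mito_genome(data.frame(
    name = c("coI", "nad1"), cls = "PCG", start = c(1L, 10L),
    end = c(9L, 30L), strand = c("H", "L")),
    seq = paste(rep("ACGT", 10), collapse = ""))
  write_gb_fixture(tiny, gb)
  gt <- read_genbank(gb)
  expect_identical(gt$features$name, c("COX1", "ND1"))  # synonyms mapped
  expect_equal(gt$features$start, c(1L, 10L))
  expect_equal(gt$features$end, c(9L, 30L))
  expect_identical(gt$features$strand, c("H", "L"))
  # a record without sequence is a format error
  writeLines(c("LOCUS x", "FEATURES", "     CDS             1..9"), gb)
  expect_error(read_genbank(gb), class = "mitochar_format_error")
})

test_that("gene-name normalisation is case-insensitive and extensible", {
  expect_identical(normalize_gene_name(c("COI", "cytb", "NAD4L", "rrnS")),
                   c("COX1", "CYTB", "ND4L", "12S-rRNA"))
  expect_identical(normalize_gene_name("mystery"), "mystery")
  expect_identical(normalize_gene_name("mystery",
                                       extra = c(mystery = "ND2")), "ND2")
})
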