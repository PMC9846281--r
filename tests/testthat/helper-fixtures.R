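# Small fixtures built in code.

fixture_table_path <- function() {
  system.file("extdata", "OP132373_feature_table.tsv",
              package = "mitochar")
}

fixture_composition_path <- function() {
  system.file("extdata", "OP132373_composition.tsv", package = "mitochar")
}

published_genome <- function() read_feature_table(fixture_table_path())

published_table <- function() {
  utils::read.delim(fixture_table_path(), stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}

# Tiny genome with a known sequence for hand-checkable cases.
toy_genome <- function() {
  # 60 bp: a 30-bp PCG (ATG + 8 codons + TAA), a tRNA, the rest spacer
  pcg <- "ATGAAACCCGGGTTTACACTAGACCTATAA"
  trna <- "ACGTACGTACGTACGTACG"
  seq <- paste0(pcg, "TT", trna, substr("AGCTAGCTA", 1, 9))
  mito_genome(data.frame(
    name = c("geneA", "tRNA-X"), cls = c("PCG", "tRNA"),
    start = c(1L, 33L), end = c(30L, 51L), strand = c("H", "H"),
    anticodon = c(NA, "TAC"), stringsAsFactors = FALSE), seq = seq)
}

# Minimal GenBank flat file writer (tests only) so read_genbank can be
# exercised on files with complement() and origin-spanning join().
write_gb_fixture <- function(genome, path, locus = "TESTREC") {
  f <- genome$features
  key_of <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
              noncoding = "D-loop")
  lines <- c(sprintf("LOCUS       %s %d bp DNA circular VRT", locus,
                     genome$length),
             "FEATURES             Location/Qualifiers")
  for (i in seq_len(nrow(f))) {
    loc <- if (f$start[i] <= f$end[i])
      sprintf("%d..%d", f$start[i], f$end[i])
    else sprintf("join(%d..%d,1..%d)", f$start[i], genome$length, f$end[i])
    if (f$strand[i] == "L") loc <- sprintf("complement(%s)", loc)
    key <- key_of[[f$cls[i]]]
    lines <- c(lines, sprintf("     %-16s%s", key, loc),
               sprintf("                     /gene=\"%s\"", f$name[i]))
    if (!is.na(f$anticodon[i]))
      lines <- c(lines, sprintf(
        "                     /anticodon=\"%s\"", f$anticodon[i]))
  }
  lines <- c(lines, "ORIGIN")
  s <- tolower(genome$seq)
  for (off in seq(1, nchar(s), 60)) {
    chunk <- substr(s, off, min(off + 59, nchar(s)))
    grp <- gsub("(.{10})", "\\1 ", chunk)
    lines <- c(lines, sprintf("%9d %s", off, trimws(grp)))
  }
  writeLines(c(lines, "//"), path)
  path
}
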