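#' Genetic-code tables and synonymous codon families
#'
#' `mito_genetic_code()` returns an NCBI translation table as a named
#' character vector (64 DNA codons to one-letter amino acids, `"*"` for
#' stops). The default is table 2, the vertebrate mitochondrial code, in
#' which AGA/AGG are stops, ATA is Met and TGA is Trp.
#'
#' `codon_families()` derives the synonymous codon families used for RSCU
#' from the code table. A family is a connected component of the
#' single-nucleotide-substitution graph restricted to one amino acid's
#' codons: under table 2 the six Leu codons (TTA/TTG/CTN) are mutually
#' reachable and form one family of six, whereas the Ser codons split into
#' the disconnected TCN (Ser1, four codons) and AGY (Ser2, two codons)
#' blocks. When an amino acid yields several components they are numbered
#' by decreasing size (ties by first codon), giving the conventional
#' Ser1/Ser2 labels. Stop codons are never part of a family.
#'
#' @param code NCBI translation table identifier, e.g. `"2"` (vertebrate
#'   mitochondrial, the default) or `"1"` (standard).
#' @return `mito_genetic_code()`: named character vector of length 64.
#'   `codon_families()`: data frame with columns `codon`, `aa` (one-letter),
#'   `family` (label such as `"Leu"` or `"Ser1"`), `family_size`.
#' @examples
#' code <- mito_genetic_code()
#' fam <- codon_families()
#' subset(fam, family == "Leu")
#' @export
mito_genetic_code <- function(code = "2") {
  tab <- Biostrings::getGeneticCode(code)
  stopifnot(length(tab) == 64L)
  tab
}

BASES <- c("A", "C", "G", "T")

AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")

all_codons <- function() {
  g <- expand.grid(p3 = BASES, p2 = BASES, p1 = BASES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$p1, g$p2, g$p3))
}

# Single-nucleotide neighbours of a codon (9 of them).
codon_neighbours <- function(codon) {
  s <- strsplit(codon, "", fixed = TRUE)[[1]]
  out <- character(0)
  for (pos in 1:3) {
    for (b in setdiff(BASES, s[pos])) {
      t <- s
      t[pos] <- b
      out <- c(out, paste(t, collapse = ""))
    }
  }
  out
}

#' @rdname mito_genetic_code
#' @export
codon_families <- function(code = "2") {
  tab <- mito_genetic_code(code)
  sense <- names(tab)[tab != "*"]
  out <- list()
  for (aa in unique(tab[sense])) {
    codons <- sort(names(tab)[tab == aa & tab != "*"])
    # connected components under single-substitution adjacency
    comp <- seq_along(codons)
    repeat {
      changed <- FALSE
      for (i in seq_along(codons)) {
        nb <- intersect(codon_neighbours(codons[i]), codons)
        for (j in match(nb, codons)) {
          if (comp[j] != comp[i]) {
            comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    ids <- unique(comp)
    sizes <- vapply(ids, function(k) sum(comp == k), 0L)
    ord <- order(-sizes, vapply(ids, function(k) codons[comp == k][1], ""))
    label <- if (aa %in% names(AA_THREE)) AA_THREE[[aa]] else aa
    for (r in seq_along(ord)) {
      k <- ids[ord[r]]
      fam <- if (length(ids) == 1L) label else paste0(label, r)
      out[[length(out) + 1L]] <- data.frame(
        codon = codons[comp == k], aa = aa, family = fam,
        family_size = sum(comp == k), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$codon), , drop = FALSE]
  rownames(res) <- NULL
  res
}
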