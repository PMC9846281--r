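# Codon counting, RSCU and usage frequencies over sense-strand CDSs.

split_codons <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  k <- n %/% 3L
  if (k == 0L) return(character(0))
  substring(cds, 3L * seq_len(k) - 2L, 3L * seq_len(k))
}

#' Codon counts over a set of coding sequences
#'
#' Counts complete in-frame codons over all supplied sense-strand CDSs
#' (reading frame starts at position 1). Trailing partial codons --
#' the T/TA remnants of incomplete stop codons -- are dropped, complete
#' terminal stop codons are excluded from the counts, and start codons
#' are included. Codons containing N or gaps are not counted but tallied
#' as `n_ambiguous`. An internal stop codon triggers a warning with its
#' position (annotations are sometimes imperfect), and is excluded from
#' the counts like a terminal stop.
#'
#' @param cds_list character vector (or list) of sense-strand CDSs.
#' @param code NCBI translation table id (default `"2"`, vertebrate
#'   mitochondrial).
#' @return object of class `codon_usage`: list with `code`, `counts`
#'   (named integer over counted codons), `total_codons`, `n_ambiguous`,
#'   `n_stops_excluded`.
#' @examples
#' u <- codon_counts(c("ATGAAATAA", "ATGAAAT"))
#' u$counts
#' @export
codon_counts <- function(cds_list, code = "2") {
  cds_list <- unlist(cds_list, use.names = FALSE)
  stopifnot(is.character(cds_list), length(cds_list) >= 1L)
  if (any(nchar(cds_list) < 6L))
    mc_stop("each CDS must be at least 6 nt", "input")
  tab <- mito_genetic_code(code)
  stops <- names(tab)[tab == "*"]
  counts <- integer(0)
  n_amb <- 0L
  n_stop <- 0L
  for (g in seq_along(cds_list)) {
    codons <- split_codons(cds_list[[g]])
    amb <- !grepl("^[ACGT]{3}$", codons)
    n_amb <- n_amb + sum(amb)
    codons <- codons[!amb]
    is_stop <- codons %in% stops
    internal <- which(is_stop[-length(is_stop)])
    if (length(internal))
      warning(sprintf("internal stop codon(s) in CDS %d at codon position(s) %s",
                      g, paste(internal, collapse = ", ")))
    n_stop <- n_stop + sum(is_stop)
    codons <- codons[!is_stop]
    t <- table(codons)
    counts <- c(counts, integer(0))  # keep type
    for (cd in names(t))
      counts[cd] <- (if (cd %in% names(counts)) counts[[cd]] else 0L) +
        as.integer(t[[cd]])
  }
  counts <- counts[order(names(counts))]
  structure(list(code = code, counts = counts,
                 total_codons = sum(counts), n_ambiguous = n_amb,
                 n_stops_excluded = n_stop),
            class = "codon_usage")
}

#' @export
print.codon_usage <- function(x, ...) {
  cat(sprintf("codon usage over %d codons (%d distinct; code table %s)\n",
              x$total_codons, length(x$counts), x$code))
  if (x$n_ambiguous > 0)
    cat(sprintf("  %d ambiguous codon(s) skipped\n", x$n_ambiguous))
  invisible(x)
}

#' Relative synonymous codon usage
#'
#' For codon *c* in a synonymous family of size *k* whose members were
#' observed *n* times in total, RSCU(*c*) = count(*c*) x *k* / *n*: the
#' observed count relative to the expectation under uniform usage within
#' the family. Within each family with nonzero total the values average
#' to 1 and sum to the family size. Families never observed yield no
#' rows; stop codons are excluded by construction. Codons are reported on
#' the RNA alphabet (CUA, not CTA), the convention of RSCU plots.
#'
#' @param usage a [codon_counts()] result.
#' @return data frame: `codon` (RNA alphabet), `dna_codon`, `aa`,
#'   `family`, `family_size`, `count`, `rscu`.
#' @examples
#' u <- codon_counts(c("ATGCTACTACTTTAA"))
#' rscu(u)
#' @export
rscu <- function(usage) {
  stopifnot(inherits(usage, "codon_usage"))
  fam <- codon_families(usage$code)
  fam$count <- ifelse(fam$codon %in% names(usage$counts),
                      usage$counts[fam$codon], 0L)
  fam_tot <- tapply(fam$count, fam$family, sum)
  fam$family_total <- as.integer(fam_tot[fam$family])
  fam <- fam[fam$family_total > 0L, , drop = FALSE]
  fam$rscu <- fam$count * fam$family_size / fam$family_total
  out <- data.frame(codon = chartr("T", "U", fam$codon),
                    dna_codon = fam$codon, aa = fam$aa,
                    family = fam$family, family_size = fam$family_size,
                    count = as.integer(fam$count), rscu = fam$rscu,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Codon usage frequencies and top-used codons
#'
#' Percentage usage `100 * count / total_codons` per counted codon,
#' sorted descending with alphabetical tie-break.
#'
#' @param usage a [codon_counts()] result with `total_codons > 0`.
#' @param top_k optionally keep only the `top_k` most used codons.
#' @return data frame: `codon` (RNA alphabet), `dna_codon`, `aa`,
#'   `count`, `freq_percent`.
#' @export
codon_frequencies <- function(usage, top_k = NULL) {
  stopifnot(inherits(usage, "codon_usage"))
  if (usage$total_codons == 0L) mc_stop("empty codon usage", "input")
  tab <- mito_genetic_code(usage$code)
  cods <- names(usage$counts)
  out <- data.frame(codon = chartr("T", "U", cods), dna_codon = cods,
                    aa = unname(tab[cods]),
                    count = as.integer(usage$counts),
                    freq_percent = 100 * as.numeric(usage$counts) /
                      usage$total_codons,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$freq_percent, out$codon), , drop = FALSE]
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  rownames(out) <- NULL
  out
}

#' Codon usage of a mitogenome's protein-coding genes
#'
#' Convenience wrapper: extracts the sense-strand sequence of every
#' protein-coding gene of an annotated genome and runs [codon_counts()].
#'
#' @param genome a [mito_genome()] with sequence.
#' @inheritParams codon_counts
#' @return a `codon_usage` object.
#' @export
genome_codon_usage <- function(genome, code = "2") {
  stopifnot(inherits(genome, "mito_genome"))
  require_sequence(genome)
  idx <- which(genome$features$cls == "PCG")
  if (!length(idx)) mc_stop("genome has no protein-coding genes", "input")
  cds <- vapply(idx, function(i) feature_sequence(genome, i), "")
  codon_counts(cds, code = code)
}
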