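# Nei-Gojobori (1986) Ka/Ks with equal-weight pathway averaging and
# Jukes-Cantor correction. Per-codon site counts and per-codon-pair
# pathway classifications are precomputed once per genetic code and
# cached, so pairwise comparisons reduce to table lookups.

.ng86_cache <- new.env(parent = emptyenv())

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' Synonymous and nonsynonymous site counts of one codon
#'
#' For each codon position, the synonymous site fraction is the fraction
#' of possible point mutations at that position that leave the amino
#' acid unchanged; mutations creating a stop codon are excluded from the
#' denominator. The codon's synonymous sites are the sum of the three
#' fractions and its nonsynonymous sites are `3 - syn`, so that
#' S + N = 3 holds exactly per codon.
#'
#' @param codon 3-letter A/C/G/T string, not a stop codon.
#' @param code NCBI translation table id.
#' @return named numeric `c(syn=, nonsyn=)`.
#' @examples
#' ng86_sites("TTT")  # Phe: only TTT->TTC is synonymous, 1/3 syn site
#' @export
ng86_sites <- function(codon, code = "2") {
  tabs <- ng86_tables(code)
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon))
    mc_stop("codon must be a 3-letter A/C/G/T string", "input")
  if (is.na(tabs$syn_sites[codon]))
    mc_stop(paste("stop codon:", codon), "input")
  s <- tabs$syn_sites[[codon]]
  c(syn = s, nonsyn = 3 - s)
}

# Build (and cache) per-code lookup tables:
#   syn_sites[64]        synonymous sites per codon (NA for stops)
#   sd[64,64], nd[64,64] pathway-averaged syn/nonsyn differences
#   ok[64,64]            FALSE where no stop-free pathway exists or a
#                        stop codon is involved
ng86_tables <- function(code = "2") {
  key <- paste0("code_", code)
  if (!is.null(.ng86_cache[[key]])) return(.ng86_cache[[key]])
  tab <- mito_genetic_code(code)
  codons <- all_codons()
  aa <- tab[codons]
  is_stop <- aa == "*"
  syn_sites <- setNames(rep(NA_real_, 64L), codons)
  for (c1 in codons[!is_stop]) {
    s <- strsplit(c1, "", fixed = TRUE)[[1]]
    tot <- 0
    for (pos in 1:3) {
      nsyn <- 0L; nvalid <- 0L
      for (b in setdiff(BASES, s[pos])) {
        t <- s; t[pos] <- b
        mut <- paste(t, collapse = "")
        if (tab[[mut]] == "*") next
        nvalid <- nvalid + 1L
        if (tab[[mut]] == tab[[c1]]) nsyn <- nsyn + 1L
      }
      if (nvalid > 0L) tot <- tot + nsyn / nvalid
    }
    syn_sites[c1] <- tot
  }
  sd <- matrix(NA_real_, 64L, 64L, dimnames = list(codons, codons))
  nd <- sd
  ok <- matrix(FALSE, 64L, 64L, dimnames = list(codons, codons))
  for (i in seq_along(codons)) {
    for (j in seq_along(codons)) {
      if (is_stop[i] || is_stop[j]) next
      pw <- pathway_differences(codons[i], codons[j], tab)
      if (is.null(pw)) next
      sd[i, j] <- pw[["syn"]]
      nd[i, j] <- pw[["nonsyn"]]
      ok[i, j] <- TRUE
    }
  }
  res <- list(tab = tab, syn_sites = syn_sites, sd = sd, nd = nd, ok = ok)
  .ng86_cache[[key]] <- res
  res
}

# Equal-weight average of synonymous/nonsynonymous single steps over all
# orderings of the differing positions, excluding pathways that pass
# through a stop codon. NULL when every pathway is excluded.
pathway_differences <- function(a, b, tab) {
  sa <- strsplit(a, "", fixed = TRUE)[[1]]
  sb <- strsplit(b, "", fixed = TRUE)[[1]]
  diff_pos <- which(sa != sb)
  k <- length(diff_pos)
  if (k == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (k == 1L) list(diff_pos) else
    if (k == 2L) list(diff_pos, rev(diff_pos)) else
      lapply(list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1)), function(o) diff_pos[o])
  tot_s <- 0; tot_n <- 0; n_valid <- 0L
  for (ord in perms) {
    cur <- sa
    s_cnt <- 0L; n_cnt <- 0L
    valid <- TRUE
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- sb[pos]
      from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
      if (tab[[to]] == "*") { valid <- FALSE; break }
      if (tab[[from]] == tab[[to]]) s_cnt <- s_cnt + 1L
      else n_cnt <- n_cnt + 1L
      cur <- nxt
    }
    if (valid) {
      tot_s <- tot_s + s_cnt
      tot_n <- tot_n + n_cnt
      n_valid <- n_valid + 1L
    }
  }
  if (n_valid == 0L) return(NULL)
  c(syn = tot_s / n_valid, nonsyn = tot_n / n_valid)
}

jukes_cantor <- function(p) {
  ifelse(is.na(p) | p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Pairwise Ka/Ks by the Nei-Gojobori (1986) method
#'
#' Compares two equal-length in-frame coding sequences codon by codon.
#' Codons containing gaps, ambiguity codes or stop codons in either
#' sequence are skipped pairwise (and counted). Codon pairs differing at
#' two or three positions average the synonymous/nonsynonymous step
#' classification over all orderings of single steps with equal weights,
#' excluding orderings that pass through a stop codon. Sites are averaged
#' over the two sequences; the proportions pS = Sd/S and pN = Nd/N are
#' corrected for multiple hits with the Jukes-Cantor distance
#' `d = -3/4 ln(1 - 4p/3)` (undefined, flagged, when p >= 3/4). The
#' result is symmetric in the two sequences, and `S + N` equals three
#' times the number of compared codons exactly.
#'
#' @param seq_a,seq_b sense-strand CDS strings of equal length divisible
#'   by 3 (terminal stop codons should be trimmed beforehand; see
#'   [codon_alignment()]).
#' @param code NCBI translation table id.
#' @return object of class `kaks`: list with `S`, `N`, `Sd`, `Nd`, `pS`,
#'   `pN`, `Ks`, `Ka`, `ratio`, `ratio_defined`, `n_codons` (compared),
#'   `n_skipped`.
#' @references Nei M, Gojobori T (1986) Mol Biol Evol 3:418-426.
#' @export
ng86_pairwise <- function(seq_a, seq_b, code = "2") {
  stopifnot(is_dna_string(seq_a), is_dna_string(seq_b))
  if (nchar(seq_a) != nchar(seq_b))
    mc_stop("sequences differ in length", "input")
  if (nchar(seq_a) %% 3L != 0L)
    mc_stop("sequence length not divisible by 3", "input")
  tabs <- ng86_tables(code)
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  usable <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  usable[usable] <- tabs$ok[cbind(ca[usable], cb[usable])]
  n_skip <- sum(!usable)
  ca <- ca[usable]; cb <- cb[usable]
  if (!length(ca)) mc_stop("no comparable codons", "compute")
  S <- (sum(tabs$syn_sites[ca]) + sum(tabs$syn_sites[cb])) / 2
  N <- 3 * length(ca) - S
  idx <- cbind(ca, cb)
  Sd <- sum(tabs$sd[idx])
  Nd <- sum(tabs$nd[idx])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  Ks <- jukes_cantor(pS)
  Ka <- jukes_cantor(pN)
  ratio_defined <- !is.na(Ks) && !is.na(Ka) && Ks > 0
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 Ks = Ks, Ka = Ka,
                 ratio = if (ratio_defined) Ka / Ks else NA_real_,
                 ratio_defined = ratio_defined,
                 n_codons = length(ca), n_skipped = n_skip),
            class = "kaks")
}

#' @export
print.kaks <- function(x, ...) {
  cat(sprintf("NG86 over %d codons: S=%.2f N=%.2f Sd=%.2f Nd=%.2f\n",
              x$n_codons, x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("Ks=%s Ka=%s Ka/Ks=%s\n",
              format(x$Ks, digits = 4), format(x$Ka, digits = 4),
              if (x$ratio_defined) format(x$ratio, digits = 4)
              else "undefined"))
  invisible(x)
}

#' Codon alignment container
#'
#' Bundles equal-length sense-strand sequences for one gene. With
#' `trim_stops = TRUE` (default) a final codon column consisting of stop
#' codons (complete or via the vertebrate-mitochondrial incomplete-stop
#' convention it should already have been removed) is dropped when every
#' row holds a stop there.
#'
#' @param seqs named character vector of aligned sequences (names =
#'   taxon labels).
#' @param gene gene name.
#' @param code NCBI translation table id used for stop trimming.
#' @param trim_stops drop an all-stop final codon column.
#' @return object of class `codon_alignment`: list with `gene`, `taxa`,
#'   `seqs`, `n_codons`, `code`.
#' @export
codon_alignment <- function(seqs, gene = "gene", code = "2",
                            trim_stops = TRUE) {
  seqs <- toupper(unlist(seqs))
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  if (length(unique(nchar(seqs))) != 1L)
    mc_stop("alignment rows differ in length", "format")
  if (is.null(names(seqs)))
    names(seqs) <- paste0("taxon", seq_along(seqs))
  if (nchar(seqs[[1]]) %% 3L != 0L)
    mc_stop("alignment length not divisible by 3", "format")
  if (trim_stops && nchar(seqs[[1]]) >= 3L) {
    tab <- mito_genetic_code(code)
    stops <- names(tab)[tab == "*"]
    n <- nchar(seqs[[1]])
    last <- substr(seqs, n - 2L, n)
    if (all(last %in% stops))
      seqs <- substr(seqs, 1L, n - 3L)
  }
  structure(list(gene = gene, taxa = names(seqs), seqs = seqs,
                 n_codons = nchar(seqs[[1]]) %/% 3L, code = code),
            class = "codon_alignment")
}

#' Read a FASTA codon alignment
#'
#' @param path FASTA file of aligned, in-frame sense-strand sequences.
#' @param gene gene name (default: file name without extension).
#' @inheritParams codon_alignment
#' @return a [codon_alignment()].
#' @export
read_codon_alignment <- function(path, gene = NULL, code = "2",
                                 trim_stops = TRUE) {
  if (!file.exists(path)) mc_stop(paste("no such file:", path), "input")
  ss <- Biostrings::readDNAStringSet(path)
  if (!length(ss)) mc_stop("empty FASTA", "format")
  seqs <- setNames(as.character(ss), names(ss))
  codon_alignment(seqs, gene = gene %||%
                    sub("\\.[^.]*$", "", basename(path)),
                  code = code, trim_stops = trim_stops)
}

#' Write a codon alignment to FASTA
#'
#' @param aln a [codon_alignment()].
#' @param path output path.
#' @export
write_codon_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "codon_alignment"))
  ss <- Biostrings::DNAStringSet(aln$seqs)
  write_atomic(function(tmp) Biostrings::writeXStringSet(ss, tmp), path)
  invisible(path)
}

#' Aggregate Ka/Ks of a gene across taxa
#'
#' Runs [ng86_pairwise()] on every unordered pair of taxa and aggregates
#' as the ratio of mean distances: aggregate Ka is the mean pairwise Ka,
#' aggregate Ks the mean pairwise Ks (pairs whose Jukes-Cantor correction
#' is undefined are excluded from both means and counted), and the
#' reported ratio is mean-Ka / mean-Ks. The ratio of means avoids the
#' division blow-ups of per-pair ratios when a pairwise Ks is near zero.
#' An aggregate with mean Ks = 0 (e.g. identical sequences) is flagged
#' undefined, never reported as infinity.
#'
#' @param alignment a [codon_alignment()] with at least two taxa.
#' @param code NCBI translation table id (default: the alignment's).
#' @return object of class `gene_kaks`: list with `gene`, `Ka`, `Ks`,
#'   `ratio`, `ratio_defined`, `n_taxa`, `n_pairs`, `n_pairs_undefined`,
#'   `pairs` (per-pair data frame).
#' @export
gene_kaks <- function(alignment, code = NULL) {
  stopifnot(inherits(alignment, "codon_alignment"))
  code <- code %||% alignment$code
  n <- length(alignment$taxa)
  if (n < 2L) mc_stop("need at least two taxa", "input")
  pairs <- utils::combn(n, 2)
  rows <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    r <- ng86_pairwise(alignment$seqs[[i]], alignment$seqs[[j]], code)
    rows[[p]] <- data.frame(taxon_a = alignment$taxa[i],
                            taxon_b = alignment$taxa[j],
                            Ka = r$Ka, Ks = r$Ks, ratio = r$ratio,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  def <- !is.na(tab$Ka) & !is.na(tab$Ks)
  if (!any(def)) mc_stop("all pairwise corrections undefined", "compute")
  Ka <- mean(tab$Ka[def])
  Ks <- mean(tab$Ks[def])
  ratio_defined <- Ks > 0
  structure(list(gene = alignment$gene, Ka = Ka, Ks = Ks,
                 ratio = if (ratio_defined) Ka / Ks else NA_real_,
                 ratio_defined = ratio_defined, n_taxa = n,
                 n_pairs = ncol(pairs), n_pairs_undefined = sum(!def),
                 pairs = tab),
            class = "gene_kaks")
}

#' @export
print.gene_kaks <- function(x, ...) {
  cat(sprintf("%s: %d taxa, %d pairs (%d undefined)\n", x$gene, x$n_taxa,
              x$n_pairs, x$n_pairs_undefined))
  cat(sprintf("mean Ka=%.4f  mean Ks=%.4f  Ka/Ks=%s\n", x$Ka, x$Ks,
              if (x$ratio_defined) sprintf("%.4f", x$ratio)
              else "undefined"))
  invisible(x)
}
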