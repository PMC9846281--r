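# Derived gene-table columns: lengths, spacers/overlaps, codon classes,
# and the overlap/IGN summary. All coordinate arithmetic is 1-based
# inclusive on the circular heavy strand.

#' Feature length on a circular genome
#'
#' `end - start + 1` for an ordinary range; a wrap-around feature
#' (`start > end`) has length `(L - start + 1) + end`.
#'
#' @param feature list/one-row data frame with `start` and `end`.
#' @param genome_length total genome length in bp.
#' @return integer length in bp.
#' @export
feature_length <- function(feature, genome_length) {
  s <- as.integer(feature$start)
  e <- as.integer(feature$end)
  L <- as.integer(genome_length)
  if (s < 1L || e < 1L || s > L || e > L)
    mc_stop("feature coordinates outside [1, genome length]", "coordinate")
  if (s <= e) e - s + 1L else (L - s + 1L) + e
}

#' Signed spacer from one feature to the next in annotation order
#'
#' The number of intergenic nucleotides between feature `index` and the
#' following feature in the annotation (the last feature's neighbour is
#' the first, reached across the circular origin). Negative values are
#' overlaps. For a single-feature genome the spacer is the self-wrap gap
#' `L - length(feature)`.
#'
#' @param genome a [mito_genome()].
#' @param index position of the feature in `genome$features`.
#' @return signed integer bp.
#' @examples
#' tsv <- system.file("extdata", "OP132373_feature_table.tsv",
#'                    package = "mitochar")
#' g <- read_feature_table(tsv)
#' spacer_to_next(g, 7)   # tRNA-Ile overlaps tRNA-Gln by 2 bp: -2
#' @export
spacer_to_next <- function(genome, index) {
  stopifnot(inherits(genome, "mito_genome"))
  f <- genome$features
  n <- nrow(f)
  if (n == 0L) mc_stop("no features", "input")
  index <- as.integer(index)
  if (index < 1L || index > n) mc_stop("feature index out of range", "input")
  L <- genome$length
  if (n == 1L) return(L - feature_length(f[1, ], L))
  cur <- f[index, ]
  nxt <- f[if (index == n) 1L else index + 1L, ]
  cur_end <- if (cur$start > cur$end) cur$end + L else cur$end
  nxt_start <- if (index == n) nxt$start + L else nxt$start
  as.integer(nxt_start - cur_end - 1L)
}

#' Start/stop codon classification of a coding sequence
#'
#' Classifies a sense-strand CDS: the start codon is the first triplet;
#' the stop is the last complete triplet when the length is a multiple of
#' three, otherwise the incomplete remnant left by the annotation --
#' `"TA-"` for a trailing TA (length mod 3 = 2) and `"T--"` for a
#' trailing T (mod 3 = 1), both completed to UAA by polyadenylation in
#' vertebrate mitochondria. A complete stop outside `{TAA, TAG}` -- or a
#' remnant that is not TA/T -- is reported as `"other"` with a warning.
#'
#' @param cds sense-strand nucleotide string, length >= 6.
#' @return list with `start_codon`, `stop_codon` (token) and
#'   `stop_complete` (logical).
#' @examples
#' classify_codons("ATGAAATAA")
#' @export
classify_codons <- function(cds) {
  stopifnot(is_dna_string(cds))
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 6L) mc_stop("degenerate CDS (< 6 nt)", "input")
  start <- substr(cds, 1L, 3L)
  rem <- n %% 3L
  if (rem == 0L) {
    last <- substr(cds, n - 2L, n)
    if (!last %in% c("TAA", "TAG")) {
      warning("complete stop codon is not TAA/TAG: ", last)
      return(list(start_codon = start, stop_codon = "other",
                  stop_complete = TRUE))
    }
    return(list(start_codon = start, stop_codon = last,
                stop_complete = TRUE))
  }
  tail <- substr(cds, n - rem + 1L, n)
  ok <- (rem == 2L && tail == "TA") || (rem == 1L && tail == "T")
  if (!ok) {
    warning("incomplete stop remnant is not T/TA: ", tail)
    return(list(start_codon = start, stop_codon = "other",
                stop_complete = FALSE))
  }
  list(start_codon = start,
       stop_codon = if (rem == 2L) "TA-" else "T--",
       stop_complete = FALSE)
}

#' Gene table of an annotated mitogenome
#'
#' One row per feature in annotation order: class, strand, coordinates,
#' length from the coordinates, the signed spacer to the next feature,
#' and (when the genome carries a sequence) the start/stop codon
#' classification of each protein-coding gene.
#'
#' @param genome a [mito_genome()].
#' @return data frame of class `gene_table` with columns `name`, `cls`,
#'   `strand`, `start`, `end`, `length`, `start_codon`, `stop_codon`,
#'   `spacer_to_next`.
#' @examples
#' tsv <- system.file("extdata", "OP132373_feature_table.tsv",
#'                    package = "mitochar")
#' gt <- gene_table(read_feature_table(tsv))
#' head(gt)
#' sum(gt$length + gt$spacer_to_next)   # closes the 16,592 bp circle
#' @export
gene_table <- function(genome) {
  stopifnot(inherits(genome, "mito_genome"))
  f <- genome$features
  n <- nrow(f)
  out <- data.frame(
    name = f$name, cls = f$cls, strand = f$strand,
    start = f$start, end = f$end,
    length = vapply(seq_len(n), function(i)
      feature_length(f[i, ], genome$length), 0L),
    start_codon = rep(NA_character_, n),
    stop_codon = rep(NA_character_, n),
    spacer_to_next = vapply(seq_len(n), function(i)
      spacer_to_next(genome, i), 0L),
    stringsAsFactors = FALSE)
  if (has_sequence(genome)) {
    for (i in which(f$cls == "PCG")) {
      cc <- classify_codons(feature_sequence(genome, i))
      out$start_codon[i] <- cc$start_codon
      out$stop_codon[i] <- cc$stop_codon
    }
  }
  class(out) <- c("gene_table", "data.frame")
  out
}

#' @export
print.gene_table <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

is_control_region <- function(names) {
  grepl("d[-_ ]?loop|control", names, ignore.case = TRUE)
}

#' Overlap and intergenic-spacer summary
#'
#' Counts gene overlaps (negative spacers) and intergenic-nucleotide
#' (IGN) regions (positive spacers) over all adjacent feature pairs of
#' the circle. By convention the spacer immediately upstream of the
#' control region (D-LOOP) is not counted as an IGN region -- the flank
#' of the control region is treated as part of it; set
#' `count_dloop_flank = TRUE` to count it.
#'
#' @param genome a [mito_genome()].
#' @param count_dloop_flank count the spacer whose downstream feature is
#'   the control region as an IGN region (default `FALSE`).
#' @return list of class `spacer_summary`: `n_overlaps`, `overlap_min`,
#'   `overlap_max` (absolute bp), `n_ign`, `ign_total`, `ign_min`,
#'   `ign_max`.
#' @examples
#' tsv <- system.file("extdata", "OP132373_feature_table.tsv",
#'                    package = "mitochar")
#' spacer_summary(read_feature_table(tsv))   # 10 overlaps, 17 IGN / 84 bp
#' @export
spacer_summary <- function(genome, count_dloop_flank = FALSE) {
  stopifnot(inherits(genome, "mito_genome"))
  f <- genome$features
  n <- nrow(f)
  if (n == 0L)
    return(structure(list(n_overlaps = 0L, overlap_min = NA_integer_,
                          overlap_max = NA_integer_, n_ign = 0L,
                          ign_total = 0L, ign_min = NA_integer_,
                          ign_max = NA_integer_),
                     class = "spacer_summary"))
  sp <- vapply(seq_len(n), function(i) spacer_to_next(genome, i), 0L)
  downstream <- c(seq_len(n)[-1L], 1L)
  ov <- -sp[sp < 0L]
  ign <- sp
  if (!count_dloop_flank)
    ign[is_control_region(f$name[downstream])] <- 0L
  ign <- ign[ign > 0L]
  structure(list(
    n_overlaps = length(ov),
    overlap_min = if (length(ov)) min(ov) else NA_integer_,
    overlap_max = if (length(ov)) max(ov) else NA_integer_,
    n_ign = length(ign),
    ign_total = if (length(ign)) sum(ign) else 0L,
    ign_min = if (length(ign)) min(ign) else NA_integer_,
    ign_max = if (length(ign)) max(ign) else NA_integer_),
    class = "spacer_summary")
}

#' @export
print.spacer_summary <- function(x, ...) {
  cat(sprintf("%d gene overlap(s)", x$n_overlaps))
  if (x$n_overlaps > 0)
    cat(sprintf(", %d to %d bp", x$overlap_min, x$overlap_max))
  cat(sprintf("\n%d intergenic region(s) totalling %d bp", x$n_ign,
              x$ign_total))
  if (x$n_ign > 0)
    cat(sprintf(", %d to %d bp", x$ign_min, x$ign_max))
  cat("\n")
  invisible(x)
}
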