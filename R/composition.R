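#' Base composition and strand skews of a sequence
#'
#' Counts A/C/G/T (ambiguity codes are excluded from numerator and
#' denominator alike) and computes the strand-asymmetry skews
#' \deqn{AT\mbox{-}skew = (A - T)/(A + T), \quad
#'       GC\mbox{-}skew = (G - C)/(G + C)}
#' from the raw counts. Both skews lie in \[-1, 1\] and change sign under
#' reverse complementation.
#'
#' @param seq nucleotide string.
#' @return list of class `composition_summary`: `n` (bases counted),
#'   `counts` (named A/C/G/T), `pct` (percentages of `n`), `at_percent`,
#'   `gc_percent`, `at_skew`, `gc_skew`. Values are stored at full
#'   precision; the print method rounds to 2 decimals.
#' @examples
#' base_composition("AAAT")$at_skew   # 0.5
#' @export
base_composition <- function(seq) {
  stopifnot(is_dna_string(seq))
  seq <- toupper(seq)
  if (nchar(seq) == 0L) mc_stop("empty sequence", "input")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  counts <- vapply(BASES, function(b) sum(chars == b), 0L)
  n <- sum(counts)
  if (n == 0L) mc_stop("sequence has no unambiguous A/C/G/T", "input")
  pct <- 100 * counts / n
  a <- counts[["A"]]; c_ <- counts[["C"]]
  g <- counts[["G"]]; t <- counts[["T"]]
  structure(list(
    n = n, counts = counts, pct = pct,
    at_percent = pct[["A"]] + pct[["T"]],
    gc_percent = pct[["G"]] + pct[["C"]],
    at_skew = if (a + t > 0) (a - t) / (a + t) else NA_real_,
    gc_skew = if (g + c_ > 0) (g - c_) / (g + c_) else NA_real_),
    class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, digits = 2, ...) {
  cat(sprintf("%d bp: A %.1f%%  C %.1f%%  G %.1f%%  T %.1f%%\n", x$n,
              x$pct[["A"]], x$pct[["C"]], x$pct[["G"]], x$pct[["T"]]))
  cat(sprintf("A+T %.1f%%  AT-skew %s  GC-skew %s\n", x$at_percent,
              format(round(x$at_skew, digits), nsmall = digits),
              format(round(x$gc_skew, digits), nsmall = digits)))
  invisible(x)
}

#' Skews recomputed from printed percentages
#'
#' Audit mode for published composition tables: applies the skew formulae
#' directly to base percentages as printed, so a reported AT-/GC-skew can
#' be checked without the underlying sequence. An undefined component
#' (zero denominator) is returned as `NA` with a warning.
#'
#' @param a,t,c,g base percentages (any common scale).
#' @return named numeric vector `c(at_skew=, gc_skew=)`.
#' @examples
#' round(skew_from_percentages(a = 13.5, t = 42.8, c = 11.6, g = 32.2), 2)
#' @export
skew_from_percentages <- function(a, t, c, g) {
  stopifnot(all(c(a, t, c, g) >= 0))
  if (a + t == 0 && g + c == 0)
    mc_stop("both skews undefined (all-zero percentages)", "input")
  at <- if (a + t > 0) (a - t) / (a + t) else {
    warning("AT-skew undefined: A + T = 0"); NA_real_
  }
  gc <- if (g + c > 0) (g - c) / (g + c) else {
    warning("GC-skew undefined: G + C = 0"); NA_real_
  }
  c(at_skew = at, gc_skew = gc)
}

#' Per-partition composition table of a mitogenome
#'
#' Composition and skews for the standard reporting partitions: each
#' protein-coding gene on its sense strand (so a light-strand gene such
#' as ND6 shows skews of opposite sign to the genome), then the
#' concatenated rRNAs, tRNAs, control region and all-PCG partitions as
#' annotated on the heavy strand, and the whole heavy strand
#' (partition `"Total"`). Concatenation follows annotation order;
#' missing partitions are omitted with a warning.
#'
#' @param genome a [mito_genome()] with sequence.
#' @param pcg_partition_strand `"H"` (default) to take the concatenated
#'   PCG partition as annotated on the heavy strand, `"sense"` to
#'   concatenate sense-strand gene sequences instead.
#' @return data frame with one row per partition: `partition`, `n`,
#'   `a_pct`, `c_pct`, `g_pct`, `t_pct`, `at_percent`, `gc_percent`,
#'   `at_skew`, `gc_skew` (full precision).
#' @export
partition_composition <- function(genome, pcg_partition_strand = "H") {
  stopifnot(inherits(genome, "mito_genome"))
  require_sequence(genome)
  pcg_partition_strand <- match.arg(pcg_partition_strand, c("H", "sense"))
  f <- genome$features
  rows <- list()
  add <- function(name, s) {
    if (is.null(s) || !nzchar(s)) return()
    cs <- base_composition(s)
    rows[[length(rows) + 1L]] <<- data.frame(
      partition = name, n = cs$n,
      a_pct = cs$pct[["A"]], c_pct = cs$pct[["C"]],
      g_pct = cs$pct[["G"]], t_pct = cs$pct[["T"]],
      at_percent = cs$at_percent, gc_percent = cs$gc_percent,
      at_skew = cs$at_skew, gc_skew = cs$gc_skew,
      stringsAsFactors = FALSE)
  }
  h_range <- function(i) {
    ff <- f[i, ]
    if (ff$start <= ff$end) substr(genome$seq, ff$start, ff$end)
    else paste0(substr(genome$seq, ff$start, genome$length),
                substr(genome$seq, 1L, ff$end))
  }
  concat <- function(idx, strand = "H") {
    if (!length(idx)) return(NULL)
    paste(vapply(idx, function(i)
      if (strand == "H") h_range(i) else feature_sequence(genome, i), ""),
      collapse = "")
  }
  for (i in which(f$cls == "PCG")) add(f$name[i], feature_sequence(genome, i))
  parts <- list(
    rRNAs = concat(which(f$cls == "rRNA")),
    tRNAs = concat(which(f$cls == "tRNA")),
    `D-LOOP` = concat(which(f$cls == "noncoding" &
                              is_control_region(f$name))),
    PCGs = concat(which(f$cls == "PCG"),
                  strand = if (pcg_partition_strand == "H") "H" else "sense"))
  for (nm in names(parts)) {
    if (is.null(parts[[nm]]))
      warning("partition '", nm, "' has no features; row omitted")
    else add(nm, parts[[nm]])
  }
  add("Total", genome$seq)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
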