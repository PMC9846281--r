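# Optional checks against a locally cached GenBank record. The package
# never downloads anything: a record is used only if the user has placed
# its flat file in the cache directory (or points to it directly).

#' Locate a locally cached GenBank flat file
#'
#' Looks for `<accession>.gb` (or `.gbk`/`.txt`) in `cache_dir`. Returns
#' the path, or `NA_character_` when the record is not cached.
#'
#' @param accession GenBank accession, e.g. `"OP132373"`.
#' @param cache_dir directory searched; defaults to the
#'   `mitochar.cache_dir` option, else `~/.cache/mitochar`.
#' @return file path or `NA_character_`.
#' @export
genbank_cache_path <- function(accession,
                               cache_dir = getOption(
                                 "mitochar.cache_dir",
                                 file.path(path.expand("~"), ".cache",
                                           "mitochar"))) {
  for (ext in c(".gb", ".gbk", ".txt")) {
    p <- file.path(cache_dir, paste0(accession, ext))
    if (file.exists(p)) return(p)
  }
  NA_character_
}

#' Characterisation checks on a cached accession
#'
#' When the record is cached locally, parses it and reports the total
#' length and the most-used codon of its protein-coding genes -- the two
#' headline quantities of a mitogenome characterisation. Returns `NULL`
#' (with a message) when the record is not cached; nothing is
#' downloaded.
#'
#' @inheritParams genbank_cache_path
#' @return `NULL`, or a list with `accession`, `length_bp`,
#'   `top_codon`, `top_codon_percent`.
#' @export
accession_report <- function(accession = "OP132373", cache_dir = NULL) {
  path <- if (is.null(cache_dir)) genbank_cache_path(accession)
          else genbank_cache_path(accession, cache_dir)
  if (is.na(path)) {
    message("accession ", accession,
            " is not cached locally; checks skipped")
    return(NULL)
  }
  g <- read_genbank(path)
  top <- codon_frequencies(genome_codon_usage(g), top_k = 1)
  list(accession = accession, length_bp = g$length,
       top_codon = top$codon[1],
       top_codon_percent = top$freq_percent[1])
}
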