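#' Annotated circular mitogenome
#'
#' Container for a circular mitochondrial genome: the heavy-strand
#' sequence (optional) plus an ordered feature annotation. Coordinates are
#' 1-based inclusive on the heavy strand, matching the GenBank convention;
#' a feature whose `start > end` spans the circular origin and its length
#' is `(L - start + 1) + end`. Feature order is preserved exactly as read
#' because the intergenic-spacer arithmetic of [gene_table()] depends on
#' annotation order.
#'
#' @param features data frame with columns `name`, `cls` (one of `"PCG"`,
#'   `"tRNA"`, `"rRNA"`, `"noncoding"`), `start`, `end`, `strand` (`"H"`
#'   heavy / `"L"` light) and optionally `anticodon`. Extra columns are
#'   kept untouched.
#' @param seq heavy-strand sequence as a single character string over
#'   A/C/G/T/N, or `NULL` for a coordinates-only annotation (sequence
#'   operations then refuse to run).
#' @param length genome length in bp; mandatory when `seq` is `NULL` and
#'   no feature reaches the last position, otherwise inferred.
#' @param circular logical; the model is built for circular molecules and
#'   this is `TRUE` throughout the package.
#' @return An object of class `mito_genome`: a list with elements `seq`
#'   (string or `NULL`), `length`, `features` (data frame), `circular`.
#' @seealso [read_feature_table()], [read_genbank()], [feature_sequence()]
#' @export
mito_genome <- function(features, seq = NULL, length = NULL,
                        circular = TRUE) {
  stopifnot(is.data.frame(features))
  need <- c("name", "cls", "start", "end", "strand")
  miss <- setdiff(need, names(features))
  if (base::length(miss))
    mc_stop(paste("feature table lacks column(s):",
                  paste(miss, collapse = ", ")), "format")
  if (!"anticodon" %in% names(features)) features$anticodon <- NA_character_
  bad <- setdiff(unique(features$cls), c("PCG", "tRNA", "rRNA", "noncoding"))
  if (base::length(bad))
    mc_stop(paste("unknown feature class token(s):",
                  paste(bad, collapse = ", ")), "format")
  if (!all(features$strand %in% c("H", "L")))
    mc_stop("strand must be 'H' or 'L'", "format")
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (anyNA(features$start) || anyNA(features$end))
    mc_stop("feature coordinates must be integers", "format")
  if (!is.null(seq)) {
    stopifnot(is_dna_string(seq))
    seq <- toupper(seq)
    if (nchar(seq) == 0L) mc_stop("empty sequence", "format")
    if (!grepl("^[ACGTN]*$", seq))
      mc_stop("sequence contains characters outside A/C/G/T/N", "format")
    if (!is.null(length) && length != nchar(seq))
      mc_stop("declared length disagrees with sequence length", "format")
    length <- nchar(seq)
  }
  if (is.null(length)) {
    if (nrow(features) == 0L)
      mc_stop("length required for an empty coordinates-only genome",
              "format")
    length <- max(features$end, features$start)
  }
  length <- as.integer(length)
  if (nrow(features) > 0L &&
      (any(features$start < 1L) || any(features$end < 1L) ||
       any(features$start > length) || any(features$end > length)))
    mc_stop("feature coordinates outside [1, genome length]", "coordinate")
  dup <- unique(features$name[duplicated(features$name)])
  if (base::length(dup))
    warning("duplicate feature name(s): ", paste(dup, collapse = ", "))
  structure(list(seq = seq, length = length, features = features,
                 circular = isTRUE(circular)),
            class = "mito_genome")
}

#' @export
print.mito_genome <- function(x, ...) {
  cat("Annotated circular mitogenome\n")
  cat(sprintf("  length: %d bp (%s)\n", x$length,
              if (is.null(x$seq)) "coordinates only" else "with sequence"))
  n <- table(factor(x$features$cls,
                    levels = c("PCG", "tRNA", "rRNA", "noncoding")))
  cat(sprintf("  features: %d (%d PCG, %d tRNA, %d rRNA, %d noncoding)\n",
              nrow(x$features), n[["PCG"]], n[["tRNA"]], n[["rRNA"]],
              n[["noncoding"]]))
  invisible(x)
}

has_sequence <- function(genome) !is.null(genome$seq)

require_sequence <- function(genome) {
  if (!has_sequence(genome))
    mc_stop("this operation needs a genome with a sequence", "input")
}

#' Gene-name normalisation
#'
#' Mitochondrial gene names are written many ways across GenBank records
#' (COI/CO1/COXI, cytb/cob, NAD1, ...). `gene_name_map()` returns the
#' built-in synonym table; `normalize_gene_name()` applies it (plus any
#' user additions) case-insensitively. Unknown names pass through
#' unchanged.
#'
#' @param x character vector of gene names.
#' @param extra optional named character vector of additional synonyms
#'   (`c(weirdname = "ND1")`), taking precedence over the built-ins.
#' @return character vector of normalised names.
#' @export
normalize_gene_name <- function(x, extra = NULL) {
  map <- gene_name_map()
  if (!is.null(extra)) {
    stopifnot(!is.null(names(extra)))
    map[tolower(names(extra))] <- unname(extra)
  }
  key <- tolower(gsub("[ _]", "", x))
  hit <- key %in% names(map)
  x[hit] <- unname(map[key[hit]])
  x
}

#' @rdname normalize_gene_name
#' @export
gene_name_map <- function() {
  c(coi = "COX1", co1 = "COX1", coxi = "COX1", cox1 = "COX1",
    coii = "COX2", co2 = "COX2", coxii = "COX2", cox2 = "COX2",
    coiii = "COX3", co3 = "COX3", coxiii = "COX3", cox3 = "COX3",
    cytb = "CYTB", cob = "CYTB", cob1 = "CYTB",
    nad1 = "ND1", nad2 = "ND2", nad3 = "ND3", nad4 = "ND4",
    nad4l = "ND4L", nad5 = "ND5", nad6 = "ND6",
    atp8 = "ATP8", atpase8 = "ATP8", atp6 = "ATP6", atpase6 = "ATP6",
    rrns = "12S-rRNA", `12s` = "12S-rRNA", `12srrna` = "12S-rRNA",
    `12sribosomalrna` = "12S-rRNA", `srrna` = "12S-rRNA",
    rrnl = "16S-rRNA", `16s` = "16S-rRNA", `16srrna` = "16S-rRNA",
    `16sribosomalrna` = "16S-rRNA", `lrrna` = "16S-rRNA",
    dloop = "D-LOOP", `d-loop` = "D-LOOP", controlregion = "D-LOOP")
}

#' Read an annotated mitogenome from a feature table (TSV) and FASTA
#'
#' The table must carry the header `name cls from to strand anticodon`
#' (anticodon optional; extra columns are preserved). When `fasta_path`
#' is omitted the genome is coordinates-only: gene-table and spacer
#' arithmetic work, sequence-based operations (composition, codon work)
#' refuse with an error. A row with `from > to` is a feature spanning the
#' circular origin.
#'
#' @param table_path path to the TSV feature table.
#' @param fasta_path optional path to a FASTA file holding the single
#'   heavy-strand sequence.
#' @param length genome length override for coordinates-only input (by
#'   default the maximal annotated position).
#' @return a [mito_genome()] object with features in file order.
#' @examples
#' tsv <- system.file("extdata", "OP132373_feature_table.tsv",
#'                    package = "mitochar")
#' g <- read_feature_table(tsv, length = 16592)
#' g
#' @export
read_feature_table <- function(table_path, fasta_path = NULL,
                               length = NULL) {
  if (!file.exists(table_path))
    mc_stop(paste("no such file:", table_path), "input")
  tab <- utils::read.delim(table_path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  if (nrow(tab) == 0L && is.null(length) && is.null(fasta_path))
    mc_stop("empty feature table needs an explicit genome length", "format")
  need <- c("name", "cls", "from", "to", "strand")
  miss <- setdiff(need, names(tab))
  if (base::length(miss))
    mc_stop(paste("feature table lacks column(s):",
                  paste(miss, collapse = ", ")), "format")
  if (nrow(tab) > 0L) {
    from <- suppressWarnings(as.integer(gsub(",", "", tab$from)))
    to <- suppressWarnings(as.integer(gsub(",", "", tab$to)))
    if (anyNA(from) || anyNA(to))
      mc_stop("from/to must be integers", "format")
    tab$from <- from
    tab$to <- to
  }
  names(tab)[names(tab) == "from"] <- "start"
  names(tab)[names(tab) == "to"] <- "end"
  seq <- NULL
  if (!is.null(fasta_path)) {
    ss <- Biostrings::readDNAStringSet(fasta_path)
    if (base::length(ss) == 0L) mc_stop("FASTA holds no sequence", "format")
    if (base::length(ss) > 1L)
      warning("FASTA holds several sequences; using the first")
    seq <- as.character(ss[[1]])
  }
  mito_genome(tab, seq = seq, length = length)
}

#' Write a mito_genome feature annotation back to TSV
#'
#' Emits the canonical `name cls from to strand anticodon` schema (and,
#' with `fasta_path`, the sequence), so that
#' `read_feature_table(write_feature_table(g))` round-trips exactly.
#'
#' @param genome a [mito_genome()].
#' @param path output TSV path.
#' @param fasta_path optional output FASTA path for the sequence.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(genome, path, fasta_path = NULL) {
  stopifnot(inherits(genome, "mito_genome"))
  f <- genome$features
  out <- data.frame(name = f$name, cls = f$cls, from = f$start, to = f$end,
                    strand = f$strand, anticodon = f$anticodon,
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
  if (!is.null(fasta_path)) {
    require_sequence(genome)
    ss <- Biostrings::DNAStringSet(genome$seq)
    names(ss) <- "mitogenome"
    write_atomic(function(tmp) Biostrings::writeXStringSet(ss, tmp),
                 fasta_path)
  }
  invisible(path)
}

#' Read an annotated mitogenome from a GenBank flat file
#'
#' A deliberately small parser for the flat-file layout of mitogenome
#' records: the LOCUS length, the ORIGIN sequence block, and the CDS /
#' tRNA / rRNA / D-loop / misc_feature entries of the FEATURES table.
#' `complement(a..b)` locations become strand `L`; a
#' `join(a..N,1..b)` across the origin becomes a single feature with
#' `start > end`. Gene names are taken from the `/gene` (else `/product`)
#' qualifier and passed through [normalize_gene_name()].
#'
#' @param path GenBank flat file.
#' @param name_map extra synonyms forwarded to [normalize_gene_name()].
#' @return a [mito_genome()] with features in file order.
#' @export
read_genbank <- function(path, name_map = NULL) {
  if (!file.exists(path)) mc_stop(paste("no such file:", path), "input")
  lines <- readLines(path, warn = FALSE)
  ori <- grep("^ORIGIN", lines)
  if (!length(ori))
    mc_stop("GenBank record has no ORIGIN sequence block", "format")
  seq_lines <- lines[(ori[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(seq) == 0L) mc_stop("GenBank record has an empty sequence",
                                "format")
  feat_start <- grep("^FEATURES", lines)
  if (!length(feat_start)) mc_stop("GenBank record has no FEATURES table",
                                   "format")
  block <- lines[(feat_start[1] + 1L):(ori[1] - 1L)]
  keys <- c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature")
  cls_of <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
              `D-loop` = "noncoding", misc_feature = "noncoding")
  # split the block at feature-key lines (key at column 6, location after)
  is_key <- grepl("^ {5}\\S", block)
  idx <- which(is_key)
  rows <- list()
  for (i in seq_along(idx)) {
    first <- block[idx[i]]
    key <- sub("^ {5}(\\S+).*$", "\\1", first)
    if (!key %in% keys) next
    last <- if (i < length(idx)) idx[i + 1L] - 1L else length(block)
    body <- block[idx[i]:last]
    loc <- sub("^ {5}\\S+\\s+", "", first)
    # locations can continue on following lines until the first qualifier
    qual_at <- grep("^\\s+/", body)
    loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(body)
    if (loc_end > 1L)
      loc <- paste0(loc, paste(trimws(body[2:loc_end]), collapse = ""))
    strand <- if (grepl("complement", loc)) "L" else "H"
    nums <- as.integer(unlist(regmatches(loc, gregexpr("[0-9]+", loc))))
    if (length(nums) < 2L)
      mc_stop(paste("cannot parse location:", loc), "format")
    if (grepl("join", loc) && length(nums) >= 4L &&
        nums[2] == nchar(seq) && nums[3] == 1L) {
      start <- nums[1]; end <- nums[4]       # wraps the origin
    } else {
      start <- min(nums); end <- max(nums)
    }
    grab <- function(q) {
      m <- grep(paste0("^\\s+/", q, "="), body, value = TRUE)
      if (!length(m)) return(NA_character_)
      gsub("\"", "", sub(paste0("^/", q, "="), "", trimws(m[1])))
    }
    name <- grab("gene")
    if (is.na(name)) name <- grab("product")
    if (is.na(name)) name <- key
    anticodon <- grab("anticodon")
    rows[[length(rows) + 1L]] <- data.frame(
      name = name, cls = cls_of[[key]], start = start, end = end,
      strand = strand, anticodon = anticodon, stringsAsFactors = FALSE)
  }
  if (!length(rows)) mc_stop("no usable features found", "format")
  feats <- do.call(rbind, rows)
  feats$name <- normalize_gene_name(feats$name, extra = name_map)
  if (any(feats$start > nchar(seq) | feats$end > nchar(seq)))
    mc_stop("feature beyond sequence length", "coordinate")
  mito_genome(feats, seq = seq)
}

#' Sense-strand sequence of one feature
#'
#' Extracts the sequence a feature is read from: heavy-strand features
#' give `seq[start..end]` directly, light-strand features its reverse
#' complement. A wrap-around range (`start > end`) concatenates the tail
#' and head of the circle before orienting.
#'
#' @param genome a [mito_genome()] carrying a sequence.
#' @param feature either a row index into `genome$features`, a feature
#'   name, or a one-row data frame / list with `start`, `end`, `strand`.
#' @return character string, the sense-strand sequence.
#' @examples
#' g <- mito_genome(data.frame(name = "x", cls = "noncoding", start = 9,
#'                             end = 2, strand = "H"),
#'                  seq = "AAAAATTTTT")
#' feature_sequence(g, 1)   # "TTAA": wraps the origin
#' @export
feature_sequence <- function(genome, feature) {
  stopifnot(inherits(genome, "mito_genome"))
  require_sequence(genome)
  f <- resolve_feature(genome, feature)
  L <- genome$length
  if (f$start < 1L || f$end < 1L || f$start > L || f$end > L)
    mc_stop("feature coordinates outside the genome", "coordinate")
  s <- if (f$start <= f$end) {
    substr(genome$seq, f$start, f$end)
  } else {
    paste0(substr(genome$seq, f$start, L), substr(genome$seq, 1L, f$end))
  }
  if (identical(f$strand, "L")) revcomp(s) else s
}

resolve_feature <- function(genome, feature) {
  if (is.numeric(feature) && length(feature) == 1L) {
    if (feature < 1L || feature > nrow(genome$features))
      mc_stop("feature index out of range", "input")
    return(as.list(genome$features[feature, ]))
  }
  if (is.character(feature) && length(feature) == 1L) {
    i <- which(genome$features$name == feature)
    if (!length(i)) mc_stop(paste("no feature named", feature), "input")
    return(as.list(genome$features[i[1], ]))
  }
  if (is.data.frame(feature)) return(as.list(feature[1, ]))
  if (is.list(feature)) return(feature)
  mc_stop("cannot interpret 'feature'", "input")
}
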