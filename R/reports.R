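# Workflow entry points tying the modules together, plus the report
# writers used by the command-line wrapper (inst/cli/mitochar.R). Every
# report embeds the configuration, package version and seed used.

report_meta <- function(config) {
  list(package = "mitochar",
       version = as.character(utils::packageVersion("mitochar")),
       config = config)
}

#' Characterise an annotated mitogenome
#'
#' Runs the full characterisation on one genome and (optionally) writes
#' the standard reports: the gene table ([gene_table()]), the partition
#' composition table ([partition_composition()]), the RSCU table
#' ([rscu()]) and a summary JSON (length, feature-class counts, the
#' overlap/IGN summary of [spacer_summary()], top-used codons). On a
#' coordinates-only genome the sequence-based reports are skipped with a
#' warning and the coordinate reports still come out.
#'
#' @param genome a [mito_genome()], or a feature-table TSV path.
#' @param out_dir optional directory to write `gene_table.tsv`,
#'   `composition.tsv`, `rscu.tsv` and `summary.json` into.
#' @param code NCBI translation table id.
#' @param round_digits decimals used in the TSV reports (the returned
#'   objects keep full precision).
#' @param count_dloop_flank forwarded to [spacer_summary()].
#' @param top_k codons listed in the summary.
#' @return (invisibly) list with `gene_table`, `spacer_summary`,
#'   `composition`, `rscu`, `top_codons`, `summary`.
#' @export
characterize <- function(genome, out_dir = NULL, code = "2",
                         round_digits = 2, count_dloop_flank = FALSE,
                         top_k = 5) {
  if (is.character(genome)) genome <- read_feature_table(genome)
  stopifnot(inherits(genome, "mito_genome"))
  gt <- gene_table(genome)
  ss <- spacer_summary(genome, count_dloop_flank = count_dloop_flank)
  comp <- NULL; rs <- NULL; top <- NULL
  if (has_sequence(genome)) {
    comp <- partition_composition(genome)
    usage <- genome_codon_usage(genome, code = code)
    rs <- rscu(usage)
    top <- codon_frequencies(usage, top_k = top_k)
  } else {
    warning("genome carries no sequence; composition and RSCU skipped")
  }
  cls_counts <- as.list(table(factor(
    genome$features$cls, levels = c("PCG", "tRNA", "rRNA", "noncoding"))))
  summary <- c(report_meta(list(code = code, round_digits = round_digits,
                                count_dloop_flank = count_dloop_flank)),
               list(length_bp = genome$length,
                    n_features = nrow(genome$features),
                    class_counts = cls_counts,
                    spacer_summary = unclass(ss),
                    top_codons = if (!is.null(top))
                      top[c("codon", "aa", "freq_percent")]))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    gt_out <- gt
    write_tsv(gt_out, file.path(out_dir, "gene_table.tsv"))
    if (!is.null(comp)) {
      comp_out <- comp
      num <- vapply(comp_out, is.numeric, TRUE) &
        !names(comp_out) %in% c("n")
      comp_out[num] <- lapply(comp_out[num], round, round_digits)
      write_tsv(comp_out, file.path(out_dir, "composition.tsv"))
    }
    if (!is.null(rs)) {
      rs_out <- rs
      rs_out$rscu <- round(rs_out$rscu, round_digits)
      write_tsv(rs_out, file.path(out_dir, "rscu.tsv"))
    }
    write_json_report(summary, file.path(out_dir, "summary.json"))
  }
  invisible(list(gene_table = gt, spacer_summary = ss, composition = comp,
                 rscu = rs, top_codons = top, summary = summary))
}

#' Per-gene Ka/Ks over a batch of codon alignments
#'
#' Runs [gene_kaks()] on each FASTA alignment and assembles the per-gene
#' table, sorted by decreasing Ka/Ks with undefined ratios last. A
#' failure in one gene is caught and reported in its row; the other
#' genes are still computed.
#'
#' @param paths FASTA file paths, or a directory containing them.
#' @param out_path optional TSV output path.
#' @param code NCBI translation table id.
#' @return data frame: `gene`, `n_taxa`, `n_pairs`, `Ka`, `Ks`, `ratio`,
#'   `error` (NA when the gene succeeded).
#' @export
kaks_batch <- function(paths, out_path = NULL, code = "2") {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.(fa|fasta|fna)$",
                        full.names = TRUE)
  if (!length(paths)) mc_stop("no alignment files", "input")
  rows <- lapply(paths, function(p) {
    tryCatch({
      r <- gene_kaks(read_codon_alignment(p, code = code))
      data.frame(gene = r$gene, n_taxa = r$n_taxa, n_pairs = r$n_pairs,
                 Ka = r$Ka, Ks = r$Ks, ratio = r$ratio,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(gene = sub("\\.[^.]*$", "", basename(p)),
                 n_taxa = NA_integer_, n_pairs = NA_integer_,
                 Ka = NA_real_, Ks = NA_real_, ratio = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  out <- out[order(is.na(out$ratio), -ifelse(is.na(out$ratio), 0,
                                             out$ratio)), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(out_path)) write_tsv(out, out_path)
  out
}

#' Genus monophyly check of a published tree
#'
#' Thin wrapper over [genus_tree()] + [monophyly_report()] with TSV
#' output.
#'
#' @inheritParams genus_tree
#' @param out_path optional TSV output path.
#' @return the [monophyly_report()] data frame.
#' @export
treecheck <- function(tree, genus_map = NULL, genus_regex = "^([^_]+)",
                      ignore_unmapped = FALSE, out_path = NULL) {
  rep <- monophyly_report(genus_tree(tree, genus_map = genus_map,
                                     genus_regex = genus_regex,
                                     ignore_unmapped = ignore_unmapped))
  if (!is.null(out_path)) write_tsv(rep, out_path)
  rep
}

#' Write a synthetic fixture bundle
#'
#' Generates an annotated genome (feature-table TSV + FASTA) and one
#' codon alignment per supplied alignment spec, together with a JSON
#' truth record. Deterministic given the specs' seeds.
#'
#' @param out_dir output directory (created if needed).
#' @param genome_spec a [genome_spec()], or `NULL` to skip the genome.
#' @param alignment_specs list of [alignment_spec()]s (possibly empty).
#' @return (invisibly) the truth list.
#' @export
simulate_fixtures <- function(out_dir, genome_spec = NULL,
                              alignment_specs = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- list()
  if (!is.null(genome_spec)) {
    sim <- generate_mitogenome(genome_spec)
    write_feature_table(sim$genome,
                        file.path(out_dir, "genome_features.tsv"),
                        fasta_path = file.path(out_dir, "genome.fasta"))
    truth$genome <- sim$truth
  }
  for (i in seq_along(alignment_specs)) {
    sim <- generate_codon_alignment(alignment_specs[[i]])
    nm <- sprintf("alignment_%02d", i)
    write_codon_alignment(sim$alignment,
                          file.path(out_dir, paste0(nm, ".fasta")))
    truth[[nm]] <- sim$truth
  }
  write_json_report(c(report_meta(list(out_dir = out_dir)), truth),
                    file.path(out_dir, "truth.json"))
  invisible(truth)
}
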