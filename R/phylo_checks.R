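# Post-hoc interrogation of published trees: genus monophyly by the
# unrooted edge-bipartition criterion.

#' Leaf-labelled tree with a tip-to-genus map
#'
#' Bundles a phylogenetic tree with the genus assignment of each tip.
#' The tree may be given as an `ape::phylo` object, a newick file path,
#' or a newick string; support values stored as internal node labels and
#' branch lengths are retained. When no explicit map is supplied the
#' genus is extracted from each tip label with `genus_regex` (default:
#' the token before the first underscore, the usual
#' `Genus_species_accession` labelling).
#'
#' @param tree `phylo`, newick file path, or newick string.
#' @param genus_map optional: named character vector (tip -> genus), or a
#'   two-column TSV path (`tip`, `genus`).
#' @param genus_regex regex whose first capture group is the genus, used
#'   when `genus_map` is absent.
#' @param ignore_unmapped drop tips missing from `genus_map` from the
#'   report instead of erroring.
#' @return object of class `genus_tree`: list with `tree` (phylo),
#'   `genus` (named character over all tips; `NA` for ignored tips).
#' @examples
#' gt <- genus_tree("((Rectoris_luxiensis,Rectoris_posehensis),(Garra_a,Labeo_b));")
#' monophyly_report(gt)
#' @export
genus_tree <- function(tree, genus_map = NULL,
                       genus_regex = "^([^_]+)", ignore_unmapped = FALSE) {
  tree <- as_phylo(tree)
  tips <- tree$tip.label
  if (anyDuplicated(tips))
    mc_stop("duplicate tip labels", "format")
  if (is.null(genus_map)) {
    m <- regmatches(tips, regexec(genus_regex, tips))
    genus <- vapply(m, function(x)
      if (length(x) >= 2L) x[[2]] else NA_character_, "")
    names(genus) <- tips
  } else {
    if (is.character(genus_map) && length(genus_map) == 1L &&
        file.exists(genus_map)) {
      tab <- utils::read.delim(genus_map, stringsAsFactors = FALSE)
      if (ncol(tab) < 2L) mc_stop("genus map needs two columns", "format")
      genus_map <- setNames(tab[[2]], tab[[1]])
    }
    genus <- setNames(unname(genus_map[tips]), tips)
  }
  if (anyNA(genus)) {
    missing_tips <- tips[is.na(genus)]
    if (!ignore_unmapped)
      mc_stop(paste("tips without a genus:",
                    paste(missing_tips, collapse = ", ")), "input")
    warning("ignoring unmapped tip(s): ",
            paste(missing_tips, collapse = ", "))
  }
  structure(list(tree = tree, genus = genus), class = "genus_tree")
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    t <- if (file.exists(tree)) ape::read.tree(file = tree)
         else suppressWarnings(tryCatch(ape::read.tree(text = tree),
                                        error = function(e) NULL))
    if (is.null(t)) mc_stop("cannot parse newick input", "format")
    return(t)
  }
  mc_stop("tree must be a phylo object, a file, or a newick string",
          "input")
}

# Tip sets below every edge, as a logical matrix (edge x tip), by a
# single post-order accumulation over the edge matrix.
edge_bipartitions <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  below <- matrix(FALSE, n_node, n_tip)
  below[cbind(seq_len(n_tip), seq_len(n_tip))] <- TRUE
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    below[p, ] <- below[p, ] | below[ch, ]
  }
  m <- below[tree$edge[, 2], , drop = FALSE]
  colnames(m) <- tree$tip.label
  m
}

#' Genus monophyly report
#'
#' Calls each genus monophyletic, non-monophyletic or trivial under the
#' unrooted bipartition criterion: a genus with two or more tips is
#' monophyletic iff removing some edge bisects the tip set into exactly
#' that genus versus the rest (so the verdict does not depend on the
#' rooting). Singleton genera are labelled trivial, and a genus
#' comprising every tip is monophyletic by definition.
#'
#' @param gt a [genus_tree()].
#' @return data frame: `genus`, `n_tips`, `status` in
#'   `{"monophyletic", "non-monophyletic", "trivial"}`.
#' @export
monophyly_report <- function(gt) {
  stopifnot(inherits(gt, "genus_tree"))
  genus <- gt$genus[!is.na(gt$genus)]
  if (!length(genus)) mc_stop("no mapped tips", "input")
  bip <- edge_bipartitions(gt$tree)
  bip <- bip[, names(genus), drop = FALSE]  # ignored tips dropped
  genera <- sort(unique(genus))
  status <- character(length(genera))
  for (k in seq_along(genera)) {
    inset <- genus == genera[k]
    n_in <- sum(inset)
    if (n_in == 1L) { status[k] <- "trivial"; next }
    if (n_in == length(genus)) { status[k] <- "monophyletic"; next }
    hit <- FALSE
    for (e in seq_len(nrow(bip))) {
      side <- bip[e, ]
      if (all(side == inset) || all(side == !inset)) { hit <- TRUE; break }
    }
    status[k] <- if (hit) "monophyletic" else "non-monophyletic"
  }
  data.frame(genus = genera,
             n_tips = as.integer(table(genus)[genera]),
             status = status, stringsAsFactors = FALSE)
}
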