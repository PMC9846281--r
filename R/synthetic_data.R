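# Seeded generators: annotated circular genomes with planted gene-table
# truth, and codon alignments evolved under a known dN/dS (omega). They
# exist so every pipeline stage can be validated against planted values
# without downloading any accession.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Specification of a synthetic annotated mitogenome
#'
#' The layout defaults to the packaged vertebrate mitogenome annotation
#' (OP132373: 13 PCGs, 22 tRNAs, 2 rRNAs, NCR and control region on a
#' 16,592 bp circle, with its real overlaps and incomplete stop codons),
#' so generated genomes reproduce the gene-table structure the analysis
#' modules are built for. Heavy-strand base probabilities default to the
#' published whole-genome composition (A- and C-rich heavy strand).
#'
#' @param layout feature data frame (`name`, `cls`, `start`, `end`,
#'   `strand`, optional `anticodon`, and for PCGs `start_codon` plus
#'   `stop_codon` tokens `TAA`/`TAG`/`TA-`/`T--`).
#' @param length genome length in bp (default: maximal coordinate).
#' @param base_probs heavy-strand A/C/G/T probabilities (normalised).
#' @param seed integer seed; generation is fully reproducible from it.
#' @return list of class `genome_spec`.
#' @export
genome_spec <- function(layout = default_genome_layout(), length = NULL,
                        base_probs = c(A = 0.320, C = 0.262, G = 0.157,
                                       T = 0.262),
                        seed = 1L) {
  stopifnot(is.data.frame(layout))
  if (!"start_codon" %in% names(layout))
    layout$start_codon <- ifelse(layout$cls == "PCG", "ATG", NA)
  if (!"stop_codon" %in% names(layout))
    mc_stop("layout lacks a stop_codon plan for its PCGs", "format")
  stopifnot(setequal(names(base_probs), BASES), all(base_probs > 0))
  base_probs <- base_probs[BASES] / sum(base_probs)
  L <- as.integer(length %||% max(layout$end, layout$start))
  for (i in which(layout$cls == "PCG")) {
    len <- feature_length(layout[i, ], L)
    rem <- len %% 3L
    tok <- layout$stop_codon[i]
    ok <- (rem == 0L && tok %in% c("TAA", "TAG")) ||
      (rem == 2L && tok == "TA-") || (rem == 1L && tok == "T--")
    if (is.na(tok) || !ok)
      mc_stop(sprintf(
        "PCG %s: stop plan '%s' inconsistent with length %d (mod 3 = %d)",
        layout$name[i], tok, len, rem), "generation")
    if (is.na(layout$start_codon[i]))
      mc_stop(paste("PCG lacks a start codon plan:", layout$name[i]),
              "generation")
  }
  structure(list(layout = layout, length = L, base_probs = base_probs,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' @rdname genome_spec
#' @export
default_genome_layout <- function() {
  path <- system.file("extdata", "OP132373_feature_table.tsv",
                      package = "mitochar")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  names(tab)[names(tab) == "from"] <- "start"
  names(tab)[names(tab) == "to"] <- "end"
  tab[c("name", "cls", "start", "end", "strand", "anticodon",
        "start_codon", "stop_codon")]
}

# Heavy-strand positions of a feature in sense order.
h_positions <- function(f, L) {
  pos <- if (f$start <= f$end) f$start:f$end else c(f$start:L, 1:f$end)
  if (identical(f$strand, "L")) rev(pos) else pos
}

#' Generate a synthetic annotated mitogenome with known truth
#'
#' Builds a heavy-strand sequence realising the layout: every PCG gets
#' its planned start codon, a stop-free interior and its planned
#' (complete or incomplete) stop codon on its own sense strand --
#' including light-strand genes and the layout's planned gene overlaps,
#' where overlapping reading frames constrain each other and are solved
#' jointly (an unsatisfiable overlap raises a generation error). All
#' remaining positions are drawn independently from the heavy-strand
#' base probabilities; PCG interior codons are drawn with the same
#' per-base weights restricted to non-stop codons. The truth record
#' carries every planted discrete value plus the exact expectation and
#' standard deviation of the base counts under the sampling scheme, so a
#' round trip `gene_table(generate_mitogenome(spec))` can be checked
#' exactly and the composition within sampling error.
#'
#' @param spec a [genome_spec()].
#' @return list with elements `genome` (a [mito_genome()]) and `truth`
#'   (list: `seed`, `base_probs`, planted `start_codon` / `stop_codon` /
#'   `strand` / `spacer_to_next` per feature, `expected_counts`,
#'   `sd_counts`).
#' @examples
#' sim <- generate_mitogenome(genome_spec(seed = 7))
#' sim$genome
#' @export
generate_mitogenome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    L <- spec$length
    layout <- spec$layout
    p <- spec$base_probs
    chars <- rep(NA_character_, L)
    exp_counts <- c(A = 0, C = 0, G = 0, T = 0)
    var_counts <- exp_counts
    sense_codons <- {
      tab <- mito_genetic_code("2")
      names(tab)[tab != "*"]
    }
    codon_mat <- do.call(rbind, strsplit(sense_codons, "", fixed = TRUE))

    write_fixed <- function(f, sense_idx, sense_bases) {
      pos <- h_positions(f, L)[sense_idx]
      hb <- if (identical(f$strand, "L")) unname(COMPLEMENT[sense_bases])
            else sense_bases
      for (t in seq_along(pos)) {
        old <- chars[pos[t]]
        if (!is.na(old)) {
          if (old != hb[t])
            mc_stop(sprintf(
              "infeasible layout: position %d needs both %s and %s",
              pos[t], old, hb[t]), "generation")
        } else {
          chars[pos[t]] <<- hb[t]
          exp_counts[hb[t]] <<- exp_counts[hb[t]] + 1
        }
      }
    }

    pcg_idx <- which(layout$cls == "PCG")
    # pass 1: plant start codons and stop codons/remnants (hard constraints)
    for (i in pcg_idx) {
      f <- as.list(layout[i, ])
      len <- feature_length(f, L)
      start <- strsplit(f$start_codon, "", fixed = TRUE)[[1]]
      write_fixed(f, 1:3, start)
      tok <- f$stop_codon
      tail_bases <- switch(tok, "TAA" = c("T", "A", "A"),
                           "TAG" = c("T", "A", "G"),
                           "TA-" = c("T", "A"), "T--" = "T")
      write_fixed(f, (len - base::length(tail_bases) + 1L):len, tail_bases)
    }
    # pass 2: fill PCG interiors codon by codon, honouring fixed positions
    for (i in pcg_idx) {
      f <- as.list(layout[i, ])
      len <- feature_length(f, L)
      n_full <- len %/% 3L
      interior <- if (len %% 3L == 0L) seq_len(n_full)[-c(1L, n_full)]
                  else seq_len(n_full)[-1L]
      pos_all <- h_positions(f, L)
      sense_p <- if (identical(f$strand, "L"))
        setNames(p[unname(COMPLEMENT[BASES])], BASES) else p
      for (k in interior) {
        pos <- pos_all[(3L * k - 2L):(3L * k)]
        have <- chars[pos]
        sense_fixed <- ifelse(is.na(have), NA,
                              if (identical(f$strand, "L"))
                                unname(COMPLEMENT[have]) else have)
        free <- is.na(sense_fixed)
        if (!any(free)) {
          cd <- paste(sense_fixed, collapse = "")
          if (!cd %in% sense_codons)
            mc_stop(sprintf(
              "infeasible layout: overlap forces stop codon in %s",
              f$name), "generation")
          next
        }
        cand <- rep(TRUE, base::length(sense_codons))
        for (t in which(!free))
          cand <- cand & codon_mat[, t] == sense_fixed[t]
        if (!any(cand))
          mc_stop(sprintf(
            "infeasible layout: no stop-free codon fits %s in %s",
            paste(ifelse(free, ".", sense_fixed), collapse = ""), f$name),
            "generation")
        w <- rep(1, sum(cand))
        sub <- codon_mat[cand, , drop = FALSE]
        for (t in which(free)) w <- w * sense_p[sub[, t]]
        w <- w / sum(w)
        pick <- sample.int(nrow(sub), 1L, prob = w)
        sense_bases <- sub[pick, ]
        hb <- if (identical(f$strand, "L")) unname(COMPLEMENT[sense_bases])
              else sense_bases
        # expectation over the candidate distribution, free positions only
        for (b in BASES) {
          cnt <- rowSums(matrix(
            (if (identical(f$strand, "L"))
               matrix(COMPLEMENT[sub], nrow(sub)) else sub)[, free,
                                                            drop = FALSE]
            == b, nrow = nrow(sub)))
          m1 <- sum(w * cnt)
          exp_counts[b] <- exp_counts[b] + m1
          var_counts[b] <- var_counts[b] + sum(w * cnt^2) - m1^2
        }
        chars[pos[free]] <- hb[free]
      }
    }
    # pass 3: background fill from the heavy-strand base probabilities
    na_idx <- which(is.na(chars))
    if (base::length(na_idx)) {
      chars[na_idx] <- sample(BASES, base::length(na_idx), replace = TRUE,
                              prob = p)
      exp_counts <- exp_counts + base::length(na_idx) * p
      var_counts <- var_counts + base::length(na_idx) * p * (1 - p)
    }
    genome <- mito_genome(layout, seq = paste(chars, collapse = ""))
    # verify planted codon truth before handing the genome out
    for (i in pcg_idx) {
      cc <- classify_codons(feature_sequence(genome, i))
      if (!identical(cc$start_codon, layout$start_codon[i]) ||
          !identical(cc$stop_codon, layout$stop_codon[i]))
        mc_stop(paste("generation self-check failed for", layout$name[i]),
                "generation")
    }
    truth <- list(
      seed = spec$seed, base_probs = p,
      name = layout$name, cls = layout$cls, strand = layout$strand,
      start_codon = layout$start_codon, stop_codon = layout$stop_codon,
      spacer_to_next = vapply(seq_len(nrow(layout)), function(i)
        spacer_to_next(genome, i), 0L),
      expected_counts = exp_counts, sd_counts = sqrt(var_counts))
    list(genome = genome, truth = truth)
  })
}

#' Specification of a simulated codon alignment
#'
#' Parameters of the star-tree codon substitution process used by
#' [generate_codon_alignment()]: `omega` is the
#' nonsynonymous/synonymous rate ratio the Ka/Ks screen estimates,
#' `kappa` the transition/transversion rate ratio, and `branch_length`
#' the expected number of substitutions per codon site from the
#' ancestor to each taxon.
#'
#' @param n_taxa number of taxa (tips of the star tree), >= 2.
#' @param n_codons codons per sequence, >= 10.
#' @param omega nonsynonymous/synonymous rate ratio, > 0.
#' @param kappa transition/transversion rate ratio, > 0.
#' @param branch_length expected substitutions per codon site per branch.
#' @param codon_freqs optional stationary codon frequencies (named over
#'   the sense codons); uniform by default.
#' @param code NCBI translation table id.
#' @param seed integer seed.
#' @return list of class `alignment_spec`.
#' @export
alignment_spec <- function(n_taxa = 10L, n_codons = 500L, omega = 0.2,
                           kappa = 2, branch_length = 0.1,
                           codon_freqs = NULL, code = "2", seed = 1L) {
  stopifnot(n_taxa >= 2L, n_codons >= 10L, omega > 0, kappa > 0,
            branch_length >= 0)
  structure(list(n_taxa = as.integer(n_taxa),
                 n_codons = as.integer(n_codons), omega = omega,
                 kappa = kappa, branch_length = branch_length,
                 codon_freqs = codon_freqs, code = code,
                 seed = as.integer(seed)),
            class = "alignment_spec")
}

# Continuous-time codon rate matrix over the sense codons: single-
# nucleotide exchanges only, rate kappa for transitions, times omega
# when nonsynonymous, times the target codon's stationary frequency,
# scaled to one expected substitution per codon site per unit time.
codon_rate_matrix <- function(omega, kappa, codon_freqs = NULL,
                              code = "2") {
  tab <- mito_genetic_code(code)
  sense <- names(tab)[tab != "*"]
  n <- base::length(sense)
  pi <- if (is.null(codon_freqs)) setNames(rep(1 / n, n), sense)
        else codon_freqs[sense] / sum(codon_freqs[sense])
  Q <- matrix(0, n, n, dimnames = list(sense, sense))
  mat <- do.call(rbind, strsplit(sense, "", fixed = TRUE))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- which(mat[i, ] != mat[j, ])
      if (base::length(d) != 1L) next
      r <- if (is_transition(mat[i, d], mat[j, d])) kappa else 1
      if (tab[[sense[i]]] != tab[[sense[j]]]) r <- r * omega
      Q[i, j] <- r * pi[[j]]
    }
  }
  total <- rowSums(Q)
  mu <- sum(pi * total)
  Q <- Q / mu
  list(Q = Q, pi = pi, sense = sense,
       nonsyn = outer(tab[sense], tab[sense], "!="))
}

#' Simulate a codon alignment on a star tree
#'
#' Samples an ancestral sequence from the stationary codon frequencies
#' and evolves each taxon independently along one branch of length
#' `branch_length` with an exact stochastic simulation (Gillespie jump
#' chain) of the codon substitution process: single-nucleotide steps,
#' transitions accelerated by `kappa`, nonsynonymous steps scaled by
#' `omega`, stop codons unreachable. Every realised substitution is
#' classified and logged, so the simulation's own synonymous /
#' nonsynonymous event counts are part of the truth record.
#'
#' @param spec an [alignment_spec()].
#' @return list with `alignment` (a [codon_alignment()]) and `truth`
#'   (list: the spec parameters plus `n_syn_events`, `n_nonsyn_events`,
#'   `expected_nonsyn_fraction`, `ancestor`).
#' @examples
#' sim <- generate_codon_alignment(alignment_spec(n_taxa = 4,
#'                                                n_codons = 50,
#'                                                omega = 0.1, seed = 3))
#' sim$alignment$n_codons
#' @export
generate_codon_alignment <- function(spec) {
  stopifnot(inherits(spec, "alignment_spec"))
  rm_ <- codon_rate_matrix(spec$omega, spec$kappa, spec$codon_freqs,
                           spec$code)
  Q <- rm_$Q
  sense <- rm_$sense
  n <- base::length(sense)
  total_rate <- rowSums(Q)
  nonsyn_rate <- rowSums(Q * rm_$nonsyn)
  exp_nonsyn_frac <- sum(rm_$pi * nonsyn_rate) / sum(rm_$pi * total_rate)
  with_seed(spec$seed, {
    anc <- sample.int(n, spec$n_codons, replace = TRUE,
                      prob = as.numeric(rm_$pi))
    n_syn <- 0L
    n_nonsyn <- 0L
    seqs <- character(spec$n_taxa)
    for (taxon in seq_len(spec$n_taxa)) {
      state <- anc
      if (spec$branch_length > 0) {
        for (site in seq_len(spec$n_codons)) {
          cur <- state[site]
          t <- stats::rexp(1L, total_rate[cur])
          while (t <= spec$branch_length) {
            nxt <- sample.int(n, 1L, prob = Q[cur, ])
            if (rm_$nonsyn[cur, nxt]) n_nonsyn <- n_nonsyn + 1L
            else n_syn <- n_syn + 1L
            cur <- nxt
            t <- t + stats::rexp(1L, total_rate[cur])
          }
          state[site] <- cur
        }
      }
      seqs[taxon] <- paste(sense[state], collapse = "")
    }
    names(seqs) <- sprintf("taxon%02d", seq_len(spec$n_taxa))
    aln <- codon_alignment(seqs, gene = "simulated", code = spec$code,
                           trim_stops = FALSE)
    truth <- list(omega = spec$omega, kappa = spec$kappa,
                  branch_length = spec$branch_length, seed = spec$seed,
                  n_syn_events = n_syn, n_nonsyn_events = n_nonsyn,
                  expected_nonsyn_fraction = exp_nonsyn_frac,
                  ancestor = paste(sense[anc], collapse = ""))
    list(alignment = aln, truth = truth)
  })
}
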