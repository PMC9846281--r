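# Independent oracles used by the tests. They deliberately share no code
# with the package internals: translation comes from seqinr, pathway
# enumeration is a fresh recursive implementation, and monophyly is
# decided by deleting edges and flood-filling components.

oracle_code_table <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  aa <- vapply(codons, function(cd)
    seqinr::translate(strsplit(cd, "")[[1]], numcode = 2), "")
  setNames(aa, codons)
}

oracle_sites <- function(codon, tab) {
  bases <- c("A", "C", "G", "T")
  s <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) {
    n_valid <- 0
    n_syn <- 0
    for (b in bases[bases != s[pos]]) {
      m <- s
      m[pos] <- b
      mut <- paste(m, collapse = "")
      if (tab[[mut]] == "*") next
      n_valid <- n_valid + 1
      if (tab[[mut]] == tab[[codon]]) n_syn <- n_syn + 1
    }
    if (n_valid > 0) syn <- syn + n_syn / n_valid
  }
  syn
}

oracle_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in oracle_permutations(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

# Average syn/nonsyn steps over stop-free pathways between two codons.
oracle_path <- function(a, b, tab) {
  sa <- strsplit(a, "")[[1]]
  sb <- strsplit(b, "")[[1]]
  d <- which(sa != sb)
  if (!length(d)) return(c(0, 0))
  acc <- c(0, 0)
  n_ok <- 0
  for (ord in oracle_permutations(d)) {
    cur <- sa
    step <- c(0, 0)
    bad <- FALSE
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- sb[pos]
      if (tab[[paste(nxt, collapse = "")]] == "*") { bad <- TRUE; break }
      if (tab[[paste(cur, collapse = "")]] ==
          tab[[paste(nxt, collapse = "")]]) step[1] <- step[1] + 1
      else step[2] <- step[2] + 1
      cur <- nxt
    }
    if (!bad) { acc <- acc + step; n_ok <- n_ok + 1 }
  }
  if (n_ok == 0) return(NULL)
  acc / n_ok
}

oracle_ng86 <- function(seq_a, seq_b, tab = oracle_code_table()) {
  ca <- substring(seq_a, seq(1, nchar(seq_a), 3), seq(3, nchar(seq_a), 3))
  cb <- substring(seq_b, seq(1, nchar(seq_b), 3), seq(3, nchar(seq_b), 3))
  S <- 0; Sd <- 0; Nd <- 0; n_used <- 0
  for (k in seq_along(ca)) {
    if (!grepl("^[ACGT]{3}$", ca[k]) || !grepl("^[ACGT]{3}$", cb[k])) next
    if (tab[[ca[k]]] == "*" || tab[[cb[k]]] == "*") next
    pd <- oracle_path(ca[k], cb[k], tab)
    if (is.null(pd)) next
    n_used <- n_used + 1
    S <- S + (oracle_sites(ca[k], tab) + oracle_sites(cb[k], tab)) / 2
    Sd <- Sd + pd[1]
    Nd <- Nd + pd[2]
  }
  N <- 3 * n_used - S
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else
    -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, n_codons = n_used,
       Ks = jc(if (S > 0) Sd / S else NA), Ka = jc(if (N > 0) Nd / N
                                                   else NA))
}

# All bipartitions of an unrooted tree, by deleting each internal edge
# and flood-filling one component over the remaining edges.
oracle_bipartitions <- function(tree) {
  n_tip <- length(tree$tip.label)
  edges <- tree$edge
  out <- list()
  for (e in seq_len(nrow(edges))) {
    adj <- edges[-e, , drop = FALSE]
    seen <- edges[e, 2]
    repeat {
      hit <- adj[, 1] %in% seen | adj[, 2] %in% seen
      grow <- unique(c(adj[hit, 1], adj[hit, 2]))
      if (all(grow %in% seen)) break
      seen <- union(seen, grow)
    }
    out[[e]] <- sort(tree$tip.label[intersect(seen, seq_len(n_tip))])
  }
  out
}

oracle_monophyly <- function(tree, genus) {
  bips <- oracle_bipartitions(tree)
  all_tips <- sort(tree$tip.label)
  verdict <- character(0)
  for (g in sort(unique(genus))) {
    tips_g <- sort(names(genus)[genus == g])
    if (length(tips_g) == 1) { verdict[g] <- "trivial"; next }
    if (length(tips_g) == length(all_tips)) {
      verdict[g] <- "monophyletic"; next
    }
    comp <- sort(setdiff(all_tips, tips_g))
    hit <- any(vapply(bips, function(b)
      identical(b, tips_g) || identical(b, comp), TRUE))
    verdict[g] <- if (hit) "monophyletic" else "non-monophyletic"
  }
  verdict
}

# Random in-frame codon pairs over the sense codons of code table 2.
random_codon_pair <- function(n_codons, p_mut = 0.3, tab =
                                oracle_code_table()) {
  sense <- names(tab)[tab != "*"]
  a <- sample(sense, n_codons, replace = TRUE)
  b <- a
  mut <- runif(n_codons) < p_mut
  b[mut] <- sample(sense, sum(mut), replace = TRUE)
  c(paste(a, collapse = ""), paste(b, collapse = ""))
}
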