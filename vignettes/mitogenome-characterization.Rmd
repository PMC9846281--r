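---
title: "Characterising annotated mitochondrial genomes with mitochar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising annotated mitochondrial genomes with mitochar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochar)
```

## What the package computes

A vertebrate mitogenome is a circular DNA molecule of roughly 16--17 kb
carrying 13 protein-coding genes (PCGs), 22 tRNAs, 2 rRNAs and a
non-coding control region (D-LOOP). Characterising a newly annotated
mitogenome is a standard exercise with a fixed repertoire of statistics,
and `mitochar` implements that repertoire as tested, reusable functions:

* **gene-table arithmetic** -- feature lengths, signed intergenic
  spacers and overlaps on the circle, start/stop codon classification
  including the incomplete T/TA stops completed by polyadenylation;
* **base composition and strand skews** -- AT-skew = (A−T)/(A+T) and
  GC-skew = (G−C)/(G+C) per gene and per partition;
* **codon usage** -- counts, usage percentages and relative synonymous
  codon usage (RSCU) under the vertebrate mitochondrial code;
* **selection screening** -- per-gene Ka/Ks across many taxa with the
  Nei--Gojobori (1986) pathway estimator and Jukes--Cantor correction;
* **genus monophyly** -- post-hoc interrogation of published trees by
  the unrooted edge-bipartition criterion;
* **synthetic data** -- seeded generators of annotated genomes and
  codon alignments with known truth, so every stage above is testable
  offline.

The packaged reference annotation (`inst/extdata`) is the published
gene table and composition table of the *Rectoris luxiensis* mitogenome,
GenBank OP132373 (16,592 bp).

## Circular coordinate conventions

Coordinates are 1-based inclusive on the heavy strand, as in GenBank.
A feature with `start > end` wraps the replication origin; its length is
`(L − start + 1) + end`. The signed spacer attributed to a feature is
the gap to the **next** feature in annotation order (the last feature
closes the circle to the first); negative spacers are overlaps. With
this convention the telescoping identity

> Σ over features of (length + spacer to next) = genome length

holds exactly on every genome, and it reproduces every printed
intergenic value of the packaged reference table. The table's footnote
describes the column as the gap to the *previous* gene, but the printed
numbers (e.g. 20 bp on the tRNA-Val row, 24 bp on the 16S row, −2 bp on
the tRNA-Ile row) only follow from next-feature arithmetic, which we
therefore adopt.

Two further reporting conventions matter for the overlap/IGN summary:

* the spacer immediately upstream of the control region (16 bp between
  tRNA-Pro and the D-LOOP in the reference) is treated as the control
  region's flank, not as an intergenic region. This matches the
  published counting (17 regions, 84 bp; with the flank it would be 18
  and 100). The choice is exposed as `count_dloop_flank`.
* the 32-bp non-coding NCR between tRNA-Asn and tRNA-Cys is an
  annotated feature, not an intergenic region, again following the
  reference table.

One published value is internally inconsistent: the tRNA-Ser1 row
prints a length of 67 bp, but its own coordinates (11,813..11,881, with
a 1-bp gap to tRNA-Leu1 at 11,883) give 69 bp. The package always
reports coordinate-derived lengths; the telescoping identity closes the
16,592 bp circle only with 69.

## Composition and skews

Skews are computed from raw counts, never from rounded percentages;
ambiguity codes are excluded from numerator and denominator (the
simplest defensible rule -- fractional allocation would change third
decimals at most on real data). `skew_from_percentages()` is a separate
audit path that applies the formulae to *printed* percentages, which is
how published tables can be checked without the sequence; both paths
agree on sequences built to hit given percentages.

Per-gene composition uses the **sense strand**: the published ND6 row
(T 42.8%, G 32.2%, skews −0.52/+0.47, opposite in sign to the
genome-wide 0.10/−0.25) is only reproducible if the light-strand gene
is read on its own strand. Concatenated partitions (rRNAs, tRNAs,
D-LOOP, all PCGs) and the Total row are reported as annotated on the
heavy strand; `pcg_partition_strand = "sense"` switches the PCG
partition if a sense-strand concatenation is wanted. PCG partitions use
the full annotated ranges including stop codons.

## Codon usage and RSCU

RSCU(c) = count(c) × k / n for codon *c* in a synonymous family of size
*k* observed *n* times in total. Families are derived from the genetic
code at run time as connected components of the single-substitution
graph within one amino acid's codons: under the vertebrate
mitochondrial code the six Leu codons are mutually reachable and form
one family, while Ser splits into the disconnected UCN (Ser1, four
codons) and AGY (Ser2, two codons) blocks. Multiple components of one
amino acid are numbered by decreasing size, reproducing the
conventional Ser1/Ser2 labels without hard-coding them.

Counting conventions (declared, since published RSCU figures rarely
state them): start codons are counted, complete terminal stops and
trailing T/TA remnants are excluded, codons containing N are skipped
and tallied, and internal stop codons warn (annotations are sometimes
imperfect) and are excluded like terminal stops. RSCU output uses the
RNA alphabet to match the field's plots.

## Ka/Ks: the NG86 pathway estimator

The selection screen needs a fully specified, auditable estimator, so
the package implements Nei--Gojobori (1986) rather than wrapping a GUI
tool. Per codon, each position contributes the fraction of its three
possible point mutations that are synonymous; mutations creating stops
are excluded from the denominator. This makes S + N = 3 × codons exact,
a property the tests assert on every pair. Codon pairs differing at two
or three positions average the step classification over all orderings
of single steps with equal weights; orderings passing through a stop
codon are excluded, and a codon pair whose every ordering is excluded
is skipped and counted. Proportions use sites averaged over the two
sequences and are corrected with the Jukes--Cantor distance
d = −(3/4)·ln(1 − 4p/3), undefined (flagged, never infinite) at
p ≥ 3/4.

Across taxa, a gene's aggregate is the **ratio of mean distances**
(mean Ka over defined pairs divided by mean Ks), not the mean of
per-pair ratios: near-zero pairwise Ks values would otherwise dominate
the average. Undefined aggregates (mean Ks = 0) are flagged. Modified
NG (unequal pathway weights), Li-type and maximum-likelihood estimators
are deliberately out of scope; the implementation is pinned to the
classical equal-weight method so its numbers are reproducible from the
definition, and the test suite holds it to an independent brute-force
pathway-enumeration oracle at 1e−9.

## The synthetic-data generators

`generate_mitogenome()` emulates exactly the structure the analysis
assumes: the default layout is the packaged published annotation
(coordinates, strands, planned start/stop codons, the ten real
overlaps, the three incomplete-stop genes), and heavy-strand bases are
drawn i.i.d. from the published whole-genome composition
(A 0.320, C 0.262, G 0.157, T 0.262 before normalisation), so the
A/C-rich heavy strand and the sign structure of the skews emerge by
construction. PCG interiors are drawn codon-wise with the same per-base
weights restricted to non-stop codons; overlapping reading frames
constrain each other and are solved jointly, with an error if a layout
is unsatisfiable. The truth record carries every planted discrete value
plus the exact expectation and standard deviation of the base counts
under the sampling scheme (accumulated from the conditional
distribution actually used at each draw), so round-trip tests can check
discrete truths exactly and composition within 3 standard errors
without re-deriving the mixture analytically.

`generate_codon_alignment()` evolves sequences on a **star tree** with
an exact Gillespie simulation of a codon substitution process:
single-nucleotide steps, transitions scaled by κ, nonsynonymous steps
scaled by ω, stop codons unreachable, rates scaled to one expected
substitution per codon site per unit branch length. Defaults are 10
taxa, 500 codons, κ = 2 (a modest vertebrate transition bias, the
conventional initialiser), branch length 0.1 -- moderate divergence at
which the Jukes--Cantor correction is accurate. Every realised
substitution is classified and logged, so the simulator's own
synonymous/nonsynonymous event counts can be tested against the rate
matrix's expectation.

What the generators deliberately do **not** emulate: tRNA secondary
structure, within-genome rate heterogeneity, tree-shaped (non-star)
phylogenies, indels and alignment error, and sequencing/assembly noise.
Passing the round-trip tests therefore shows that the *arithmetic* is
right under the declared model, not that real data meet the model.

## Validation scale and expected behaviour

The test suite validates the estimator at 10 taxa × 500 codons with 20
replicates per ω ∈ {0.05, 0.2, 0.5, 1.0} (the acceptance script uses 10
replicates per ω); these sizes give stable aggregate ratios while
keeping a full run in well under a minute of simulation time. Under
these conditions the estimated aggregate ratio is rank-concordant with
ω in every replicate, every ω < 1 run estimates below one -- the
desk-scale analogue of the published all-genes-under-purifying-selection
finding -- and the ω = 1 mean lands a little below one (about 0.85-0.9):
the classical NG86 estimator counts sites assuming equal mutation
rates, so a transition bias (κ > 1) inflates the synonymous proportion
and depresses the ratio slightly at neutrality. This bias is a known
property of the method, not a defect of the implementation, and is why
the neutrality check accepts [0.8, 1.25].

## Monophyly calls

A genus with ≥ 2 tips is monophyletic iff some edge's removal bisects
the tips into exactly that genus versus the rest. The unrooted
bipartition criterion is robust to where a published tree happens to be
rooted -- verdicts are invariant under rerooting, which the tests
assert -- while a rooted-clade reading would not be. Singleton genera
are reported as `trivial` rather than trivially monophyletic so that
summary counts of non-monophyly are not diluted. Genus names default to
the token before the first underscore in tip labels and can be replaced
by an explicit map; unmapped tips are an error unless explicitly
ignored. The published 91-taxon tree exists only as figure artwork, so
the specific published genus verdicts can be checked only against a
user-supplied machine-readable tree; the implementation is instead held
to a brute-force edge-removal oracle on random trees.

## Degenerate inputs and numerical choices

* Coordinates-only genomes (a feature table without FASTA) support all
  coordinate arithmetic; sequence operations refuse with a classed
  error rather than guessing.
* A single-feature genome defines its spacer as the self-wrap gap
  L − length.
* An empty feature table is valid; the telescoping identity is
  vacuously true.
* Skew denominators of zero give NA ("undefined"), with an error only
  when both skews are undefined.
* Reports round to 2 decimals (matching the published tables); returned
  objects and JSON keep full precision.
* All generation is seeded explicitly and restores the caller's RNG
  state; identical seeds give byte-identical output.

## Known limitations

* GenBank parsing targets the flat-file subset mitogenome records use
  (single sequence; CDS/tRNA/rRNA/D-loop features; `complement` and
  origin-spanning `join` locations), not the full format.
* No de novo annotation, ORF finding, alignment construction or tree
  inference: inputs are taken as annotated/aligned/inferred.
* Ka/Ks is the classical NG86 estimator only; with strong transition
  bias or saturation it inherits that estimator's known biases.
* The PCG composition partition uses full annotated gene ranges;
  published tables that trim stop codons can differ in the second
  decimal.
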