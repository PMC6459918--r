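---
title: "Methods: PT landscapes, defence-system neighbourhoods and coevolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PT landscapes, defence-system neighbourhoods and coevolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thioscape)
```

# The model

## Duplex loci and modification states

DNA phosphorothioate (PT) modification replaces a non-bridging oxygen of
a backbone phosphate with sulphur. In the haloarchaeal systems this
package models, PT occurs at the G–A linkage of 5′-GATC-3′. Because
GATC equals its own reverse complement, each plus-strand occurrence is a
*duplex locus*: the bottom strand carries the same motif running the
other way, with its modifiable G opposite the top-strand C. The package
therefore stores a single 0-based coordinate per locus (the plus-strand
G) and pairs strand-resolved calls by pure integer arithmetic: a `+`
call at position $p$ and a `-` call at $p + 3$ belong to the same locus.
No fuzzy matching is used; a call that hits no scanned locus is returned
separately as an orphan, with a warning, rather than being dropped.

Each locus takes one of four states: `none`, `hemi_plus`, `hemi_minus`
or `full` (both strands called). Two conventions are pinned because the
printed statistics depend on them:

* the *percent modified* is the fraction of duplex loci with at least
  one call, rounded to one decimal;
* the *hemi percentage* is the fraction of modified loci with exactly
  one call, rounded to the nearest integer.

Strand-level call counts (`n_plus_calls = n_full + n_hemi_plus`, and
symmetrically for the minus strand) are reported alongside, because
site totals quoted per strand count calls, not duplex loci, and the two
conventions differ whenever full sites exist. `calls_per_10kb` is
defined as strand-level calls per $2 L$ nucleotides of a genome of
length $L$ — a genome-wide density proxy from called sites. It is
deliberately documented as *not* comparable to bulk biochemical (LC-MS)
PT-per-nucleotide frequencies, which measure a different quantity on a
different material.

Genomes are treated as linear for spacing and feature overlap; circular
wrap-around is not applied. Spacing is computed per strand by default
(consecutive differences of sorted modified-G coordinates), with a
`combined` mode pooling both strands, because published spacing ranges
do not state which convention was used; both are available so a reader
can check either. Flanking-base context bias compares base frequencies
at offsets −1 and +1 among modified loci against all loci, as a log2
ratio; loci lacking a flank at a contig edge are excluded from both
numerator and background, and zero cells are flagged undefined rather
than given an infinite enrichment.

## Neighbourhood mining

Protein homology hits arrive in the standard 12-column tabular dialect
plus a side table of query lengths (the 12 columns do not carry the
query length, which the aligned-length filter needs). The filter keeps
a hit iff its e-value is at most $10^{-10}$ *and* its aligned length is
at least 30 % of the query length. Published descriptions of such
filters disagree at exactly 30 % (one phrasing keeps it, another drops
it); the package keeps the boundary (`>=`) by default and exposes
`len_boundary = "gt"` for the other reading.

Modification loci are built by pairing each *dndC* with its nearest
*dndD* on the same contig at an edge-to-edge gap of at most 5 kb, ties
broken towards the smaller start coordinate. Neighbourhood rules are
evaluated on edge-to-edge gaps measured from the locus span, with
"within 1 bp–W kb" read as gap $\in [0, W]$ — overlapping or abutting
genes count as present, since excluding overlapping genes would be
biologically arbitrary. The restriction cassette counts as present only
when all three of *dndF*, *dndG*, *dndH* fall inside the window; the
exclusion cassette is queried through *pbeA* and *pbeC* (its two
annotatable members; *pbeB* and *pbeD* are too small to be reliably
annotated), both required. For pbeAC-centred classification the
modification partner is the *dndCD locus* (the paired cluster), not
either gene alone, so a planted gap is exactly the gap the classifier
measures. When hits are reduced to annotations, the best kept hit per
(genome, query) — lowest e-value, then highest bitscore — becomes one
gene; best-hit is the minimal standard reduction and is applied
uniformly.

The four pbeAC categories (`dnd_only`, `mtase_only`, `both`,
`solitary`) partition any input set by construction, and enlarging any
window can only turn flags on — both properties are enforced by tests.

## Alignment and similarity rates

The aligner is an affine-gap global aligner (Gotoh three-state dynamic
programme, compiled) under the conventions of the classic needle
program, whose output defines the similarity statistic:

* a gap of length $L$ costs $\mathrm{open} + (L-1)\,\mathrm{extend}$,
  with defaults 10 and 0.5 on BLOSUM62;
* end gaps are unpenalised by default (`end_gaps_penalized = FALSE`);
* `pct_identity` is the percentage of alignment columns with identical
  residues, `pct_similarity` the percentage of columns with a positive
  substitution score; gap columns count in the denominator only, so
  identity ≤ similarity ≤ 100 always;
* traceback ties resolve deterministically, diagonal over a gap in the
  second sequence over a gap in the first, so repeated runs are
  byte-identical.

Tests verify exact score equivalence against a brute-force enumeration
of *every* gapped alignment for short pairs. Exhaustive enumeration is
combinatorial (the number of alignments of two length-12 sequences
already exceeds $10^9$), so the enumeration oracle covers pairs up to
6 residues, where all paths can be scored in milliseconds; longer pairs
up to 40 residues are cross-checked against an independent aligner
(Biostrings, ends-free mode, with its gap convention translated:
opening 9.5 + extension 0.5 there equals open 10 / extend 0.5 here).

Similarity-rate tables concatenate each strain's gene pair in fixed
gene order (C then D; A then C) and align against the concatenated
reference, mirroring how the corresponding trees are built from
concatenated proteins; a per-component averaging mode is exposed as an
alternative (`concat = FALSE`) since either convention is defensible.
`coevolution_fit()` reports Spearman ρ as the headline correlation —
the published analyses print "ρ" without naming the estimator, and the
rank correlation has the attractive property of being invariant under
the similarity-to-divergence flip $s \mapsto 100 - s$ applied to both
columns — together with Pearson r and the least-squares regression of
partner similarity on modification similarity. Constant columns flag
the correlations as undefined instead of returning a spurious value.

## Distance trees

`distance_matrix()` aligns every pair once and records
$d = 1 - \mathrm{identity}/100$, so the matrix is symmetric with a zero
diagonal by construction. `nj_tree()` applies standard neighbour
joining (exact on additive matrices; verified on four-taxon additive
fixtures to $10^{-9}$). Maximum-likelihood refinement and bootstrap
support are out of scope: NJ on alignment distances is the desk-scale
initial-tree method, and the package's trees are interchange objects
(Newick via `write_newick()`), not publication phylogenies. Negative NJ
branch estimates, which arise on non-additive input, are clamped to
zero with a warning to keep the Newick valid.

## Assay scalars

Three pure formulas: efficiency of plating (test titre / reference
titre), relative viral load $2^{\mathrm{CT}(radA) - \mathrm{CT}(repA)}$
(host single-copy gene minus viral replication gene, so a more abundant
viral template gives a larger fold), and the unadsorbed-virus
percentage ($100 \times$ titre at time $t$ / initial titre). The CT
difference direction is pinned exactly as printed in the source assay
because reversing it inverts every fold change.

# The synthetic-data generator

The generator exists so that every analysis stage can be exercised, and
scored against ground truth, without sequencing data. Its defaults are
the study conditions the analyses target: a chromosome-scale
(4 Mb) genome carrying 94,316 GATC duplex loci of which 1,310 are fully
and 1,141 hemi modified; 553 pbeAC neighbourhoods partitioned
128/155/105/165 across modification-partner categories; and
protein-family pairs with rank correlation 0.582 across strains. Values
the source material does not state were fixed once at field-typical
levels: GC content 0.62 (haloarchaeal genomes are GC-rich), an even
split of hemi calls between strands, substitution fractions between
0.05 and 0.5 per site.

Design points worth knowing:

* **Exact motif counts.** Spontaneous GATC occurrences in the random
  background are destroyed by resampling one free base each, iterating
  until the genome contains exactly the planted occurrences. Worked
  examples need exact denominators; an approximate count would smear
  every percentage. Planted motifs are at least 4 bp apart and never
  contain N.
* **Exactly measurable gaps.** Defence clusters are planted so the
  drawn gap equals the edge-to-edge gap the classifier measures, with
  partners placed left or right of the focal cluster as geometry
  requires. In strict mode the generator refuses gap ranges under which
  a planted partner could cross its category's window boundary (it
  accounts for the span of the partner's farthest required gene), so
  planted ground truth is never ambiguous.
* **Gaussian-copula divergence.** Paired substitution fractions are
  drawn from a Gaussian copula with uniform margins; the copula
  parameter is set to $2\sin(\pi\rho_S/6)$ so the *population Spearman
  correlation* equals the requested value exactly. This is the simplest
  model with a tunable rank correlation; nothing in the analyses
  depends on the copula family.
* **Substitution-only proteins.** Strain sequences derive from the
  references by point substitutions at the drawn fraction, no indels,
  keeping the planted divergence directly interpretable against
  alignment similarity. Indel robustness is a property of the aligner's
  tests, not of the mutation model.
* **Labelled decoys.** Homology-hit fixtures mix rows satisfying both
  filter rules with decoys violating exactly one, each row labelled, so
  the filter is scored row-by-row rather than in aggregate.
* **Determinism.** Identical configurations (including the seed) give
  byte-identical outputs; the pipeline fans one master seed out to
  stages by a stable string hash of the stage name, so stages are
  reproducible in isolation and do not share random streams.

What the generator does **not** emulate: single-molecule kinetic
detection (calls are consumed as ground truth, never produced from
reads), sequencing error, real gene architecture (operon structure,
strand biases, overlapping reading frames beyond the planted clusters),
compositional heterogeneity along the genome, phylogenetic correlation
between genomes (each planted genome is independent), or indel
evolution. Passing tests therefore demonstrate that the *computations*
are correct and self-consistent under the planted statistical
structure; they do not validate biological conclusions drawn from real
genomes, where annotation error, missed calls and non-independence all
enter.

# Numerical and interface conventions

* Coordinates are 0-based half-open everywhere internally; GFF3 input
  (1-based inclusive) is converted on read. PT calls are single-base
  coordinates on the plus strand, with minus-strand calls stored at the
  plus-strand C that faces the modified G, enabling the $p / p+3$
  pairing arithmetic.
* Percent rounding follows the printing conventions above (one decimal
  for percent-modified and co-occurrence percents, integer for the
  hemi percentage), so worked-example targets are exact.
* The feature-overlap summary counts a feature if its interval
  intersects any modified locus footprint $[start, start+4)$.
* All thresholds used by a pipeline run are echoed into its JSON
  report; two runs with the same configuration produce byte-identical
  reports.
* The spec-level command-line surface is fulfilled by the exported
  functions plus `run_pipeline()`; the package is primarily an R API,
  and a shell entry point would add argument plumbing without adding
  capability.

# Problem sizes

The test suite runs the worked-example landscapes at full planted motif
counts (94,316 down to 60,776 loci) on 1.2 Mb genomes — the percentages
are count ratios, so genome length only sets runtime — and the
neighbourhood figures at their full 2,322- and 553-genome sizes.
Property suites use 100 seeds for classifier-recovers-generator
identities, 50 random pairs for the alignment enumeration oracle, and
$n = 200$ strains per planted correlation for rank-correlation
recovery within ±0.1. The acceptance script uses 4 Mb genomes and the
published sample sizes (1,132 and 261 strain pairs) throughout.

# Limitations

* The aligner targets protein sequences at desk scale (thousands of
  pairwise alignments of ~10³-residue concatenations); it is not a
  batch aligner for genome-scale all-vs-all work.
* Neighbourhood mining classifies annotation tables; it does not run
  the homology search, assign taxonomy, or infer transfer events —
  statements about horizontal gene transfer require phylogenetic
  reasoning outside this package's scope.
* The NJ tree is an initial-tree proxy; no bootstrap support, no
  likelihood model.
* Reproduction of database-wide published correlations would require
  the original downloaded protein sets; the package instead verifies
  parameter recovery on planted families at the published sample sizes.
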