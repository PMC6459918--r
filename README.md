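# thioscape

Analysis of DNA **phosphorothioate (PT) modification landscapes** and the
gene neighbourhoods of PT-based defence systems in prokaryotic genomes.

In PT modification, a non-bridging oxygen of the DNA backbone phosphate is
replaced by sulphur. In several haloarchaea this happens at the G–A linkage
of the palindromic motif 5′-G<sub>PS</sub>ATC-3′, written by the DndCDEA
modification proteins and read by defence modules: the bacterial
restriction cassette *dndFGH*, or the archaeal exclusion cassette
*pbeABCD*, which blocks viral DNA replication without cleaving it. Because
GATC is its own reverse complement, every occurrence is a **duplex locus**
that can be unmodified, hemi-modified (PT on one strand) or fully modified
(PT on both strands). `thioscape` is aimed at microbial genomicists who
have strand-resolved PT calls (e.g. from SMRT sequencing) and protein
homology tables and want the downstream comparative analyses as tested,
reproducible code.

The package covers five analyses end to end:

1. **PT landscape** — scan a genome for GATC duplex loci, pair
   strand-resolved calls onto loci by integer arithmetic (a `+` call at
   *p* and a `−` call at *p* + 3 describe one duplex), and summarise:
   percent of motifs modified, full/hemi partition, strand call counts,
   spacing, feature overlap and flanking-base context bias.
2. **Neighbourhood mining** — filter homology hits
   (e-value ≤ 10⁻¹⁰ and aligned length ≥ 30 % of the query), pair *dndC*
   with its nearest *dndD* (gap ≤ 5 kb), then classify each locus by its
   window co-occupants: *dndFGH* (all three genes) within 20 kb of a
   *dndCD* locus, or *dndCD*/MTase within 10 kb of a *pbeAC* locus.
3. **Coevolution** — needle-style affine-gap global alignment
   (BLOSUM62, gap open 10, extend 0.5, free end gaps); per-strain
   similarity rates of concatenated gene pairs against fixed references;
   Spearman ρ, Pearson r and the least-squares regression of partner on
   modification similarity, returned as a classed model object with
   `print`/`coef`/`predict`/`plot`/`residuals` methods.
4. **Distance trees** — all-vs-all alignment distances
   (d = 1 − identity/100) and neighbour-joining trees with Newick output.
5. **Assay scalars** — efficiency of plating (titre ratio), the
   2^(CT(radA) − CT(repA)) relative viral load, and unadsorbed-virus
   percentages.

A seeded synthetic-data generator (`sim_config()` and the `gen_*()`
functions) produces genomes with an exact number of planted GATC motifs,
PT call sets of chosen composition, annotation tables with defence-gene
clusters planted at controlled gaps, and protein-family pairs with a
tunable rank correlation of divergence — so every stage is testable with
no downloads, and every generated fixture carries machine-readable ground
truth.

## Worked example

```r
library(thioscape)

cfg <- sim_config(seed = 42, genome_len = 2e5, n_motifs = 2000L,
                  n_full = 131L, n_hemi_plus = 57L, n_hemi_minus = 57L)
g     <- gen_genome_with_motifs(cfg)
calls <- gen_pt_calls(g$positions, cfg, names(g$genome))
loci  <- classify_duplex_states(scan_gatc_loci(g$genome), calls)
summarize_pt(loci, g$genome)
#> PT landscape summary
#>   GATC duplex loci:      2000
#>   modified loci:         245 (12.2%)
#>   full / hemi:           131 / 114 (hemi 47%)
#>   strand calls (+/-):    188 / 188
#>   calls per 10 kb (ds):  9.400
#>   per-strand spacing:    19 - 7199 bp
```

The summary says: of 2,000 GATC duplex loci, 245 carry at least one PT
call (12.2 %); 131 are fully modified and 114 hemi-modified (47 % of
modified loci are hemi — exactly the planted composition); each strand
carries 188 calls (131 full + 57 hemi), i.e. 9.4 strand-level calls per
10 kb of double-stranded sequence.

```r
ref_mod <- gen_protein(350, 1); ref_res <- gen_protein(300, 2)
fam <- gen_protein_family_pairs(ref_mod, ref_res,
         sim_config(seed = 7, divergence_corr = 0.6, n_strains = 50L))
fit <- coevolution_fit(similarity_rates(fam, ref_mod, ref_res))
fit
#> Coevolution fit of paired similarity rates
#>   strains: 50
#>   Spearman rho: 0.557
#>   Pearson r:    0.558
#>   regression:   res = 28.905 + 0.609 * mod
```

Fifty strains were planted with a rank correlation of 0.6 between the
substitution fractions of the two protein families; after mutating the
sequences, aligning them back to the references and correlating the
similarity rates, the fit recovers ρ ≈ 0.56.

`run_pipeline(pipeline_config(seed = 1))` chains all stages
(simulate → ptmap → mine → coevolve → tree → assay) and writes a
versioned JSON report in which every threshold used is echoed; identical
configurations give byte-identical reports.

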