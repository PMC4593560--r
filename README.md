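# multifunr

Genome-wide detection of multifunctional genes from ontology
annotations, with the comparison statistics and network measures used
to characterize them.

Many genes participate in more than one biological process, yet
annotation hierarchies make "has two annotations" a poor proxy for
"has two functions": a gene annotated to two closely related terms is
not multifunctional in any interesting sense. `multifunr` implements
a detection method that calls a gene multifunctional only when it is
co-annotated by two terms that are of **comparable specificity** and
**demonstrably distinct**, and provides the statistical toolkit to
compare the resulting gene classes (protein features, expression
breadth, conservation, essentiality, disease involvement, network
centrality) while controlling for study and degree biases.

The package is aimed at computational biologists working with Gene
Ontology style annotation corpora (GAF files), protein interaction
networks and cross-species orthology maps.

## The method

For a specificity level *N*, the term set *T<sub>N</sub>* contains
every term that annotates at least *N* but fewer than 2*N* genes
(true-path propagated counts) and whose every descendant term
annotates fewer than *N* genes. From all pairs
(*t*₁, *t*₂) ∈ *T<sub>N</sub>* × *T<sub>N</sub>*, a pair survives when

1. *t*₁ and *t*₂ share no common ancestor other than the ontology
   root (their least common ancestor is the root),
2. they share no common descendant term, and
3. their propagated gene sets do not overlap significantly
   (upper-tail hypergeometric test; pairs with *p* < 0.1 are removed).

A gene co-annotated by both members of a surviving pair is called
multifunctional at level *N*; the final call set is the union over
*N* ∈ {10, 20, …, *M*} with *M* = 120 by default. The comparison
background is every gene annotated by at least one selected term at
any level.

Supporting analyses include Mann–Whitney group comparisons (exact or
tie-corrected normal approximation), hypergeometric enrichment,
partial Spearman correlations, covariate-matched resampling nulls,
bootstrap median intervals, network centralities (degree, Brandes
betweenness, participation coefficient *P* = 1 − Σ᷈ᵢ(kᵢ/k)² with
iterative pruning of >200-degree hubs), and a label-permutation test
for the cross-species conservation of multifunctionality.

## Worked example

Every generator is seeded, so this is exactly reproducible:

```r
library(multifunr)

graph <- gen_ontology(n_branches = 16, depth = 1, fanout = 1, seed = 1)
sim   <- gen_annotations(graph, seed = 1)   # 25 planted calls + decoy pair
idx   <- build_index(sim$records, graph)
fit   <- detect_multifunctional(idx, graph) # N = 10..120, alpha = 0.1
fit
#> Multifunctional gene detection (N grid 10..120 step 10, alpha = 0.1)
#>   multifunctional: 25 genes
#>   background (annotated by a selected term): 220 genes
#>   evidence pairs: 25

setequal(fit$multifunctional, sim$truth$planted_multifunctional)
#> [1] TRUE
head(fit$evidence, 3)
#>     gene  N       term1       term2 overlap         p
#> 1 MF0001 10 SYN:0000008 SYN:0000013       1 0.7143853
#> 2 MF0002 10 SYN:0000005 SYN:0000008       1 0.7143853
#> 3 MF0003 10 SYN:0000002 SYN:0000003       1 0.7143853
```

The 25 planted multifunctional genes are recovered exactly; each
call's evidence row names the specificity level and the term pair
that witnessed it, with the pair's co-annotation overlap and
hypergeometric *p*. The decoy term pair — planted with an enriched
shared gene block — is removed by the co-annotation filter, so its
genes stay in the background:

```r
any(sim$truth$decoy_genes %in% fit$multifunctional)
#> [1] FALSE
```

A shell entry point wraps the same pipeline
(`Rscript inst/cli/multifun.R detect --obo ... --annotations ...
--out prefix`, plus `net-stats`, `compare`, `ortho-test` and
`simulate` subcommands; after installation the script lives at
`system.file("cli", "multifun.R", package = "multifunr")`).

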