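---
title: "Detecting multifunctional genes: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting multifunctional genes: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multifunr)
```

## The problem

Annotation corpora such as the Gene Ontology organize biological
knowledge as a rooted directed acyclic graph of terms, with genes
annotated to terms and, by the true-path rule, implicitly to every
ancestor of those terms. Counting a gene as "multifunctional" because
it carries two annotations is meaningless in such a hierarchy: the
two terms may be parent and child, siblings describing one process at
two granularities, or so correlated in their gene memberships that
they are effectively one functional signal. `multifunr` implements a
detection procedure that only accepts term pairs that are comparable
in specificity and distinct in three independent senses, and the
statistical machinery needed to characterize the resulting gene
class.

## The detection model

**Specificity levels.** For an integer $N$, the level set $T_N$
contains every term $t$ with propagated annotation count
$N \le c(t) < 2N$ whose every descendant $d$ satisfies $c(d) < N$
(terms without descendants qualify vacuously). The descendant
condition is what makes the selection meaningful: a very general term
can sit directly above many small terms, so a lower bound on its own
count alone would misclassify it as specific. The upper bound $2N$
removes terms that are far more general than the level's nominal
scale. The root receives no special treatment; it is selected iff it
satisfies the bounds, and it can never contribute a call because no
term is structurally disjoint from its own root.

**Distinct pairs.** Within one level (never across levels — pairing
across levels would compare terms of different granularity), an
unordered pair $(t_1, t_2)$ survives three filters:

1. *root-only common ancestry*: the set of common ancestors, minus
   the root, is empty. Under a DAG this is equivalent to "the least
   common ancestor is the root" and is well defined even when
   multiple common ancestors exist. Pairs where one term is an
   ancestor of the other are excluded by the same logic.
2. *no common descendant*: a shared descendant indicates an
   annotated biological situation where both functions co-occur, and
   hence non-distinctness.
3. *no co-annotation enrichment*: with $a = |g(t_1)|$,
   $b = |g(t_2)|$, overlap $k$ and universe $G$ (all genes annotated
   in the namespace), the upper tail $P[X \ge k]$ of a
   hypergeometric$(G, a, b)$ must be $\ge \alpha$. Per-pair raw
   p-values are used deliberately — the filter is a screen against
   redundant term pairs, not an inference, so no multiple-testing
   correction applies.

**Calls and background.** A gene co-annotated (propagated
membership) by both members of a surviving pair at any level
$N \in \{n_{\min}, n_{\min}+\Delta, \dots, M\}$ is multifunctional.
The background is every gene annotated by at least one selected term
at any level; group comparisons are run between the called genes and
the background minus the calls. Each call retains its full evidence
list $(N, t_1, t_2, k, p)$ so that every call can be re-audited
against the three filters.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `n_min`, `increment`, `M` | 10, 10, 120 | specificity grid; $M$ bounds how general a term may be and is the main sensitivity knob — calls grow monotonically with $M$ |
| `alpha` | 0.1 | co-annotation screen; *raising* `alpha` removes more pairs and can only shrink the call set |
| `relations` | `is_a`, `part_of` | ontology relations traversed for propagation, the convention of mainstream GO tooling |
| evidence whitelist | 14 codes | broad curated set (EXP, IDA, IMP, IGI, IEP, ISS, ISO, ISA, ISM, IGC, IBA, IC, TAS, NAS); `evidence_strict()` gives the 6-code experimental subset for sensitivity analysis |
| `max_degree` (networks) | 200 | iterative hub pruning cap; the single highest-degree node above the cap is removed per iteration, degrees recomputed |

Annotation counts are propagated by default. Direct-only counting
(`propagate = FALSE`) is retained for sensitivity analysis, but note
that it can make a parent count smaller than a child's, which
contradicts the monotonicity the level definition relies on.
Obsolete terms stay in the parsed ontology for diagnostics but carry
no traversal edges; annotations to them are discarded with a
warning. Gene identity is the annotation file's database object id
(GAF column 2).

## Statistics

* **Mann–Whitney**: exact when $n_1 n_2 \le 400$ (exact U
  distribution without ties; full labeling enumeration with ties when
  the enumeration is small), otherwise normal approximation with tie
  and continuity correction. Two-sided throughout; direction is
  reported separately rather than folded into one-sided p-values.
* **Empirical p-values** from randomization are $(r+1)/(n+1)$, so
  1000 trials with zero exceedances report $p < 10^{-3}$, never 0.
* **Matched resampling** draws candidate samples bin-matched to the
  target covariate distribution: exact-value bins when the covariate
  takes few integer values (isoform counts), otherwise deciles of the
  *target* distribution. A target-occupied bin without candidates is
  a hard error, not a silent skip.
* **Orthology permutation test**: labels are reshuffled within each
  organism over ortholog-involved genes only, once per trial per
  gene, preserving label counts and the orthology mapping. For
  one-to-one maps the null expectation is
  $|pairs| \cdot f_A \cdot f_B$, which the test suite verifies by
  simulation.
* **Participation coefficient** $P = 1 - \sum_i (k_i/k)^2$; isolated
  nodes get $P = 0$ rather than NaN so rank statistics stay total.
  Betweenness is unnormalized — every downstream use is a rank
  comparison, for which normalization is irrelevant.
* Cluster assignments are pluggable (any node→cluster table); the
  built-in deterministic greedy modularity baseline is plumbing, not
  a contribution.

## What the synthetic generators emulate

The generators create the full input universe with known ground
truth: a single-rooted ontology of disjoint branches (optionally with
within-branch DAG diamonds), annotation sets with true-path
structure, planted cross-branch multifunctional genes, an optional
co-annotation-enriched decoy pair, clustered networks (stochastic
block model), one-to-one orthologies with a planted excess of
multifunctional–multifunctional pairs, and feature tables with known
group shifts.

Default study conditions (chosen once, at a scale a reviewer can
re-run in seconds): 16 branches, 220 genes, 25 planted
multifunctional genes, leaf annotation counts equalized into the
lowest specificity window $[10, 20)$, decoy overlap inflated to
about 6× its chance expectation. The decoy factor deserves a note:
the decoy exists to exercise the hypergeometric screen, and at this
scale the chance-expected overlap of two 15-gene terms is about one
gene, so a mild (2×) inflation would not reach $p < 0.1$; 6× places
the decoy's p-value around $10^{-5}$, unambiguously inside the
filter's rejection region, without distorting the rest of the
fixture.

What the fixtures deliberately do **not** mimic: the real GO's
scale-free topology, annotation depth heterogeneity, evidence-code
mixtures, inter-ontology links, or correlated annotation noise.
Passing the planted-recovery tests therefore demonstrates
correctness of the algorithmic definitions, not field performance on
a real GO release — on real corpora the interesting behavior
(which N windows fire, how many pairs survive) is data-dependent and
should be inspected via the per-level summary (`summary(fit)`).

## Numerical and degenerate-input choices

* Hypergeometric tails come from `phyper(k - 1, ..., lower.tail =
  FALSE)`; the test suite pins them to explicit enumeration of all
  draws for universes up to 12 at $10^{-12}$ tolerance.
* Hub pruning breaks degree ties lexicographically by node id, so
  runs are reproducible regardless of input order.
* All outputs are ordered lexicographically (genes, then level, then
  term pair) and all stochastic procedures take explicit integer
  seeds; reruns are byte-identical.
* Degenerate inputs fail loudly: empty annotation sets, specificity
  grids selecting no terms (with a count-distribution diagnostic),
  constant vectors passed to rank correlations, and covariate bins
  without candidates are all hard errors.

## Open design points resolved here

* *Graded semantic similarity*: only the root-only-LCA criterion is
  implemented; a graded threshold would require an information
  content model that the detection definitions do not depend on.
* *Direct vs propagated membership for calls*: calls use propagated
  membership, consistent with the counting substrate; requiring
  direct annotation to both paired terms would make calls depend on
  curation granularity rather than biology.
* *Distinct-disease calls*: for disease ontologies the
  shared-descendant clause is relaxed by default (two diseases in
  separate branches count as distinct even if a specific syndrome
  falls under both); `full_criterion = TRUE` restores the strict
  rule.
* *Isoform weighting in conservation scores*: per-isoform means are
  averaged with equal weights (the definition fixes the order of
  averaging); length-weighted averaging would change the statistic
  and is intentionally not offered as a default.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated
fixtures: ontologies of ≤ 60 terms, annotation sets of ≤ 300 genes,
networks of ≤ 300 nodes, 50-fixture oracle-equivalence sweeps, 200
replicate calibration runs at 99 randomization trials each, and
1000-trial permutation tests. These sizes were chosen so the whole
validation cycle stays interactive while keeping every statistical
check adequately powered.

## Known limitations

* The OBO parser covers the flat-file subset relevant here (Term
  stanzas, `is_a`, `relationship`, `is_obsolete`, `replaced_by`); it
  is not an OWL processor.
* Level sets use a fixed arithmetic grid; a data-driven grid could
  be sharper but would compromise comparability across corpora.
* The co-annotation screen tests marginal pair overlap only; it
  cannot detect three-way redundancy among terms.
* Betweenness and participation are computed on the simple
  undirected graph; weighted or directed variants are out of scope.
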