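---
title: "Differential regulatory network analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential regulatory network analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffgrn)
```

# The problem

Bulk expression differences between two conditions (here: male and female
mid-gestational brain) are often subtle at the single-gene level, especially
on autosomes. `diffgrn` looks instead for differences in *regulation*: it
infers a bipartite transcription-factor (TF) to gene regulatory network per
condition, detects community structure in each, and asks where the two
networks' modular organization differs — and which TFs and genes drive that
difference. A co-expression branch (modules plus GSEA-style activity scoring)
provides a complementary, regulation-agnostic view of which gene programs are
more active in which condition.

# Models and procedures

## Preprocessing

Four fixed-order steps: (1) remove genes with sample variance strictly below
0.1 — the conventional cut for variance-stabilized RNA-seq ahead of
correlation-network work (a gene exactly at the threshold is kept, because
the rule is "smaller than"); (2) remove genes annotated to chromosomes X or Y
so autosomal signal dominates, with `"chrX"`-style labels normalized before
matching; (3) flag outlier samples by average-linkage hierarchical clustering
of Euclidean distances — a sample is an outlier when its first merge height
exceeds the mean merge height by `cut_sd` (default 3) standard deviations.
The underlying study only reports that clustering revealed one outlier, not
the rule used; the merge-height z-cut is this package's own deterministic,
testable formalization of "joins the tree anomalously late"; (4) remove
additive batch effects per gene by least squares with the sex effect
protected in the design (`limma::removeBatchEffect` with `~ sex`). Protecting
the phenotype of interest is the conservative choice when the original design
matrix is unknown.

## Co-expression modules and activity

The similarity is unsigned Pearson correlation `|r|`, raised to a
soft-threshold power `beta` chosen as the smallest power whose weighted
degree distribution fits a scale-free form with R² ≥ 0.8 (signed fit:
increasing fits never qualify; degenerate degree distributions with fewer
than three informative bins score 1, so block-constant similarities resolve
to the smallest candidate power). Modules come from average-linkage
clustering of the topological-overlap dissimilarity `1 - TOM` with a fixed
absolute cut at 0.99: gene pairs that only co-cluster above 0.99
dissimilarity are not co-expressed in any useful sense, so unstructured genes
stay unassigned rather than pooling into a noise module. Clusters below
`min_size` (30 at cohort scale, 10 at the desk scale used in the tests) are
unassigned; modules are renumbered by size. Genes are processed in
lexicographic id order, making the partition independent of input order.

Module activity per sex: each gene is z-scored across *all* samples, each
class is summarized by its mean z per gene, and each module is scored in each
class ranking with a weighted Kolmogorov–Smirnov enrichment statistic
(weight exponent 1). The null is gene-label permutation — random same-size
gene sets — which is feasible at any class size; `NES = ES / mean(|ES*|)`
over same-sign permutation scores, with a +1 pseudocount in the empirical p.
A module is "sex-different" when `|NES| > 2` in at least one class (the
source study states only the absolute-NES cut, not a two-class rule; one
exceeding class is the permissive reading), and its direction is the class
with the largest signed NES.

## Regulatory network inference

Condition-specific networks are inferred by message passing that integrates
three evidence layers: a motif prior `W0` (TF × gene), a TF–TF PPI matrix
`P`, and gene co-expression `C` (Pearson correlation of that condition's
samples). All three are first z-normalized: each entry becomes
`(z_row + z_col)/sqrt(2)`, degenerate rows or columns falling back to the
overall z with `1/sqrt(2)` scaling. Each iteration computes a responsibility
`R = T(P, W)` and availability `A = T(W, C)` with the continuous Tanimoto
similarity `T(x, y) = <x,y> / sqrt(||x||² + ||y||² - |<x,y>|)`, then updates
`W <- (1 - alpha) W + alpha (R + A)/2` with `alpha = 0.1`. `P` and `C` move
toward the co-regulation (`T(W, Wᵗ)`) and co-targeting (`T(Wᵗ, W)`)
similarities of the current `W`; the diagonal of each similarity update is
replaced by the off-diagonal row SD scaled by the matrix dimension and
`exp(2·alpha·step)`. This growing self-similarity enters later Tanimoto
denominators and is what keeps the message-passing gain bounded — without it
the iteration diverges geometrically. Iteration stops when the mean absolute
change of `W` falls below `tol = 1e-3`. The procedure is deterministic; the
two sexes' networks differ only through the expression subset.

Only canonical TF→gene edges are used: motif edges whose target is itself a
TF of the motif set are dropped, along with edges to genes absent from the
expression matrix. "Canonical" is not defined in the source study; excluding
TF-as-target edges keeps the network strictly bipartite, which the community
stage requires.

## Bipartite communities and differential modularity

Positive edge weights are evidence for an interaction, so each network is
projected onto its strictly positive entries (weighted, not binarized —
binarization would discard the strength information the weights carry).
Communities maximize Barber bipartite modularity
`Q = (1/m) Σ_ij [w_ij - k_i d_j / m] δ(c_i, c_j)`
via a deterministic engine: gene labels seeded by label propagation on the
gene–gene co-targeting projection, then alternating TF/gene assignment
(BRIM-style), sequential single-node best moves (with a spare empty label so
communities can split), and greedy community merges. All tie-breaks go to the
smallest label index, so results are reproducible without seeds, and the
returned partition never scores below the all-in-one partition. On small
graphs the engine attains the exhaustive-search optimum (verified in the
tests over a suite of graphs up to 9 nodes).

The two networks are compared by differential modularity
`D = Σ_{c_i = c_j} [w_ij^pert / m_pert - k_i^base d_j^base / m_base²]`
— observed within-module weight in the "perturbed" network minus the
"baseline" network's configuration-model expectation. With identical networks
this is exactly Barber's Q, which anchors the implementation. The same move
engine maximizes D starting from the baseline's own partition, so the result
never scores below its initialization. Because the comparison is asymmetric,
both directions are always run: female baseline yields male-biased modules
and vice versa.

Per-node scores are each node's within-module differential contribution,
floored at `eps = 1e-12` before the natural-log transform (the log must
exist; floored nodes carry no real contribution and are never selectable as
drivers). The log is natural — `ln`, not `log10` — which the published
(score, logScore) pairs pin down to 10 decimal places. Driver selection:
a node is a driver when its log score exceeds its own module's median
(within node type) by more than `k · IQR`, with `k = 1.5` for TFs and `3`
for genes. The IQR is computed per node type over the whole network by
default: the source text computes medians per module but IQRs "for TFs and
genes separately", and the global reading reconciles both clauses (a
per-module IQR is available behind `iqr_scope = "module"`). The deviation is
one-sided upward, since drivers are highest-contribution nodes. Modules with
fewer than three nodes of a type are not tested for that type.

## Enrichment

Over-representation uses the upper-tail hypergeometric test with BH
adjustment across all tested (module, set) pairs of a collection; defaults
follow the conventions for each module family (minimum set size 10 and
adjusted p < 0.0005 for co-expression modules; more than 5 genes and
adjusted p < 0.05 for differential modules). The permutation test draws
`n_perm = 10000` random same-size gene sets from the background without
replacement; the empirical p carries a +1 pseudocount so it is never zero,
and fold enrichment divides the observed overlap by the analytic expectation
`n_module · n_set / n_background` (the permutation mean agrees with it in
expectation, but the analytic form is deterministic). BH adjustment is per
collection; a global family across collections is not used because the
collections answer separate questions.

# The synthetic-data generator

Real data for this design — a 120-sample fetal-brain cohort with external
motif, PPI and gene-set resources — cannot ship with a package, so every
claim is validated on synthetic data with planted ground truth. The
generator emulates, at desk scale (40 TFs, 600 genes, 40 + 30 samples by
default): two unbalanced sample classes, batch structure, a variance
spectrum including a sub-0.1-variance fraction (default 0.25, drawn from the
unstructured background genes), planted correlated gene blocks, a sparse
bipartite motif prior with TF–gene communities, PPI homophily, and
sex-specific rewiring of one community's edges.

Expression is Gaussian on a log-like scale — the package sits downstream of
count normalization and variance-stabilization, which are the data
provider's responsibility. Each TF's activity is
`sqrt(coh) · community factor + sqrt(1 - coh) · own factor` with
`tf_coherence = 0.35`, and each gene averages the activities of its
regulators *in the sample's sex-specific truth network*, mixed with noise to
hit the within-module correlation target (default 0.75). The coherence value
matters: with fully shared community factors, co-expression cannot tell
which TF in a community regulates which gene, so an edge swap that preserves
every TF's degree leaves nothing for differential-modularity scoring to
detect — the planted drivers would be statistically identical to their
peers. Giving each TF a mostly individual factor is the minimal mechanism
under which rewiring genuinely reshapes the correlation structure.

Rewiring swaps `rewired_fraction` (default 0.5) of the rewired community's
within-community edges to targets in one destination community, in the
rewired sex's truth network only. Three deliberate design choices make the
planted signal coherent rather than diffuse:

* **Concentrated retargeting.** The r-th swapped edge of each rewired TF
  goes to the r-th destination gene, so each receiving gene gains one edge
  from (almost) every rewired TF — a coordinated dual-regulation program.
  Scattering the same edges thinly across all destination genes buries the
  signal below the co-expression noise floor.
* **The prior is a sex-agnostic superset.** Motif maps are sequence-based;
  binding sites used by one sex still exist in the other's DNA. The
  swapped-in edges therefore appear in the shared motif prior, and the two
  inferred networks differ only through expression support — which is
  exactly the contract of the inference stage.
* **Community architecture.** The rewired community is TF-poor and gene-rich
  (5 TFs × 120 genes) next to a 5-TF destination community and two 15-TF
  intact communities. The differential module that captures the rewiring
  then contains the planted drivers as a minority tail among other TFs —
  the regime in which a per-module-median + IQR rule is meaningful. (In the
  published tables, the selected TFs are likewise a small tail of much
  larger modules.) If every TF of a module were a planted driver, no
  median-based rule could select more than half of them, by construction.

What the generator does *not* emulate: count-level noise, gene length or GC
effects, gestational-age trajectories, correlated batch-by-sex structure,
TF–TF regulation, and the scale of real cohorts (hundreds of TFs, tens of
thousands of genes). Passing tests therefore demonstrate that the pipeline's
logic recovers planted structure of the assumed form at desk scale — not
that real fetal-brain results are reproduced. Published cohort-scale numbers
(module counts, NES values, driver counts, fold enrichments) depend on the
external dataset and database versions and are out of reach by design; the
exact checks that *are* portable — the published score-to-logScore
arithmetic of the driver tables — are asserted to 1e-10.

# Numerical choices and problem sizes

* TSVs are written with 15 significant digits; round-trips are tested at 12.
* Soft-threshold fallback: below 50 genes the degree distribution is too
  short for a meaningful scale-free fit and `beta` is fixed at 6, the
  conventional default for unsigned networks.
* `run_pipeline()` defaults to `beta = 6` rather than automatic selection.
  Scale-free targeting presumes a hub-like degree spectrum; the generator's
  planted blocks have near-uniform within-module degrees, for which the
  R² ≥ 0.8 rule drifts to extreme powers that push the topological overlap
  below the module cut. Automatic selection (`beta = NULL`) remains
  available and is exercised on hub-structured fixtures in the tests.
* The module-activity permutation null uses 1000 permutations in tests
  (10000 for final analyses); the MSET calibration checks run at 10000
  permutations against the exact hypergeometric answer, and the null
  uniformity check uses a 4000-gene background with 500-gene modules so the
  overlap distribution is fine-grained enough for a Kolmogorov–Smirnov
  comparison against the uniform to be informative.
* Planted-recovery runs use the default desk-scale configuration
  (40 TFs, 600 genes, 70 samples); at this size a full per-sex inference +
  communities + differential-modularity cycle takes seconds on one CPU, and
  the ten-seed recovery study stays within a few minutes.
* Optimizer tie-breaks are smallest-label; the optimizer is deterministic,
  so pipeline reruns with the same master seed are byte-identical.

# Known limitations

* The move engine is a local optimizer: global optimality is guaranteed only
  at the exhaustively tested sizes; at scale it inherits the usual
  modularity-maximization caveats (resolution limit, near-degenerate
  optima).
* Differential modularity rewards any module denser in the perturbed network
  than the baseline expectation, including structure shared by both sexes;
  driver scores are therefore only meaningful *relative to their module*,
  which is exactly what the IQR rule encodes.
* The GSEA activity flag treats classes marginally; a contrast-based rule
  (e.g. on the NES difference) would be stricter but is not what the source
  methodology states.
* With unweighted `iqr_scope = "global"`, heterogeneous module sizes can
  inflate the IQR and make selection conservative; the per-module variant is
  provided for sensitivity analyses.
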