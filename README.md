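# diffgrn

Differential gene regulatory network analysis of two-condition bulk
expression data, built for the question: *where does gene regulation — not
just gene expression — differ between conditions such as male and female
developing brain?*

Single-gene expression differences between sexes are concentrated on the sex
chromosomes and are small on autosomes, yet regulatory wiring can differ even
when expression levels do not. `diffgrn` implements the full analysis chain
for detecting such differences:

1. **Preprocessing** — low-variance gene filter (variance < 0.1, strict),
   sex-chromosome gene removal, hierarchical-clustering outlier detection,
   additive batch adjustment that protects the sex effect.
2. **Co-expression modules and activity** — soft-thresholded `|r|^β`
   networks, topological-overlap clustering into modules CM1…CMk, and a
   GSEA-style activity score per module and sex: genes are z-scored across
   all samples, ranked by mean class z, and each module's weighted
   Kolmogorov–Smirnov enrichment score is normalized against a gene-label
   permutation null (`NES`); a module with `|NES| > 2` is sex-different.
3. **Regulatory network inference** — per-sex bipartite TF→gene networks by
   message passing over a motif prior `W`, TF–TF PPI `P` and co-expression
   `C`, with the continuous Tanimoto similarity
   `T(x,y) = ⟨x,y⟩ / √(‖x‖² + ‖y‖² − |⟨x,y⟩|)` and update
   `W ← (1−α)W + α(T(P,W) + T(W,C))/2`.
4. **Bipartite communities** — Barber modularity
   `Q = (1/m) Σᵢⱼ [wᵢⱼ − kᵢdⱼ/m] δ(cᵢ,cⱼ)` maximized over positive-edge
   projections by a deterministic BRIM-style engine (exhaustive and provably
   optimal on small graphs).
5. **Differential modularity** — the two networks are compared by
   `D = Σ_{cᵢ=cⱼ} [wᵢⱼᵖᵉʳᵗ/mᵖᵉʳᵗ − kᵢᵇᵃˢᵉdⱼᵇᵃˢᵉ/(mᵇᵃˢᵉ)²]`,
   maximized to find differential modules M1…Mk; both baseline directions are
   always run (female baseline ⇒ male-biased modules, and vice versa).
   Driver TFs/genes are nodes whose natural-log score exceeds their module's
   median by more than 1.5×IQR (TFs) or 3×IQR (genes), with IQRs computed
   per node type.
6. **Enrichment** — hypergeometric over-representation and a permutation
   test (random same-size draws from the background, 10,000 permutations,
   +1-pseudocount empirical p, fold enrichment = observed/expected overlap),
   both BH-adjusted per collection.

A first-class synthetic-data generator (`simulate_study()`) plants all of the
structure the pipeline assumes — correlated gene blocks, sex-shifted module
activity, batch effects, low-variance genes, a community-structured motif
prior with PPI homophily, and sex-specific rewiring of one community — and
returns the ground truth needed to score every stage.

## Worked example

```r
library(diffgrn)

cfg <- sim_config(seed = 42)     # 40 TFs, 600 genes, 40 male + 30 female
sim <- simulate_study(cfg)
sim
#> diffgrn_sim: 600 genes x 70 samples; 40 TFs; motif 3173 edges; ppi 137 edges
#>   rewired community 1 -> 2 (male truth), 5 planted driver TFs

run <- run_pipeline(sim$expression, sim$motif, sim$ppi,
                    seed = 42, min_module_size = 10, n_perm_activity = 500)
run
#> diffgrn_run
#>   preprocess: 600 -> 450 genes, 70 -> 69 samples
#>   coexpression: 5 modules (beta 6)
#>   differential: 4 male-biased / 4 female-biased modules, 3 shared top TFs

dr <- run$drivers$male_biased
head(dr[dr$type == "TF", c("node", "score", "module", "log_score", "selected")], 8)
#>    node  score module log_score selected
#> 1 TF005 0.0308     M1     -3.48     TRUE
#> 2 TF003 0.0306     M1     -3.49     TRUE
#> 3 TF001 0.0303     M1     -3.50     TRUE
#> 4 TF002 0.0302     M1     -3.50     TRUE
#> 5 TF004 0.0300     M1     -3.51     TRUE
#> 6 TF020 0.0156     M2     -4.16    FALSE
#> 7 TF029 0.0154     M3     -4.17    FALSE
#> 8 TF022 0.0152     M2     -4.19    FALSE

sim$truth$driver_tfs
#> [1] "TF001" "TF002" "TF003" "TF004" "TF005"
```

What the numbers mean: 150 planted sub-0.1-variance genes were filtered and
one sample was dropped as a clustering outlier; five co-expression modules
were detected; the female-baseline comparison found four male-biased
differential modules, and driver extraction selected exactly the five TFs
whose targets were rewired in the male truth network — each with a raw
differential-modularity score about twice that of the next TF (log scores
−3.5 vs −4.2). Module CM1 (the planted sex-active block) is flagged as more
active in females by the GSEA activity scores.

`run_pipeline(..., outdir = "run1")` additionally writes every stage's
tables (TSV) plus a JSON run summary; reruns with the same seed are
byte-identical.

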