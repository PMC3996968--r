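# msidbn

Critical-protein identification in dynamic protein–protein interaction
(PPI) networks.

Static PPI catalogs aggregate interactions over every condition ever
assayed.  Along a periodic process such as the yeast cell cycle, however,
a small set of proteins rewires its local neighborhood at specific
phases.  `msidbn` finds candidates for these structure-changing
("critical") proteins from two inputs — a gene-expression time course
with replicate cycles and a static interactome edge list — in three
stages:

1. **Dynamic network construction.**  A protein is *active* at timepoint
   t when its replicate-mean expression meets its gene-specific threshold
   `AcScore(p) = μ(p) + α·σ(p)³/(1+σ(p)²)` (default α = 1.5).  The
   timepoint network is `A_t = CoE_t ∘ δ_t δ_tᵀ ∘ Ppi` — the static
   adjacency masked by joint activity and weighted by windowed Pearson
   co-expression mapped to [0,1] — and its second matrix power (diagonal
   zeroed, max-rescaled) is taken as each timepoint's soft neighborhood
   profile.
2. **Shared representation (msiDBN).**  One two-layer restricted
   Boltzmann machine stack per timepoint, trained greedily by
   contrastive divergence on the matrix rows, joined by a single shared
   top RBM over the concatenated second-layer activations.  Mean-field
   encode/decode through the shared code reconstructs every timepoint
   network from the structure common to all of them.
3. **Ranking.**  Per protein and timepoint, the row reconstruction RMSE
   `Er_i(t)`; per protein, the relative standard deviation `RSD = σ/μ`
   of that error profile.  Proteins whose structure the shared code
   explains unevenly across time rank highest.

The package also provides AVG and joint-NMF reconstruction baselines,
complex-overlap precision metrics (neighborhood-affinity overlap score,
match threshold 0.2), a fully seeded synthetic benchmark generator with
planted critical proteins, exact-enumeration oracles for small RBMs, and
a command-line pipeline (`inst/scripts/msidbn`).

## Worked example

```r
library(msidbn)

ds     <- generate_dataset(synthetic_spec(seed = 42))  # 100 proteins, T = 12
series <- build_series(ds$expr, ds$ppin)
series
#> network_series: 12 timepoints, 100 proteins
head(attr(series, "log"), 3)      # per-timepoint activity, as logged
#>   timepoint active edges
#> 1        t1     27    98
#> 2        t2     21    68
#> 3        t3     23    81

model <- msidbn_train(series, config = train_config(seed = 42))
rec   <- msidbn_reconstruct(model, series)
series_rmse(series, rec)                       # 0.0509
series_rmse(series, avg_baseline(series))      # 0.0788

report <- rank_critical(rmse_profile(series, rec), k = 10)
report
#> criticality_report: 100 proteins x 12 timepoints; top 10
#>   head of ranking: P007 (2.372), P003 (2.286), P080 (2.281), ...
gold_list_precision(report$top_k, ds$critical_ids)$matched  # 2
```

Read: the shared-representation model reconstructs the 12 networks with
overall RMSE 0.051, clearly better than the best time-constant
reconstruction (0.079) — the common structure it extracts is genuinely
time-aware.  Two of the ten planted module-switching proteins appear in
the RSD top-10 (P007, P003); the vignette explains why RSD favors
narrowly active proteins over module switchers on this kind of fixture.

On real data, replace the simulated inputs with
`read_expression()` / `read_edge_list()` (wide TSV or GEO
series-matrix-style layouts; BioGRID-style edge lists), and evaluate
externally produced module detections against a curated complex catalog
with `complex_precision()`.

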