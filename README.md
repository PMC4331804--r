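# apinet

Predicting essential proteins from **active** protein–protein interaction
networks built with dynamic gene expression.

Static PPI networks aggregate interactions from every condition and carry
substantial false-positive noise, which blunts the classic observation that
topologically central proteins tend to be essential. `apinet` implements a
pipeline that scores centrality on the *active* part of the interactome
instead:

1. **Time-dependence test.** Each gene's expression series
   `x = (x_1, …, x_M)` is classified as *time-dependent* (well described by
   an AR(p) model) or *time-independent* (constant + noise) with a
   likelihood-ratio test. For each admissible order
   `1 ≤ p ≤ (M−1)/2`, the statistic
   `F = (M − 2p − 1)/p · (σ̂c²/σ̂² − 1)` is referred to an
   `F(p, M − 2p − 1)` distribution, and the gene is called time-dependent
   when the minimum p-value across orders falls below `alpha`.
2. **Noise filter.** Genes that are time-independent *and* weakly expressed
   (mean below a floor) are discarded.
3. **Active threshold.** Each retained gene gets the variance-damped
   k-sigma threshold `u + kσ(1 − F)` with `F = 1/(1 + σ²)` (default
   `k = 2.5`); a protein is active at a time point when its expression
   strictly exceeds its threshold.
4. **Active network.** A static edge is active at time `t` when both
   endpoint proteins are active at `t`; the union over time points is the
   active network.
5. **Centrality + evaluation.** Six measures — degree (DC), betweenness
   (BC), closeness (CC), subgraph (SC), local average connectivity (LAC)
   and edge-clustering-coefficient centrality (NC) — rank proteins on the
   static and active networks, and rankings are evaluated against a
   reference essential-protein list by top-k counts, jackknife cumulative
   curves with (normalized) AUC, and overlap decomposition.

A synthetic benchmark generator with planted co-active modules and
enrichable essential labels makes every stage testable without any external
database. See the vignette (`vignettes/active-networks.Rmd`) for the full
model description, parameter rationale, and known limitations.

## Worked example

```r
library(apinet)

b <- gen_benchmark(seed = 7)   # 50 proteins, 120 interactions, 36 time points
res <- run_pipeline(b$network, b$expression, b$essential,
                    out_dir = "readme_out", mean_floor = 1)
```

The pipeline logs each stage to standard error:

```
inputs: 50 proteins / 120 interactions; 50 expression profiles (36 time points); 15 essential identifiers
time-dependence: 10 of 50 genes called time-dependent (alpha = 0.01)
noise filter: removed 40 gene(s) below mean floor 1; 10 retained
activity: 20 active flags over 10 genes x 36 time points (k = 2.5)
active network: 8 nodes / 6 edges in the union graph
wrote 9 report files to readme_out
```

The 40 flat low-expression background genes are filtered as noise; the 10
planted module genes are active exactly in their 2-point co-active window
(20 flags), and the union network is exactly the static subgraph on the
module. Because the essential labels were planted with 3× enrichment inside
that module, every measure finds at least as many essentials in the top 10
of the active network (APPIN) as of the static one (PPIN):

```r
cc <- res$comparison$counts
cc[cc$k == 10, ]
#>    measure network  k count
#>         DC    PPIN 10     4
#>         DC   APPIN 10     5
#>         BC    PPIN 10     4
#>         BC   APPIN 10     5
#>         CC    PPIN 10     5
#>         CC   APPIN 10     5
#>         SC    PPIN 10     3
#>         SC   APPIN 10     5
#>        LAC    PPIN 10     2
#>        LAC   APPIN 10     5
#>         NC    PPIN 10     2
#>         NC   APPIN 10     5
```

`count` is the number of true essentials among the top-10 proteins of each
ranking. `res$comparison$auc` holds the jackknife AUCs, and `readme_out/`
contains the per-stage artifacts (dependence calls, activity flags with
thresholds, active edges as `u v t` triples, per-measure score tables, and
the evaluation report as TSV and JSON, plus the resolved configuration).

A thin command-line front end with the same stages
(`simulate`, `filter-genes`, `thresholds`, `build-network`, `centrality`,
`evaluate`, `run`) is installed at `inst/cli/apinet.R`:

```sh
Rscript inst/cli/apinet.R simulate --out sim --seed 7
Rscript inst/cli/apinet.R run --network sim/network.tsv \
    --expression sim/expression.tsv --essential sim/essential.txt \
    --out results --mean-floor 1
```

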