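# samgsr

Pathway-based feature selection for two-class gene expression studies:
the **SAM gene-set reduction** algorithm (SAMGSR) and its
**connectivity-weighted** extension, with permutation-based gene-set
significance, core-subset reduction, cross-validated tuning of the
sparseness threshold, calibrated SVM classification, evaluation metrics,
and a synthetic benchmark harness.

## Who this is for

Analysts building gene signatures from genes × samples log-expression
matrices who want selection guided by pathway membership (MSigDB-style GMT
collections) and, optionally, by protein–protein interaction connectivity
(HPRD-style binary or STRING-style scored edge lists). The weighted variant
is designed to rescue *driving* genes — network hubs whose own expression
change is subtle.

## The method

Per gene, the moderated mean-difference (SAM) statistic

    d_i = (x̄_case(i) − x̄_control(i)) / (s(i) + s0)

with `s(i)` the pooled two-group standard deviation and `s0` a small
damping constant (median of the positive per-gene `s(i)`). A gene set is
scored by `Σ d_i²` over its members and tested by permuting phenotype
labels. Each significant set is reduced to a *core*: genes are ranked by
`|d_i|`, and genes enter the core one by one until the residual subset's
permutation p-value exceeds a threshold `c_k` (tuned by k-fold
cross-validation). The signature is the union of the cores.

The weighted variant computes per-gene connectivity weights from the
symmetric adjacency with unit self-loops,

    w_i = Σ_j a_ij ,  a_ii = 1    (so w_i = 1 + degree for binary networks)

and substitutes `w_i · d_i` for `d_i` throughout — scoring, testing, and
ranking — so highly connected genes need a smaller expression difference to
be retained.

## Worked example

Generate a synthetic benchmark dataset (1000 iid normal genes, 5 gene sets,
60 + 60 samples, two causal genes: the hub HDAC1 with a weak coefficient
and the sparsely connected GNAS with a strong one), then run the weighted
pipeline:

```r
library(samgsr)

dat <- generate_dataset(simulation_config(seed = 3))
w   <- build_weights(dat$edges, dat$gsc$universe)
w
#> ConnectivityWeights: 1000 genes, transform=identity, weight range [1, 32]

sel <- run_selection(dat$train, dat$gsc, weights = w,
                     c_k = 0.05, alpha = 0.05, B = 200, seed = 3)
sel
#> SelectionResult (weighted): 1 significant set(s), 2 core gene(s), c_k=0.05
#>   genes: HDAC1, GNAS
sel$selected_sets
#>    set size     p_value selected
#> 1 SET1  200 0.004975124     TRUE
#> 2 SET2  200 0.134328358    FALSE
#> 3 SET3  200 0.119402985    FALSE
#> 4 SET4  200 0.059701493    FALSE
#> 5 SET5  200 0.288557214    FALSE

clf <- fit_classifier(dat$train, sel$genes, "case", "control", seed = 3)
metrics_report(predict(clf, dat$test))
#> MetricsReport: error 0.083, GBS 0.067, BCM 0.826, AUPR 0.997
```

Only the set containing the causal genes is significant (p ≈ 0.005); its
core is exactly `{HDAC1, GNAS}`, and the resulting 2-gene SVM classifies
the independent test set with 8.3% error. The stage-1 p-values of the four
noise sets illustrate the permutation screen; the weighted ranking is what
places the hub HDAC1 at the top of the core despite its weak coefficient.

Real data come in through `read_expression()` (TSV/CSV + a sample→class
label table), `read_gmt()`, and `read_edge_list()` (binary or scored;
STRING 0–1000 scores are rescaled to (0,1]). `tune_ck()` chooses `c_k` by
stratified cross-validation and reports selection-stability (mean pairwise
Jaccard) at the gene and gene-set level. A thin command-line wrapper with
subcommands `select`, `tune`, `simulate`, `metrics` is installed at
`system.file("scripts", "samgsr", package = "samgsr")`.

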