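---
title: "Pathway-based gene selection with SAMGSR and connectivity weights"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-based gene selection with SAMGSR and connectivity weights}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(samgsr)
```

## The problem

Gene-based feature selection for expression classifiers treats each gene on
its own and ignores two well-established facts: genes act in pathways, and
genes act on each other through physical interactions. Pathway-based
selection uses gene-set membership to guide which genes enter a signature.
This package implements a two-stage pathway-based selector and a weighted
extension of it that additionally uses protein-protein interaction (PPI)
connectivity, aimed at rescuing "driving" genes: hubs whose own expression
change between phenotypes is subtle but which sit at the centre of the
interaction network.

## The statistics

For gene $i$ with case/control sample means $\bar x_d(i), \bar x_c(i)$, the
moderated mean-difference (SAM) statistic is

$$d_i = \frac{\bar x_d(i) - \bar x_c(i)}{s(i) + s_0},$$

where $s(i)$ is the pooled two-group standard deviation of the difference,
$s(i) = \sqrt{(1/n_d + 1/n_c)\,(SS_d + SS_c)/(n_d + n_c - 2)}$, and $s_0$ is
a small positive constant damping genes with near-zero variance. A gene set
$j$ with $|j|$ members is scored by

$$\mathrm{score}_j = \sum_{i=1}^{|j|} d_i^2,$$

and its significance is assessed by permuting the phenotype labels
(preserving class sizes) and recomputing the score. The weighted variant
defines per-gene connectivity weights from the symmetric gene-gene adjacency
$a_{ij}$ with unit self-loops,

$$w_i = \sum_j a_{ij}, \qquad a_{ii} = 1,$$

(so isolated genes get $w_i = 1$, and in the binary case $w_i$ is 1 plus the
gene's degree) and replaces $d_i$ with $w_i d_i$ everywhere: in the set
score, in the permutation test, and in the within-set gene ranking.

Each significant set is then reduced to its *core subset*: genes are ranked
by decreasing $|d_i|$ (or $|w_i d_i|$), and for $k = 1, 2, \dots$ the
permutation p-value of the *residual* subset (everything below rank $k$) is
computed; the first $k$ at which that p-value exceeds a threshold $c_k$
stops the iteration and the core is the top-$k$ genes. The final signature
is the union of the cores of all significant sets. A support-vector machine
with sigmoid probability calibration (or, optionally, logistic regression)
is fitted on the signature; selection itself produces no classifier.

## Parameters that matter

* `alpha` (default 0.05) — stage-1 significance level on the raw permutation
  p-value. No multiplicity correction is applied across sets; stage 1 is a
  screen, not an inference.
* `c_k` (default 0.05; tune with `tune_ck()`) — the reduction stopping
  threshold, the sparseness dial of the method. Larger values make the
  residual harder to "lose significance", so cores grow monotonically with
  `c_k`. It is tuned by stratified k-fold cross-validated misclassification
  (10 folds for two-class problems, 5 for multi-class compositions), ties
  broken toward the smaller (sparser) value.
* `B` (default 1000) — permutations per test. P-values use the add-one
  estimator $(1 + \#\{\text{null} \ge \text{obs}\})/(B+1)$ and are bounded
  below by $1/(B+1)$; choose `B` so that $1/(B+1)$ is comfortably below
  `alpha` and `c_k`.
* `s0` — by default the median of the positive per-gene pooled standard
  deviations, computed once from the observed labelling over the whole gene
  universe and held fixed across permutations. The original SAM
  percentile search is deliberately not implemented: the median is a
  standard simplification, and holding $s_0$ fixed keeps permuted scores on
  the same scale as the observed one. For expression that is iid across
  genes the choice of $s_0$ cancels out of the permutation test entirely.
* `transform` — connectivity weights can optionally be tamed with
  `log2(1+w)` or rank transforms, because raw hub degrees enter the score
  squared and a single large hub can dominate both the observed and the
  null scores. The default is the identity (the literal definition).

## Numerical and procedural choices

* **Tie-breaking.** Gene ranking ties on $|d|$ break lexicographically by
  gene ID; AUPR confidence ties break by sample ID. Both make results
  platform-independent.
* **Permutation streams.** Every permutation test derives its own seed from
  the master seed plus a stream tag (set name, reduction step, replicate,
  fold) via a rolling string hash (`derive_seed()`). Reduction step $k$
  therefore sees the same permutations whatever `c_k` is, which is what
  makes the core monotone in `c_k`, and results are exactly reproducible
  from one integer.
* **Canonical permutation group.** The set score is invariant to
  complementing a label assignment ($d$ flips sign), so permutations draw
  the smaller class; exchanging the case/control roles then reproduces the
  identical p-value, not just a statistically equivalent one. Tied null
  scores are counted as exceedances within a small numerical tolerance so
  that mathematically tied assignments (e.g. the observed one) always
  count.
* **Degenerate inputs.** A singleton set is its own core without a residual
  test. An all-zero variance vector falls back to $s_0 = 10^{-6}$. A CV
  fold whose selection is empty predicts the training majority class with
  the training class frequencies as constant confidences, rather than
  aborting the cross-validation. A confidence of exactly 0.5 classifies to
  the case (first) class.
* **Classifier.** The default is `e1071`'s linear SVM with Platt
  calibration, fitted under a set seed (the calibration's internal
  cross-validation consumes randomness). The contract only requires
  calibrated probabilities monotone in a linear margin, so the logistic
  option is a drop-in substitute.

## What the synthetic generator emulates

`simulation_config()` describes the benchmark design: ~1000 iid standard
normal genes over 60 training and 60 test samples, partitioned into 5 gene
sets of 200, with two causal genes in the first set driving the phenotype
through $u = 0.37\,x_{\mathrm{weak}} - 0.86\,x_{\mathrm{strong}}$ and a
class assigned by thresholding ($u > 0$). Thresholding rather than Bernoulli
sampling is the default because the implied Bayes error of a Bernoulli rule
at $\lVert\beta\rVert \approx 0.94$ (roughly a third) is incompatible with
the test-error levels this design is meant to produce; the Bernoulli rule
remains available as an option. With $\beta = (0,0)$ the threshold ties are
broken by a fair coin, which turns the null design into balanced random
labels.

The interaction network gives the weak-effect gene a target degree of 30
and the strong-effect gene 3. Background target degrees are drawn from a
floored exponential with mean about 0.6, so most genes are isolated within
the analysis universe — this emulates what a curated PPI database looks
like after restriction to a ~1000-gene analysis set, where coverage is
partial and within-set neighbours are rare. Each gene then links to its
target number of uniformly chosen distinct partners, so achieved degrees
can slightly exceed targets. The generator writes the same TSV/GMT/edge
formats the readers accept.

What it does *not* emulate: microarray/RNA-seq noise models, probe-level
artefacts, batch effects, correlated co-expression within pathways, or
realistic gene-set overlap (the generated sets partition the universe; the
overlap of real GO collections can be configured in principle but is not
part of the benchmark design). Passing benchmarks here therefore says the
algorithm behaves as specified under its own generative assumptions, not
that it will attain any particular accuracy on real cohorts.

## Benchmark problem sizes and what they show

The replicated benchmark (`run_replicates()`) runs 50 replicates at
$B = 100$ permutations with a fixed $c_k = 0.05$, the conventional level
and a member of the default tuning grid; fixing it keeps all replicates on
one condition, and per-replicate cross-validated tuning is available via
`c_k = "tune"`. The package's own test suite checks, among others:

* permutation p-values against exhaustive label enumeration, and reduction
  stopping indices against a brute-force all-$k$ oracle;
* that constant weights reproduce the unweighted pipeline exactly,
  end to end, at a fixed seed;
* the evaluation metrics against hand-computed values;
* stage-1 type-I error under the null design, within binomial tolerance of
  the nominal level, and chance-level test error there;
* that the weighted variant recovers the weak-effect hub gene at least as
  often as the unweighted one on paired replicates — the design's central
  qualitative claim.

A known quantitative limitation, visible in the benchmark and deliberately
not tuned away: with a 200-gene causal set, $n = 60$, and these effect
sizes, the stage-1 permutation test has roughly 70–80% power at
`alpha = 0.05` (the causal set's score excess is about 2 null standard
deviations), so even the strong-effect gene is recovered in only ~60–75% of
replicates rather than essentially always. Near-certain recovery under this
design would require either a smaller causal set or a more liberal stage-1
screen; both `alpha` and the set sizes are kept at their documented
defaults.

## Evaluation metrics

`error_rate` (0.5-cutoff / argmax misclassification), `gbs` (generalized
Brier score, $\frac{1}{2n}\sum_i\sum_k (Y_{ik}-p_{ik})^2$), `bcm` (belief
confusion metric: mean over classes of the average confidence assigned to
the true class), `aupr` (macro-averaged step-wise average precision), and
`rand_index` (mean pairwise Jaccard similarity of selections across runs, a
stability measure; a pair of empty selections counts 1, a mixed pair 0).
Multi-class problems that factor into binary tasks are composed by
probability products (`compose_multiclass()`), e.g.
$P(\mathrm{AC\!-\!I}) = P(\mathrm{AC}) \times P(\mathrm{stage\ I})$.

## Worked example

```{r, eval = FALSE}
library(samgsr)

dat <- generate_dataset(simulation_config(seed = 3))
w <- build_weights(dat$edges, dat$gsc$universe)

sel <- run_selection(dat$train, dat$gsc, weights = w,
                     c_k = 0.05, alpha = 0.05, B = 200, seed = 3)
sel$genes

clf <- fit_classifier(dat$train, sel$genes, "case", "control", seed = 3)
metrics_report(predict(clf, dat$test))
```
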