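---
title: "Batch-robust miRNA ratio biomarkers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Batch-robust miRNA ratio biomarkers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(errmir)
```

## The problem

miRNA expression profiles are attractive diagnostic material, but absolute
expression levels measured by small RNA sequencing are strongly affected by
the library preparation kit, sequencing platform and center. A classifier
trained on one cohort's expression matrix routinely fails on an external
cohort because the feature distributions have shifted wholesale — the batch
effect. Post-hoc correction tools (ComBat-style location/scale adjustment,
linear-model residualization) require re-fitting on every new cohort and can
distort genuine signal.

`errmir` takes a different route: it never uses a miRNA's absolute level as
a feature. Instead, every feature is a **within-sample ratio** of two
miRNAs,

$$\mathrm{ERRmiR}(a,b) = \frac{x_a}{x_b + 1},$$

where \(x_a, x_b\) are the RPM values of miRNAs \(a\) and \(b\) in the same
sample and the +1 offset keeps the denominator positive when \(b\) is
undetected. A per-sample scale factor \(c\) (total library size, global
capture efficiency) multiplies both numerator and denominator and cancels
almost exactly: the residual log2 distortion is
\(\log_2\{(b+1)/(b+1/c)\}\), which for \(b \ge 100\) RPM and
\(c \in [1/4, 4]\) never exceeds 0.05 log2 units, while the raw
expression values move by up to 2 full log2 units. That bound is asserted
numerically in the test suite and is the quantitative heart of the
batch-robustness claim.

Ratios are formed only for **biologically connected pairs**: miRNA \(a\) is
linked to miRNA \(b\) when \(a\) represses a transcription factor (TF) that
in turn regulates \(b\). This keeps the feature space small (network edges,
not all \(\binom{p}{2}\) pairs) and keeps each feature interpretable — every
marker comes with the mediating TF set attached.

## Network composition

Two regulation layers are joined: a miRNA→TF table (miRTarBase-style,
mature miRNA ids) and a TF→miRNA table (TransmiR-style, precursor ids).
`compose_network()` creates the directed edge \(a \to b\) whenever some TF
\(t\) satisfies \(a \to t\) and \(t \to b\); the mediator set of the edge is
exactly the set of such TFs. Self-loops are dropped, duplicate pairs merged.

Two readings of "a regulated a TF that was regulated by b" are possible: a
chain \(a \to t \to b\), or co-targeting (both miRNAs repress the same TF).
We default to the chain — it is the only reading that uses both collected
layers, and it matches the pentagram→square→circle narrative of the
original network figure — but expose `join_mode = "co_target"` for the
other reading rather than deciding silently.

Because the two layers name miRNAs at different maturity levels,
`map_to_mature()` expands precursor endpoints to all their mature forms
(cross-product per edge, mediators preserved, duplicates merged by mediator
union). Mapping is symmetric: whichever endpoint appears in the precursor
map is expanded; already-mature ids pass through.

`topology_stats()` characterizes the undirected projection: degree
histogram, a power-law exponent (negative slope of the least-squares fit of
log count on log degree over observed degrees — a deliberately simple,
reproducible tail diagnostic, not a maximum-likelihood fit), average local
clustering (isolates contribute 0) and mean shortest path on the largest
connected component. Real miRNA–TF networks show scale-free-like tails and
small-world path lengths; the statistics let users verify their own edge
tables behave similarly.

## Feature engineering

* `counts_to_rpm()` scales each sample to reads per million; if mapped-read
  totals are not supplied, column sums are used, making the operation
  idempotent on already-normalized data.
* `filter_low_expression()` retains miRNAs whose **median** training RPM is
  at least 100. The threshold follows the stable-detection convention for
  small RNA-seq; the aggregation rule is configurable (`median`, `mean`,
  `min`), with the median chosen as the default for robustness to single
  outlying samples. The filter is computed on training samples only and
  frozen, so no information leaks from test or validation data.
* `compute_errmir()` emits one feature per network edge with both endpoints
  retained, in deterministic lexicographic order, named `"a|b"`.

Downstream statistics operate on \(\log_2(\text{ratio} + \varepsilon)\)
with \(\varepsilon = 2^{-20}\): ratios are strictly positive only when the
numerator is detected, and the tiny offset keeps zeros finite without
distorting values of magnitude ≥ 1. Raw expression, where it is analyzed
for comparison, is transformed as \(\log_2(x+1)\), the usual convention for
count-scale data.

`batch_stability_report()` quantifies the robustness claim on real or
simulated multi-batch data: per miRNA and per feature, the range of
per-batch medians on the log2 scale, plus per-sample quartile summaries for
the classic quartile-plot contrast (stable ratio distributions versus
drifting raw distributions).

## Screening

Candidate features pass a univariate filter: two-sided Mann–Whitney U test
(distribution-free, appropriate for right-skewed ratios; Welch's t is
available), Benjamini–Hochberg adjustment across all tested features,
candidates at \(q < 0.05\) and \(|\log_2 \mathrm{FC}| \ge 0.5\). The
fold-change floor deserves a note: the canonical cutoff of 1.0 log2 unit
would sit exactly at a two-fold effect size, and an estimate-based filter
centered on the true effect excludes about half of genuine two-fold markers
purely by sampling symmetry. We therefore default to 0.5 — half the effect
size the pipeline is designed to detect — which keeps essentially all
two-fold signals at the study's sample sizes while still removing the bulk
of the null features. Both thresholds are configurable, and the filter can
be bypassed entirely (`use_univariate = FALSE`).

The wrapper stage is a genetic algorithm over binary feature masks
(`ga_select()`): tournament selection (size 3), uniform crossover
(probability 0.8), per-bit mutation at \(1/L\), elitism 1, population 50,
40 generations by default. Fitness is the mean stratified 5-fold
cross-validated AUC of the downstream SVM on the masked features, minus an
optional subset-size penalty (0 by default). Three design choices matter
for reproducibility:

1. **Fixed fitness landscape.** The cross-validation folds inside the
   fitness are derived from the configuration seed, not the per-run search
   seed. Repeated runs and the exhaustive-enumeration oracle used in the
   tests therefore score every mask identically; only the search path
   varies across repeats.
2. **Tie-break toward smaller subsets.** When two masks tie on fitness
   (common once CV-AUC saturates at 1), the best-ever record keeps the
   smaller subset. Without this, uninformative features ride along in
   optimal subsets at the ~50% rate of random inclusion and blur the
   frequency tally.
3. **Memoised fitness.** Masks are cached within a run, so a converged
   population costs almost nothing to re-score.

`repeat_ga()` runs the GA `n_repeats` times (seeds `seed + 0, 1, ...`) and
counts, once per run, which features appear in the run's optimal subset.
Stable markers accumulate high counts and the distribution is steep when
signal is strong; `top_k_markers()` takes the top k (default 3), breaking
ties lexicographically for determinism.

## Classification and evaluation

`split_train_test()` allocates `round(0.75 n)` samples to training,
apportioned across classes by largest remainder — a balanced cohort of 100
yields exactly 75/25 with 38/37 per class.

`train_model()` fits the pipeline log2 → per-feature z-score (training
statistics only) → radial-kernel C-SVM (C = 1, kernel width by the
"scale" convention \(\gamma = 1/(d \cdot \overline{\mathrm{var}})\), i.e.
approximately \(1/d\) after standardization) with Platt-calibrated
probabilities. The risk score is the calibrated probability of the disease
class, computed from the serialized support vectors, coefficients and
sigmoid — the model round-trips through plain JSON with no binary payload,
and the serialized decision function is verified against the fitting
library's own predictions in the tests.

The operating threshold is chosen by maximizing Youden's J on the
**training** scores and frozen for every subsequent evaluation (a fixed 0.5
cut is available). `evaluate()` reports sensitivity and specificity at that
threshold plus the full ROC curve; ROC points group tied scores (midrank
convention), which makes the trapezoidal AUC exactly equal to the
Mann–Whitney concordance probability — an identity the tests assert on
random score vectors. `learning_curve()` provides the usual
train-versus-validation AUC curves over increasing training sizes for
overfitting diagnosis.

`run_discover()` chains the whole pipeline; `run_validate()` applies a
frozen marker panel to an external cohort, computing ratio features for the
marker pairs directly **without** re-applying the abundance filter — a
deployed panel is fixed, and re-filtering on validation data would silently
change the model's inputs.

## The synthetic study generator

`simulate_study()` generates everything needed to test the pipeline end to
end with known ground truth. On the log2 scale,

\[
\log_2 x_{ij} = \mu_j + \epsilon_{ij} + y_i\,\delta\,[j \in \text{planted
numerators}] + \log_2 c_i + \beta_{jb(i)},
\]

with baseline \(\mu_j \sim N(10, 2^2)\) log2-RPM (putting ~95% of miRNAs
above the 100-RPM filter), biological noise
\(\epsilon_{ij} \sim N(0, 0.5^2)\), group effect \(\delta = 1\) log2 unit
(two-fold) applied to the numerator miRNA of each planted network edge,
per-sample library factor \(c_i\) log-uniform on [1/4, 4], and per-miRNA
per-batch protocol bias \(\beta_{jb} \sim N(0, 0.1^2)\). The defaults
follow the regime the method targets: two batches of 30 + 30 samples, 60
miRNAs, 15 TFs with 5% regulation density, 5 planted pairs.

The two batch terms are deliberately different in kind. The library factor
is large (a 16-fold range, sd ≈ 1.15 log2 units) and cancels in ratios —
this is the component that defeats raw-expression models. The protocol
bias is small and does **not** cancel, so ratio features are robust, not
magically immune.

Planting deserves care: the group effect sits on the numerator miRNA, so
*every* network edge incident to that miRNA becomes differential, and the
GA frequency tally splits across these collinear siblings. The generator
therefore prefers planted edges whose numerator appears in no other edge —
a sole signal carrier — degrading to pairwise-disjoint endpoints (and
finally arbitrary edges) when the network is too dense to supply enough
such nodes. Planted endpoints are also required, where possible, to have
baseline abundance above the 100-RPM detection filter: a signal planted on
an undetectable miRNA is vacuous ground truth, since the filter is *meant*
to remove it before screening. In the recovery checks the two regulation layers are drawn
asymmetrically (dense miRNA→TF, sparse TF→miRNA, mirroring the
miRTarBase/TransmiR asymmetry), which keeps composed out-degrees near one
and makes sole carriers plentiful. When planted numerators are shared by
several edges, recovery should be read at the numerator level, as the unit
tests do.

Abundances are log-normal rather than negative-binomial: the pipeline
consumes RPM-scale values, and the log-normal form keeps the planted log2
effects exact and the stability bounds analytic. What the generator does
*not* emulate: count-level sampling noise at low abundance, correlated
miRNA co-expression programs, mixed cell-type composition, and real
platform-specific sequence biases. Passing the recovery tests therefore
demonstrates the pipeline's mechanics — filtering, ratio formation,
screening, selection, transfer — under a faithful but idealized batch
model, not clinical performance on any particular cohort.

## Problem sizes used in the checks

The bundled checks run the full pipeline at deliberately modest sizes
chosen to exercise every code path: network-composition oracles on up to 50
miRNAs / 20 TFs; GA-versus-exhaustive comparisons on 10-feature instances
(1,024 subsets enumerable exactly); recovery runs with 200 miRNAs, 5
planted pairs and 60 samples per group, with the GA at population 30 and 15
generations repeated 10 times; and cross-batch transfer at the default
two-batch configuration. These sizes are statements of the test design —
larger studies simply scale the same operations.

## Known limitations

* The ratio offset (+1) assumes RPM-like scaling; counts from very deep or
  very shallow libraries should be converted to RPM first.
* The GA's fitness is a cross-validated estimate; with tiny training sets
  its variance can make the frequency table flat. More repeats, not larger
  populations, are the effective remedy.
* Marker collinearity: edges sharing a differential numerator are
  near-duplicates, and the frequency tally splits across them. Marker
  lists should be read at the miRNA level as well as the pair level.
* Platform migration beyond scale-plus-bias (e.g. qPCR versus sequencing)
  is outside the generator's batch model and untested here.
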