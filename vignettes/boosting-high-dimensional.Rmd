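---
title: "Boosting depth-capped trees on high-dimensional two-class data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boosting depth-capped trees on high-dimensional two-class data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdboost)
```

## The problem

In gene-expression class prediction the number of variables `p` (thousands
of probes) dwarfs the number of samples `n` (tens of patients). hdboost
studies how boosting ensembles of classification and regression trees
behave in this regime, where a phenomenon specific to high dimensions
dominates: even a *depth-capped* tree — nominally a weak learner — can
separate a small training set perfectly. With `n = 50` samples and
`p >= 1000` independent variables there is almost always some combination
of a few variables that shatters the sample, so a depth-5 tree (at most 31
internal splits) reaches a resubstitution error of exactly zero even when
the two classes have identical distributions.

This breaks AdaBoost.M1. Its weight update is driven by the weighted
resubstitution error $\epsilon_m$ of stage $m$: when $\epsilon_m = 0$ the
weights never move, every stage refits the identical tree, and the
thousand-tree ensemble predicts exactly like one overfit tree. The package
implements that failure mode faithfully (it is asserted bit-for-bit in the
tests) together with the algorithms that avoid it:

* **AdaBoost.M1.ICV** replaces $\epsilon_m$ with an internally
  cross-validated error: within each boosting iteration the weighted
  training set is split into 5 class-stratified folds, a weighted tree is
  fit on each complement, and the held-out misclassification indicators
  $\epsilon_m^i$ drive the update
  $w_i \leftarrow w_i e^{\alpha_m \epsilon_m^i}$,
  $\alpha_m = \ln((1-\epsilon_m)/\epsilon_m)$. An honest error estimate
  stays away from zero, so the weights keep moving and the stage trees
  stay diverse.
* **Gradient boosting** (exponential loss) updates a real-valued score by
  one Newton step per terminal node of a regression tree fit to the
  pseudo-residuals; even at zero training error the residuals are nonzero,
  so the ensemble never degenerates, though with very small samples its
  updates become negligible and it tracks its base tree.
* **Stochastic gradient boosting** grows each tree (and computes its leaf
  updates) on a random half of the samples while applying the score update
  to all of them; the update is therefore partly driven by samples the
  tree never saw — the same honesty principle as the ICV variant, and
  empirically the strongest method here.
* **LogitBoost** performs adaptive Newton fitting of an additive logistic
  model with weighted regression stumps on the working response.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `max_depth` | depth cap of the base trees | 5 (stumps: 1) | the two base learners under study |
| `M` | boosting iterations | 100 (studies use up to 1000) | curves flatten after a few hundred |
| `nu` | shrinkage on each gradient stage | 1 (GrBoost), 0.01 (St-GrBoost) | shrinkage helps only with subsampling in this regime |
| `eta` | subsampling fraction per iteration | 0.5 | half-sampling without replacement |
| `icv_folds` | internal CV folds per iteration | 5 | avoids one-class folds at n = 50 |

Tree growth deliberately uses `min_samples_split = 2`,
`min_samples_leaf = 1` and no pruning: only the depth cap regularizes.
The overfitting phenomenon the package studies requires trees able to
shatter a small sample; stronger stopping rules would suppress it.

## The synthetic designs

All studies run on seeded synthetic data, so every result in the tests is
reproducible without downloads.

* **Block-correlated normal data** (the flagship design): `p = 1000`
  variables with unit variance in blocks of 10 with exchangeable
  correlation 0.8, independent across blocks; the first 100 variables are
  differentially expressed with a mean shift of 0.7 in class 2; balanced
  training sets of 50, test sets of 500 per class. DE variables occupy the
  first columns (and hence the first 10 blocks) — their placement is a
  design choice; contiguous placement keeps DE variables correlated within
  blocks, matching the 10-per-block structure.
* **Independent null data**: iid standard normals, labels independent of
  the features (Bayes error 0.5); used to demonstrate the
  zero-resubstitution-error phenomenon.
* **Variance-shift data**: equal means everywhere, 20 informative
  variables whose variance shrinks four-fold in class 2, nesting one class
  inside the other; a separation no stump can express.
* **Imbalanced null fixtures** for the preprocessing operators
  (variance pre-filter, missingness rules, majority down-sizing, repeated
  stratified CV with per-run down-sizing).

What these designs do *not* emulate: heavy-tailed and skewed expression
distributions, batch effects, gene-network correlation beyond exchangeable
blocks, and annotation-level artifacts. Passing tests demonstrate
algorithmic correctness and the regime's qualitative behavior, not
end-to-end performance on real microarray series.

## Numerical choices

* Split thresholds are midpoints between consecutive distinct sorted
  values; candidate splits tie-break toward the lowest variable index and
  then the lowest threshold; a sample exactly at the threshold routes
  left; weighted-majority ties at leaves go to class 1. These rules make
  every fit bit-reproducible.
* Zero-weight samples are excluded from fitting entirely, which makes
  duplicating a sample exactly equivalent to doubling its weight.
* AdaBoost variants: at $\epsilon_m = 0$ the stage weight is clamped to
  $\ln((1-\delta)/\delta)$, $\delta = 1/(2n)$, and the weights left
  unchanged — reproducing the frozen-ensemble behavior. For plain
  AdaBoost.M1, a stage with $\epsilon_m \ge 1/2$ restarts once from
  uniform weights and is accepted with $\alpha_m = 0$ if it fails again
  (with resubstitution error this is a near-impossible edge case). For the
  ICV variant the restart rule turned out to be wrong in practice: an
  honest error estimate legitimately crosses 1/2 as the weights
  concentrate, and resetting to uniform collapses the ensemble onto its
  deterministic base tree. The ICV update therefore applies
  $\alpha_m = \ln((1-\epsilon_m)/\epsilon_m)$ without clamping: past the
  1/2 boundary the stage weight turns negative, which pushes weight *off*
  the currently misclassified samples — a self-stabilizing feedback that
  keeps the weighted CV error hovering near 1/2 and the stage trees
  diverse. The voted ensemble then behaves like an adaptively reweighted
  tree committee, which is what makes the method effective at large M.
* Gradient leaf updates are capped at $|\gamma| \le 8$ and the initial
  score is the half log-odds $F_0 = \tfrac12\ln(n_2/n_1)$ (zero on
  balanced data).
* LogitBoost uses the standard working-response clipping
  $z_{\max} = 4$ and weight floor $2\sqrt{\varepsilon_{mach}}$.
* AUC uses midrank tie handling. Ensemble scores: normalized vote margin
  for the AdaBoost variants, the additive score $F$ for the gradient
  variants, the fitted probability for LogitBoost.
* Cross-validated iteration selection pools held-out predictions across
  folds (a step function with increments of $1/n$) and takes the smallest
  minimizer on ties; out-of-bag selection takes the argmax of the
  cumulative sum of per-iteration out-of-bag loss improvements,
  unsmoothed by default.
* Wilcoxon signed-rank comparisons use the exact null for up to 25 paired
  settings and Holm's step-down adjustment.

## Scale of the shipped checks

The package's acceptance-style checks rerun the flagship design at reduced
replicate counts, chosen so that the standard error of a mean error over a
1000-sample test set stays near 0.01: 30 replicates for the single-tree
reference error, 20 for the 1000-iteration stochastic-gradient and
LogitBoost curves. The full-scale analyses behind the package use 100
replicates; `run_experiment()` accepts any `R`.

## Known limitations

* The quantitative degree of LogitBoost's late overfitting depends on
  implementation details of the stump and the working-response clipping.
  This implementation reproduces the qualitative signature — the test
  error reaches its minimum early (typically before iteration 300 of
  1000) and never improves afterwards — but its late-iteration rebound is
  a few thousandths rather than the several hundredths other
  implementations can show: with clipping active, the fitted scores
  saturate and the curve flattens instead of climbing.
* The ICV variant's large-M behavior depends on the $\epsilon \ge 1/2$
  policy discussed above; the unclamped choice is the package's own
  resolution of an underdetermined recursion, selected because the
  alternatives (restart or freeze) demonstrably collapse or degrade the
  ensemble.
* Real-microarray reanalysis is out of scope; only the preprocessing
  operators (variance pre-filter, missingness handling, majority-class
  down-sizing, repeated stratified CV) are provided, tested on synthetic
  fixtures.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(p = 1000, n_train = 50, mu2 = 0.7, rho = 0.8,
                  block_size = 10, n_de = 100, seed = 1)
d <- simulate_block_mvn(cfg)

tree <- fit_classification_tree(d$train)
resubstitution_error(tree, d$train)   # 0: the tree shatters the sample

fit <- fit_st_grboost(d$train, boost_config(M = 1000, seed = 1))
curve <- staged_errors(fit, d$test)
min(curve$error)                       # the optimal staged test error
select_m_oob(fit)                      # OOB-selected iteration count
```
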