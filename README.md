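# hdboost

Boosting ensembles of depth-capped CART trees for two-class prediction
when the number of variables vastly exceeds the number of samples — the
regime of gene-expression class prediction, where a study typically has
tens of patients and thousands of probes.

## The problem and the algorithms

A depth-capped classification tree is nominally a weak learner, but in
high dimensions it stops being weak in the one sense that matters to
AdaBoost: with `n = 50` samples and thousands of variables a depth-5 tree
almost surely attains *zero* resubstitution error, even when the classes
are identically distributed. AdaBoost.M1 reweights samples according to
the stage's weighted resubstitution error
ε_m = Σᵢ wᵢ·1[c_m(xᵢ) ≠ yᵢ]; when ε_m = 0 the weights never move, every
stage refits the same tree, and the ensemble of a thousand trees predicts
exactly like one overfit tree.

The package implements five boosting algorithms around this phenomenon,
all sharing one weighted tree engine (weighted Gini for classification,
weighted least squares for regression, written in C++):

* `fit_adaboost_m1()` — classical discrete AdaBoost with
  α_m = ln((1−ε_m)/ε_m) and weighted majority voting;
* `fit_adaboost_m1_icv()` — the same recursion with ε_m replaced by an
  *internally cross-validated* error: each iteration 5 class-stratified
  folds are refit under the current weights and the held-out per-sample
  indicators εᵢ drive the update wᵢ ← wᵢ·exp(α_m εᵢ);
* `fit_grboost()` — gradient boosting of a score F(x) under the
  exponential loss L = exp(−ỹF), ỹ ∈ {−1,+1}, with one Newton step per
  terminal node, γ_j = Σ r_i / Σ |r_i|, and shrinkage ν;
* `fit_st_grboost()` — stochastic gradient boosting: each tree and its
  leaf updates are computed on a random ⌊ηn⌋-subsample (η = 0.5,
  ν = 0.01 by default) while the score update applies to all samples;
* `fit_logitboost()` — adaptive Newton fitting of an additive logistic
  model with weighted regression stumps on the working response
  z = (y* − p)/(p(1−p)).

Around them sit the pieces needed to study the regime end to end: seeded
generators for block-correlated expression-like data, independent null
data and variance-shift ("nested classes") data; staged prediction for
error-versus-iterations curves; PA/PA1/PA2/AUC/g-means metrics;
cross-validated and out-of-bag selection of the iteration count;
Wilcoxon/Holm classifier ranking; a replicated experiment runner; and the
microarray preprocessing operators (variance pre-filter, missingness
rules, majority-class down-sizing, repeated stratified CV).

## A worked example

```r
library(hdboost)

cfg <- sim_config(p = 1000, n_train = 50, mu2 = 0.7, rho = 0.8,
                  block_size = 10, n_de = 100, seed = 42)
d <- simulate_block_mvn(cfg)

tree <- fit_classification_tree(d$train)
resubstitution_error(tree, d$train)
#> [1] 0
mean(predict(tree, d$test) != d$test$class)
#> [1] 0.286

fit <- fit_adaboost_m1(d$train, boost_config(M = 10))
tidy(fit)[1:3, ]
#> # A tibble: 3 x 3
#>       m epsilon alpha
#>   <int>   <dbl> <dbl>
#> 1     1       0  4.60
#> 2     2       0  4.60
#> 3     3       0  4.60
staged_errors(fit, d$test)$error[c(1, 10)]
#> [1] 0.286 0.286

sgb <- fit_st_grboost(d$train, boost_config(M = 100, seed = 7))
min(staged_errors(sgb, d$test)$error)
#> [1] 0.182
```

The tree shatters its 50 training samples (resubstitution error 0) yet
errs on 28.6% of fresh samples; AdaBoost.M1's stage errors are all zero,
so its ensemble error is bit-identical to the single tree's at every
iteration count, while stochastic gradient boosting — whose updates are
partly driven by samples each tree never saw — cuts the error to 0.182
within 100 iterations on the same data.

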