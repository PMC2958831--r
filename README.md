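# mirfuse

Integrative scoring of microRNA target predictions.

## What it is for

Sequence-based miRNA target predictors — miRanda, PicTar, TargetScan —
disagree widely: a strong candidate for one algorithm is often a weak
candidate for the others, and each suffers substantial false-positive and
false-negative rates. Paired miRNA/mRNA expression profiles measured
across a sample panel carry an orthogonal, function-level signal: a true
target's transcript level should *fall* as its regulator's level rises.

mirfuse combines the four evidence streams into one probability of
experimental support per predicted target site, for anyone benchmarking
target predictors or building an integrated target catalogue from score
tables plus an expression panel.

## The model

For site *i* with per-source scores *x*<sub>j,i</sub> (miRanda score on
its native scale, PicTar score / 1000, TargetScan P<sub>CT</sub>, and an
expression score), the integrated score is a logistic regression fitted
by maximum likelihood against a curated gold standard of validated
(miRNA, gene) pairs:

```
p_i = 1 / (1 + exp(-(b0 + sum_j b_j * x_ji)))
```

The expression score is the two-sided p-value of the OLS slope of gene on
miRNA expression across samples *when that slope is negative*, and 1
otherwise. Evaluation uses ROC curves with trapezoidal AUC
(= Mann–Whitney with ties at 1/2), the Hanley–McNeil closed-form AUC
standard error with Q1 = θ/(2−θ) and Q2 = 2θ²/(1+θ), a z test for the
difference of two correlated AUCs, and K-fold cross-validation of the
fitted model. A seeded synthetic-data generator with planted regulatory
structure makes the whole pipeline testable offline.

## Worked example

Simulate a small study (1000 candidate pairs, 100 truly regulatory, 58
samples), score the pairs by expression association, assemble features,
fit and evaluate:

```r
library(mirfuse)

truth    <- simulation_truth(n_pairs = 1000, n_true = 100, seed = 42)
ds       <- simulate_dataset(truth)
preds    <- ds$predictions
pairs    <- unique(do.call(rbind, unname(preds))[, c("mirna_id", "gene_id")])
assoc    <- associate_pairs(ds$mirna_expr, ds$gene_expr, pairs)
gold     <- build_gold_standard(ds$gold, "tarbase")
features <- assemble_features(preds, assoc, gold)

fit <- fit_model(features)
fit
#> Integrative logistic target-scoring model
#>   features: x_miranda, x_pictar, x_targetscan, x_expr
#>   n = 1320  prevalence = 0.09924
#>              estimate std_error
#> (Intercept)  -3.11784   0.41285
#> x_miranda     0.06209   0.01536
#> x_pictar      1.27503   0.36045
#> x_targetscan  2.75748   0.39151
#> x_expr       -3.84035   0.54503
#>   converged: TRUE in 8 iterations; log-likelihood -188.163
```

Positive coefficients for the three algorithm scores and a negative one
for the expression p-value (low p = support) mean every source
contributes in the expected direction. Compare the integrated score with
the best single source on the same rows:

```r
est    <- auc_estimate(predict_score(fit, features), features$label)
single <- auc_estimate(features$x_targetscan, features$label)
r      <- estimate_r(predict_score(fit, features), features$x_targetscan,
                     features$label)
cmp    <- compare_auc(est, single, r)
est$omega; single$omega; cmp$z
#> integrated AUC: 0.9383 (SE 0.0147)
#> targetscan AUC: 0.8257 (SE 0.0227)
#> difference: z = 6.62, p = 3.7e-11 (r = 0.66)

kfold_cv(features, K = 10, seed = 1)$mean_prediction_error
#> [1] 0.03838771
```

The integration clearly outperforms the lone source (z = 6.6 on the
correlated-AUC test), and the held-out squared error of ~0.038 against
a label prevalence of ~0.1 says most held-out probabilities sit near
their labels.

The same workflow is available from a shell via `exec/mirfuse`
(subcommands `simulate`, `associate`, `assemble`, `fit`, `predict`,
`evaluate`, `cv`, `run`).

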