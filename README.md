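# sccat — adaptive skin-cancer risk assessment and classification

`sccat` is an R implementation of a computerized-adaptive-testing (CAT)
pipeline for self-assessed skin-cancer (SC) risk. It is aimed at
psychometricians and biostatisticians who want to study — or reuse —
the combination of a Rasch partial credit model (PCM), adaptive item
administration, expected-value imputation of unanswered items, and
simple machine-learning classifiers for the resulting risk label.

The package ships a calibrated 30-item difficulty bank (pigmentation,
sun exposure, sunburn and sunscreen history, personal cancer history;
difficulties in logits) and builds everything else from it:

* **PCM core** — category probabilities
  `P(X=k|θ) ∝ exp Σ_{j≤k}(θ − δ_ij)`, expected scores, item (Fisher)
  information, and seeded response sampling.
* **Cohort simulator** — `n = 1000` virtual respondents with
  `θ ~ N(0,1)` logits, PCM responses to all 30 items, binary cancer
  labels by thresholding the true ability at 0.88 logits (~19%
  positives), plus 70:30 hold-out and stratified k-fold splitters.
* **CAT engine** — Newton–Raphson ability updates
  `θ' = θ + Σ(O−E)/ΣVar`, maximum-information item selection,
  stopping at CAT SE below the SEM `SD·√(1−Rel)` (0.469 logits at
  reliability .78), expected-score imputation, and infit/outfit
  person-fit diagnostics with the `t = ln v + v − 1` normalization.
* **Classifiers** — Gaussian naive Bayes, k-nearest neighbors
  (Weka-IBk-style `k = 1` default), and unregularized logistic
  regression, all predicting `P(SC+)` from the 30 (possibly imputed)
  item scores.
* **Evaluation calculus** — confusion-matrix metrics, the
  single-operating-point AUC
  `(1−spec)·sens/2 + (sens+1)·spec/2` with normal-approximation 95%
  CIs, full trapezoidal ROC AUC for pooled out-of-fold predictions,
  and imbalance-aware balanced operating thresholds.
* **Forest-plot module** — per-item standardized mean differences
  (Cohen's d, pooled SD) between label groups with Cochran's Q
  heterogeneity.

## Worked example

```r
library(sccat)

bank <- skin_item_bank()
cohort <- generate_cohort(bank, n = 1000, seed = 1)
cohort
#> Simulated cohort: 1000 respondents x 30 items; 194 positive labels (19.4%)

# one adaptive test for a respondent with true ability 1.2 logits
session <- run_cat(bank, responder = 1.2, seed = 7)
session
#> CAT session: 3 of 30 items administered (90% saved); stopped: sem_reached
#> Final ability: 0.99 logits (SE 0.419)
#> Person fit: infit 0.47, outfit 0.45

evaluate_holdout(cohort, seed = 1)
#>  model    split   n sensitivity specificity precision accuracy     AUC (95% CI)
#>     nb training 700        0.99        0.86      0.62     0.88 0.93 (0.91-0.95)
#>     nb  testing 300        0.95        0.86      0.64     0.88 0.91 (0.87-0.94)
#>    knn training 700        1.00        1.00      1.00     1.00 1.00 (1.00-1.00)
#>    knn  testing 300        0.90        0.92      0.74     0.91 0.91 (0.88-0.94)
#>     lr training 700        0.93        0.98      0.90     0.97 0.95 (0.94-0.97)
#>     lr  testing 300        0.85        0.96      0.84     0.94 0.91 (0.87-0.94)
#> Non-overlapping AUC CIs:
#>   training: nb vs knn
#>   training: knn vs lr
```

Reading the output: the adaptive test reached the 0.469-logit
precision target after only 3 of 30 items (a 90% reduction in
respondent burden) and its fit statistics are unremarkable (outfit well
below the 2.0 aberrance cutoff). In the hold-out comparison, training
rows are scored by the model that memorized them — which is why
self-inclusive 1-NN is perfect there — while the testing columns
estimate generalization; all three models hold AUCs near 0.91 on the
held-out 300. `evaluate_kfold()` gives the stricter pooled out-of-fold
picture, and `forest_summary()` the per-item group separation.

A command-line front end over the same functions lives at
`inst/cli/sccat-cli.R` (subcommands `simulate`, `evaluate`, `cat`,
`forest`, `train`, `predict`).

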