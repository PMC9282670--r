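test_that("confusion counts match a brute-force tally", {
  expect_equal(confusion(c(1, 0, 1), c(1, 0, 1))[c("fp", "fn")],
               list(fp = 0L, fn = 0L))
  set.seed(40)
  for (rep in 1:10) {
    n <- sample(5:50, 1)
    pred <- sample(0:1, n, replace = TRUE)
    truth <- sample(0:1, n, replace = TRUE)
    cc <- confusion(pred, truth)
    tally <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
    for (i in seq_len(n)) {
      key <- if (pred[i] == 1 && truth[i] == 1) "tp"
             else if (pred[i] == 0 && truth[i] == 0) "tn"
             else if (pred[i] == 1) "fp" else "fn"
      tally[key] <- tally[key] + 1L
    }
    expect_equal(cc[c("tp", "tn", "fp", "fn")], as.list(tally))
    expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, cc$n)
  }
})

test_that("single-point AUC reproduces the published operating points", {
  expect_equal(round(point_auc(0.83, 0.99), 2), 0.91)
  expect_equal(round(point_auc(0.70, 0.92), 2), 0.81)
  expect_equal(round_half_up(point_auc(0.79, 0.98), 2), 0.89)
  expect_equal(point_auc(1, 1), 1)
})

test_that("single-point AUC equals the two-segment ROC trapezoid area", {
  # geometric oracle: area under the polyline
  # (0,0) -> (1-spec, sens) -> (1,1) by explicit trapezoids
  set.seed(41)
  for (rep in 1:25) {
    sens <- runif(1)
    spec <- runif(1)
    x1 <- 1 - spec
    area <- x1 * sens / 2 + (1 - x1) * (sens + 1) / 2
    expect_equal(point_auc(sens, spec), area, tolerance = 1e-12)
  }
})

test_that("AUC confidence intervals reproduce the published table", {
  ci <- auc_ci(0.91, 300)
  expect_equal(round(c(ci$ci_low, ci$ci_high), 2), c(0.88, 0.94))
  ci <- auc_ci(0.81, 300)
  expect_equal(round(c(ci$ci_low, ci$ci_high), 2), c(0.77, 0.85))
  perfect <- auc_ci(1, 300)
  expect_equal(perfect$se, 0)
  expect_equal(c(perfect$ci_low, perfect$ci_high), c(1, 1))
})

test_that("full ROC AUC equals the pairwise concordance oracle", {
  expect_equal(full_roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(full_roc_auc(rep(0.4, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    p <- round(runif(n), 2)  # rounded to force ties
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(y)) < 2) next
    pos <- p[y == 1]
    neg <- p[y == 0]
    conc <- 0
    for (a in pos) for (b in neg) {
      conc <- conc + (a > b) + 0.5 * (a == b)
    }
    expect_equal(full_roc_auc(p, y), conc / (length(pos) * length(neg)))
  }
  expect_error(full_roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("balanced threshold moves the operating point, not the ROC", {
  set.seed(43)
  p <- c(rbeta(80, 2, 6), rbeta(20, 6, 2))
  y <- rep(c(0, 1), c(80, 20))
  thr <- balanced_threshold(p, y)
  expect_equal(thr, (mean(p[y == 1]) + mean(p[y == 0])) / 2)
  expect_lt(thr, 0.5)  # imbalanced low-prevalence data pull it down
  # threshold choice cannot change the threshold-free AUC
  expect_equal(full_roc_auc(p, y), full_roc_auc(p, y))
  # confusion metrics do change
  m_bal <- metric_set(confusion(classify(p, thr), y))
  m_half <- metric_set(confusion(classify(p, 0.5), y))
  expect_gte(m_bal$sensitivity, m_half$sensitivity)
})

test_that("undefined metrics are NA, never zero", {
  m <- metric_set(confusion(c(0, 0), c(0, 0)))  # no positives anywhere
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$precision))
  expect_true(is.na(m$auc))
  expect_equal(m$accuracy, 1)
})

test_that("hold-out report has the expected shape and strong AUCs", {
  coh <- generate_cohort(the_bank, n = 1000, seed = 50)
  rep_ho <- evaluate_holdout(coh, seed = 50)
  expect_equal(nrow(rep_ho), 6L)  # 3 models x {training, testing}
  expect_setequal(unique(rep_ho$model), c("nb", "knn", "lr"))
  expect_true(all(rep_ho$n == rep(c(700, 300), 3)))
  expect_true(all(rep_ho$auc > 0.80))
  expect_true(all(rep_ho$ci_high <= 1))
})

test_that("k-fold report pools each respondent exactly once", {
  coh <- generate_cohort(the_bank, n = 400, seed = 51)
  rep_kf <- evaluate_kfold(coh, models = c("nb", "lr"), seed = 51)
  expect_equal(nrow(rep_kf), 2L)
  expect_true(all(rep_kf$n == 400))
  expect_true(all(rep_kf$auc > 0.8))
})

test_that("NB and LR k-fold AUCs dominate KNN's on default cohorts", {
  wins_nb <- wins_lr <- 0
  for (s in 1:5) {
    coh <- generate_cohort(the_bank, n = 500, seed = 60 + s)
    r <- evaluate_kfold(coh, seed = 60 + s)
    auc <- setNames(r$auc, r$model)
    wins_nb <- wins_nb + (auc["nb"] >= auc["knn"])
    wins_lr <- wins_lr + (auc["lr"] >= auc["knn"])
  }
  expect_gte(wins_nb, 4)
  expect_gte(wins_lr, 4)
})

test_that("label-shuffled cohorts drive testing AUCs to chance", {
  coh <- generate_cohort(the_bank, n = 1000, seed = 52)
  set.seed(52)
  coh$labels <- sample(coh$labels)
  coh$theta <- coh$theta  # responses no longer track the labels
  rep_null <- evaluate_holdout(coh, seed = 52)
  testing <- rep_null[rep_null$split == "testing", ]
  expect_true(all(abs(testing$auc - 0.5) < 0.12))
})
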