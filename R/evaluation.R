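#' Confusion counts
#'
#' Tallies true/false positives and negatives from predicted and true
#' 0/1 labels (positive = cancer = 1).
#'
#' @param pred predicted 0/1 labels.
#' @param truth true 0/1 labels, same length.
#' @return list with `tp`, `tn`, `fp`, `fn`, `n`.
#' @export
confusion <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  pred <- as.integer(pred)
  truth <- as.integer(truth)
  list(tp = sum(pred == 1L & truth == 1L),
       tn = sum(pred == 0L & truth == 0L),
       fp = sum(pred == 1L & truth == 0L),
       fn = sum(pred == 0L & truth == 1L),
       n = length(pred))
}

#' Single-operating-point AUC
#'
#' The area under the two-segment ROC polyline through a single
#' operating point `(1 - specificity, sensitivity)`:
#' \deqn{AUC = (1 - spec) \cdot sens / 2 + (sens + 1) \cdot spec / 2}
#' This is the AUC implied by one confusion matrix; e.g. sensitivity
#' 0.83 with specificity 0.99 gives 0.91.
#'
#' @param sensitivity,specificity proportions in `[0, 1]`.
#' @return AUC in `[0, 1]`.
#' @export
point_auc <- function(sensitivity, specificity) {
  (1 - specificity) * sensitivity / 2 + (sensitivity + 1) * specificity / 2
}

#' Classification metrics from confusion counts
#'
#' Sensitivity, specificity, precision, accuracy, and the
#' single-operating-point AUC ([point_auc()]). A metric with a zero
#' denominator is reported as `NA`, never as 0.
#'
#' @param counts a list from [confusion()].
#' @return list of proportions: `sensitivity`, `specificity`,
#'   `precision`, `accuracy`, `auc`, plus the counts.
#' @export
metric_set <- function(counts) {
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- safe_div(counts$tp, counts$tp + counts$fn)
  spec <- safe_div(counts$tn, counts$tn + counts$fp)
  list(
    sensitivity = sens,
    specificity = spec,
    precision = safe_div(counts$tp, counts$tp + counts$fp),
    accuracy = safe_div(counts$tp + counts$tn, counts$n),
    auc = if (is.na(sens) || is.na(spec)) NA_real_ else point_auc(sens, spec),
    counts = counts
  )
}

#' Normal-approximation confidence interval for an AUC
#'
#' `SE = sqrt(AUC (1 - AUC) / N)`; 95% CI = `AUC +/- 1.96 SE`, bounds
#' clipped to `[0, 1]`.
#'
#' @param auc AUC in `[0, 1]`.
#' @param n number of evaluated cases.
#' @return list with `se`, `ci_low`, `ci_high`.
#' @export
auc_ci <- function(auc, n) {
  stopifnot(auc >= 0, auc <= 1, n >= 1)
  se <- sqrt(auc * (1 - auc) / n)
  list(se = se,
       ci_low = max(0, auc - 1.96 * se),
       ci_high = min(1, auc + 1.96 * se))
}

#' Full (trapezoidal) ROC AUC
#'
#' Threshold-free area under the empirical ROC curve of continuous
#' scores against binary labels, computed by [pROC::roc()]. With ties
#' this equals the Mann-Whitney concordance probability.
#'
#' @param probabilities numeric scores (higher = more positive).
#' @param truth 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
full_roc_auc <- function(probabilities, truth) {
  truth <- as.integer(truth)
  if (length(unique(truth)) < 2L) {
    stop("both classes must be present to compute a ROC", call. = FALSE)
  }
  r <- pROC::roc(response = truth, predictor = probabilities,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Balanced decision threshold
#'
#' The midpoint of the two class-conditional mean predicted scores.
#' With imbalanced classes (cancer prevalence ~19% at the 0.88-logit
#' cutoff) a fixed 0.5 threshold starves sensitivity; centering the
#' operating point between the group means balances sensitivity and
#' specificity. Threshold-free metrics (the full ROC AUC) are
#' unaffected by this choice.
#'
#' @param probabilities predicted scores.
#' @param truth 0/1 labels used to locate the group means (the
#'   training labels in a hold-out design).
#' @return scalar threshold.
#' @export
balanced_threshold <- function(probabilities, truth) {
  truth <- as.integer(truth)
  stopifnot(length(unique(truth)) == 2L)
  (mean(probabilities[truth == 1L]) + mean(probabilities[truth == 0L])) / 2
}

eval_one_split <- function(probabilities, truth, threshold_mode, threshold) {
  thr <- if (threshold_mode == "balanced") {
    balanced_threshold(probabilities, truth)
  } else {
    threshold
  }
  m <- metric_set(confusion(classify(probabilities, thr), truth))
  ci <- auc_ci(m$auc, length(truth))
  c(m[c("sensitivity", "specificity", "precision", "accuracy", "auc")],
    list(se_auc = ci$se, ci_low = ci$ci_low, ci_high = ci$ci_high,
         n = length(truth), threshold = thr))
}

report_row <- function(model, split, m) {
  data.frame(model = model, split = split, n = m$n,
             sensitivity = m$sensitivity, specificity = m$specificity,
             precision = m$precision, accuracy = m$accuracy,
             auc = m$auc, se_auc = m$se_auc, ci_low = m$ci_low,
             ci_high = m$ci_high, stringsAsFactors = FALSE)
}

#' Hold-out model comparison
#'
#' Splits the cohort (default 70:30), trains each requested model on
#' the training rows, and reports the full metric set on both the
#' training and the testing rows. AUC here is the
#' single-operating-point AUC at the chosen operating threshold
#' (default: the balanced threshold computed from the evaluated
#' split's own predictions), with its normal-approximation CI.
#' Significance flags mark model pairs whose AUC CIs do not overlap
#' within a split.
#'
#' @param cohort an `sc_cohort`.
#' @param models character vector from `c("nb", "knn", "lr")`.
#' @param train_fraction hold-out proportion (default 0.7).
#' @param seed seed for the split.
#' @param threshold_mode `"balanced"` (default) or `"fixed"` (use
#'   `threshold`).
#' @param threshold fixed decision threshold when
#'   `threshold_mode = "fixed"`.
#' @param knn_k neighbor count for the KNN model.
#' @return an object of class `sc_report`: a data frame with one row
#'   per model x split plus a `significance` attribute.
#' @export
evaluate_holdout <- function(cohort, models = c("nb", "knn", "lr"),
                             train_fraction = 0.7, seed = 1L,
                             threshold_mode = c("balanced", "fixed"),
                             threshold = 0.5, knn_k = 1L) {
  threshold_mode <- match.arg(threshold_mode)
  sp <- split_holdout(cohort, train_fraction, seed)
  rows <- list()
  for (kind in models) {
    model <- train_model(kind, sp$train$responses, sp$train$labels,
                         k = knn_k)
    p_train <- predict(model, sp$train$responses)
    p_test <- predict(model, sp$test$responses)
    rows[[length(rows) + 1L]] <- report_row(
      kind, "training",
      eval_one_split(p_train, sp$train$labels, threshold_mode, threshold))
    rows[[length(rows) + 1L]] <- report_row(
      kind, "testing",
      eval_one_split(p_test, sp$test$labels, threshold_mode, threshold))
  }
  as_sc_report(do.call(rbind, rows))
}

#' k-fold cross-validated model comparison
#'
#' Runs stratified k-fold cross-validation (default 10 folds): each
#' model is trained on the out-of-fold rows and predicts its test
#' fold, so every respondent is predicted exactly once out-of-fold.
#' Pooled out-of-fold probabilities give one full trapezoidal ROC AUC
#' per model ([full_roc_auc()]) with CI at N = cohort size; confusion
#' metrics come from the pooled predictions at the operating threshold.
#'
#' @inheritParams evaluate_holdout
#' @param folds number of folds (default 10).
#' @param stratified stratify folds by label (default TRUE).
#' @return an `sc_report` with one `"kfold"` row per model.
#' @export
evaluate_kfold <- function(cohort, models = c("nb", "knn", "lr"),
                           folds = 10L, stratified = TRUE, seed = 1L,
                           threshold_mode = c("balanced", "fixed"),
                           threshold = 0.5, knn_k = 1L) {
  threshold_mode <- match.arg(threshold_mode)
  fold_list <- make_folds(cohort, folds, stratified, seed)
  n <- length(cohort$ids)
  rows <- list()
  for (kind in models) {
    pooled <- numeric(n)
    for (f in fold_list) {
      model <- train_model(kind, f$train$responses, f$train$labels,
                           k = knn_k)
      idx <- match(f$test$ids, cohort$ids)
      pooled[idx] <- predict(model, f$test$responses)
    }
    thr <- if (threshold_mode == "balanced") {
      balanced_threshold(pooled, cohort$labels)
    } else {
      threshold
    }
    m <- metric_set(confusion(classify(pooled, thr), cohort$labels))
    roc_auc <- full_roc_auc(pooled, cohort$labels)
    ci <- auc_ci(roc_auc, n)
    rows[[length(rows) + 1L]] <- data.frame(
      model = kind, split = "kfold", n = n,
      sensitivity = m$sensitivity, specificity = m$specificity,
      precision = m$precision, accuracy = m$accuracy,
      auc = roc_auc, se_auc = ci$se, ci_low = ci$ci_low,
      ci_high = ci$ci_high, stringsAsFactors = FALSE)
  }
  as_sc_report(do.call(rbind, rows))
}

as_sc_report <- function(df) {
  rownames(df) <- NULL
  sig <- list()
  for (split in unique(df$split)) {
    sub <- df[df$split == split, , drop = FALSE]
    if (nrow(sub) < 2L) next
    pairs <- utils::combn(nrow(sub), 2)
    for (p in seq_len(ncol(pairs))) {
      a <- sub[pairs[1, p], ]
      b <- sub[pairs[2, p], ]
      if (a$ci_low > b$ci_high || b$ci_low > a$ci_high) {
        sig[[length(sig) + 1L]] <- data.frame(
          split = split, model_a = a$model, model_b = b$model,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(df, class = c("sc_report", "data.frame"),
            significance = if (length(sig)) do.call(rbind, sig)
                           else data.frame())
}

#' @export
print.sc_report <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "n"
  df[num] <- lapply(df[num], round, digits)
  df$`AUC (95% CI)` <- sprintf("%.2f (%.2f-%.2f)", df$auc, df$ci_low,
                               df$ci_high)
  print.data.frame(df[, c("model", "split", "n", "sensitivity",
                          "specificity", "precision", "accuracy",
                          "AUC (95% CI)")], row.names = FALSE)
  sig <- attr(x, "significance")
  if (!is.null(sig) && nrow(sig) > 0) {
    cat("Non-overlapping AUC CIs:\n")
    for (i in seq_len(nrow(sig))) {
      cat("  ", sig$split[i], ": ", sig$model_a[i], " vs ",
          sig$model_b[i], "\n", sep = "")
    }
  }
  invisible(x)
}
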