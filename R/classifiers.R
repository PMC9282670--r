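#' Train a skin-cancer risk classifier
#'
#' Fits one of the three reference models on a complete feature matrix
#' of item scores (integer categories from full tests, or real-valued
#' expected-score imputations from adaptive tests) against the binary
#' cancer label:
#'
#' * `"nb"` — Gaussian naive Bayes: per-class, per-feature means and
#'   variances (variance floored at 1e-9) plus empirical class priors.
#' * `"knn"` — k-nearest neighbors: memorizes the training matrix;
#'   prediction is the positive fraction among the `k` nearest rows by
#'   Euclidean distance (default `k = 1`, the Weka IBk default, which
#'   the benchmark classifiers mirror). When the query set is the
#'   training set itself, the self row participates like any other.
#' * `"lr"` — unregularized logistic regression fitted by iteratively
#'   reweighted least squares via [stats::glm()].
#'
#' @param kind one of `"nb"`, `"knn"`, `"lr"`.
#' @param x numeric feature matrix (rows = respondents).
#' @param y binary 0/1 label vector.
#' @param k neighbor count for `"knn"`.
#' @return an object of class `sc_model`.
#' @export
train_model <- function(kind = c("nb", "knn", "lr"), x, y, k = 1L) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y), nrow(x) >= 2L)
  if (length(unique(y)) < 2L) {
    stop("training data contain a single class", call. = FALSE)
  }
  fit <- switch(kind,
    nb = {
      classes <- sort(unique(y))
      stats_by_class <- lapply(classes, function(cl) {
        xs <- x[y == cl, , drop = FALSE]
        v <- apply(xs, 2, stats::var)
        v[!is.finite(v)] <- 0
        list(mean = colMeans(xs), var = pmax(v, 1e-9))
      })
      names(stats_by_class) <- as.character(classes)
      list(classes = classes, stats = stats_by_class,
           prior = as.numeric(table(factor(y, levels = classes)) / length(y)))
    },
    knn = {
      stopifnot(k >= 1L, k <= nrow(x))
      list(x = x, y = y, k = as.integer(k))
    },
    lr = {
      df <- data.frame(y = y, x)
      g <- suppressWarnings(
        stats::glm(y ~ ., data = df, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8,
                                                maxit = 100L))
      )
      if (!g$converged) {
        warning("logistic regression did not converge; using last iterate",
                call. = FALSE)
      }
      co <- stats::coef(g)
      co[is.na(co)] <- 0  # rank-deficient columns drop out of the score
      list(coef = co, converged = g$converged)
    }
  )
  structure(list(kind = kind, fit = fit, n_features = ncol(x)),
            class = "sc_model")
}

#' Predicted positive-class probabilities
#'
#' @param object an `sc_model`.
#' @param newdata numeric feature matrix with the training column count.
#' @param ... unused.
#' @return numeric vector of `P(label = 1)` per row, in `[0, 1]`.
#' @export
predict.sc_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != object$n_features) {
    stop("feature count mismatch: model expects ", object$n_features,
         " columns, got ", ncol(x), call. = FALSE)
  }
  switch(object$kind,
    nb = nb_posterior(object$fit, x),
    knn = knn_positive_fraction(object$fit, x),
    lr = {
      eta <- drop(cbind(1, x) %*% object$fit$coef)
      stats::plogis(eta)
    }
  )
}

# Gaussian class-conditional log-likelihoods -> posterior P(y=1)
nb_posterior <- function(fit, x) {
  loglik <- vapply(seq_along(fit$classes), function(ci) {
    st <- fit$stats[[ci]]
    ll <- rep(log(fit$prior[ci]), nrow(x))
    for (j in seq_len(ncol(x))) {
      ll <- ll + stats::dnorm(x[, j], st$mean[j], sqrt(st$var[j]),
                              log = TRUE)
    }
    ll
  }, numeric(nrow(x)))
  loglik <- matrix(loglik, nrow = nrow(x))
  m <- apply(loglik, 1, max)
  post <- exp(loglik - m)
  post <- post / rowSums(post)
  pos_col <- match(1L, fit$classes)
  if (is.na(pos_col)) rep(0, nrow(x)) else post[, pos_col]
}

# fraction of positive labels among the k nearest training rows;
# distance ties broken by lowest training-row index (stable order())
knn_positive_fraction <- function(fit, x) {
  train <- fit$x
  train_sq <- rowSums(train^2)
  vapply(seq_len(nrow(x)), function(i) {
    d2 <- train_sq - 2 * drop(train %*% x[i, ]) + sum(x[i, ]^2)
    nn <- order(d2)[seq_len(fit$k)]
    mean(fit$y[nn] == 1L)
  }, numeric(1))
}

#' @export
print.sc_model <- function(x, ...) {
  label <- c(nb = "Gaussian naive Bayes", knn = "k-nearest neighbors",
             lr = "logistic regression")[x$kind]
  cat("sc_model: ", label, " (", x$n_features, " features)\n", sep = "")
  if (x$kind == "knn") cat("k =", x$fit$k, "\n")
  invisible(x)
}

#' Threshold probabilities into class labels
#'
#' @param probabilities numeric vector in `[0, 1]`.
#' @param threshold decision threshold; label 1 iff `p >= threshold`
#'   (boundary inclusive). Default 0.5.
#' @return integer 0/1 vector.
#' @export
classify <- function(probabilities, threshold = 0.5) {
  stopifnot(all(probabilities >= 0 & probabilities <= 1))
  as.integer(probabilities >= threshold)
}

#' Convert a probability to odds
#'
#' `p / (1 - p)`; e.g. a classification probability of 0.88 corresponds
#' to odds 7.33.
#'
#' @param p probability in `[0, 1)`.
#' @return odds value.
#' @export
odds <- function(p) {
  stopifnot(all(p >= 0), all(p <= 1))
  if (any(p == 1)) stop("odds are infinite at p = 1", call. = FALSE)
  p / (1 - p)
}

#' Save / load a trained model as JSON
#'
#' `nb` and `lr` models serialize their parameters; `knn` serializes
#' the memorized training matrix inline.
#'
#' @param model an `sc_model`.
#' @param path file path.
#' @return `write_model`: the path, invisibly. `read_model`: an
#'   `sc_model`.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(
    list(kind = model$kind, n_features = model$n_features,
         fit = model$fit),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  fit <- obj$fit
  if (obj$kind == "nb") {
    fit$classes <- as.integer(fit$classes)
    fit$stats <- lapply(fit$stats, function(st) {
      list(mean = unlist(st$mean), var = unlist(st$var))
    })
  } else if (obj$kind == "knn") {
    fit$x <- as.matrix(fit$x)
    fit$y <- as.integer(fit$y)
    fit$k <- as.integer(fit$k)
  } else if (obj$kind == "lr") {
    fit$coef <- unlist(fit$coef)
  }
  structure(list(kind = obj$kind, fit = fit,
                 n_features = as.integer(obj$n_features)),
            class = "sc_model")
}
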