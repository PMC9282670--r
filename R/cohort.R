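#' Simulate a virtual respondent cohort
#'
#' Draws `n` latent abilities from Normal(`ability_mean`, `ability_sd`)
#' (logits), samples every respondent's category score on every bank
#' item from the partial credit model at their true ability, and
#' assigns the binary cancer label by thresholding the TRUE ability at
#' `cutoff`: label 1 (cancer) iff `theta >= cutoff`. The default
#' configuration — 1000 respondents, standard-normal abilities, cutoff
#' 0.88 logits — matches the calibrated risk scale's suggested
#' screening cut point and yields roughly 19% positives.
#'
#' @param bank an [item_bank()].
#' @param n cohort size (default 1000).
#' @param ability_mean,ability_sd latent ability distribution (logits);
#'   defaults 0 and 1.
#' @param cutoff label threshold in logits (default 0.88). Boundary is
#'   inclusive: a respondent exactly at the cutoff is labeled 1.
#' @param seed integer seed; the cohort is fully reproducible per seed.
#' @return an object of class `sc_cohort`: list with `responses`
#'   (n x items integer matrix, columns `item_1..item_N`), `theta`
#'   (true abilities), `labels` (0/1), `ids`, and the generating
#'   configuration in `config`.
#' @export
generate_cohort <- function(bank, n = 1000L, ability_mean = 0,
                            ability_sd = 1, cutoff = 0.88, seed = 1L) {
  stopifnot(n >= 2L, ability_sd > 0)
  set.seed(seed)
  theta <- stats::rnorm(n, mean = ability_mean, sd = ability_sd)
  m <- n_items(bank)
  responses <- matrix(0L, nrow = n, ncol = m,
                      dimnames = list(NULL, paste0("item_", bank$items$item_id)))
  for (j in seq_len(m)) {
    itm <- item_params(bank, bank$items$item_id[j])
    for (i in seq_len(n)) {
      responses[i, j] <- pcm_sample(theta[i], itm)
    }
  }
  structure(
    list(
      responses = responses,
      theta = theta,
      labels = as.integer(theta >= cutoff),
      ids = seq_len(n),
      config = list(n = n, ability_mean = ability_mean,
                    ability_sd = ability_sd, cutoff = cutoff, seed = seed)
    ),
    class = "sc_cohort"
  )
}

#' @export
print.sc_cohort <- function(x, ...) {
  cat("Simulated cohort: ", length(x$ids), " respondents x ",
      ncol(x$responses), " items; ", sum(x$labels), " positive labels (",
      sprintf("%.1f", 100 * mean(x$labels)), "%)\n", sep = "")
  invisible(x)
}

subset_cohort <- function(cohort, idx) {
  structure(
    list(responses = cohort$responses[idx, , drop = FALSE],
         theta = cohort$theta[idx],
         labels = cohort$labels[idx],
         ids = cohort$ids[idx],
         config = cohort$config),
    class = "sc_cohort"
  )
}

#' Hold-out train/test split
#'
#' Seeded uniform shuffle into disjoint, exhaustive train and test
#' subsets; train size is `round(n * train_fraction)`. Unstratified:
#' the validation design is a plain 70:30 split.
#'
#' @param cohort an `sc_cohort`.
#' @param train_fraction proportion in (0,1), default 0.7.
#' @param seed integer seed for the shuffle.
#' @return list with `train` and `test` cohorts.
#' @export
split_holdout <- function(cohort, train_fraction = 0.7, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- length(cohort$ids)
  n_train <- round(n * train_fraction)
  if (n_train < 1L || n_train >= n) {
    stop("degenerate split: ", n_train, " training rows of ", n,
         call. = FALSE)
  }
  set.seed(seed)
  perm <- sample.int(n)
  list(train = subset_cohort(cohort, sort(perm[seq_len(n_train)])),
       test = subset_cohort(cohort, sort(perm[(n_train + 1L):n])))
}

#' k-fold partition
#'
#' Assigns each respondent to exactly one test fold. Stratified by
#' label by default (fold assignment shuffled within each label group),
#' so per-fold prevalence tracks the cohort's.
#'
#' @param cohort an `sc_cohort`.
#' @param folds number of folds (default 10).
#' @param stratified stratify fold assignment by label (default TRUE).
#' @param seed integer seed.
#' @return list of `folds` elements, each a list with `train` and
#'   `test` cohorts.
#' @export
make_folds <- function(cohort, folds = 10L, stratified = TRUE, seed = 1L) {
  n <- length(cohort$ids)
  stopifnot(folds >= 2L)
  if (folds > n) stop("more folds than respondents", call. = FALSE)
  set.seed(seed)
  assignment <- integer(n)
  if (stratified) {
    for (lab in unique(cohort$labels)) {
      idx <- which(cohort$labels == lab)
      assignment[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  } else {
    assignment <- sample(rep_len(seq_len(folds), n))
  }
  lapply(seq_len(folds), function(f) {
    list(train = subset_cohort(cohort, which(assignment != f)),
         test = subset_cohort(cohort, which(assignment == f)))
  })
}

#' Write / read a cohort as CSV
#'
#' Lossless round-trip of responses, true abilities and labels.
#' Columns: `id`, `theta`, `label`, `item_1..item_N`.
#'
#' @param cohort an `sc_cohort`.
#' @param path file path.
#' @return `write_cohort`: the path, invisibly. `read_cohort`: an
#'   `sc_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  df <- data.frame(id = cohort$ids, theta = cohort$theta,
                   label = cohort$labels)
  df <- cbind(df, as.data.frame(cohort$responses))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path)
  for (col in c("id", "theta", "label")) {
    if (!col %in% names(df)) {
      stop("cohort file ", path, " is missing column '", col, "'",
           call. = FALSE)
    }
  }
  item_cols <- grep("^item_", names(df), value = TRUE)
  responses <- as.matrix(df[, item_cols, drop = FALSE])
  storage.mode(responses) <- "integer"
  structure(
    list(responses = responses, theta = df$theta,
         labels = as.integer(df$label), ids = df$id, config = list()),
    class = "sc_cohort"
  )
}
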