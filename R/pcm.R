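#' Partial credit model category probabilities
#'
#' Under the Rasch partial credit model (PCM), the probability that a
#' person at ability `theta` (logits) scores category `k` of item `i`
#' with effective category thresholds `delta_1..delta_K` is
#' \deqn{P(X=k \mid \theta) = \frac{\exp \sum_{j \le k} (\theta - \delta_j)}
#'   {\sum_{h=0}^{K} \exp \sum_{j \le h} (\theta - \delta_j)}}
#' with the empty sum equal to 0 for `k = 0`. Categories are scored
#' `0..K`; all items share unit discrimination. Computation uses
#' log-sum-exp stabilization, so extreme abilities (|theta| up to ~40)
#' do not overflow.
#'
#' @param theta person ability in logits (finite scalar).
#' @param item an item parameter list from [item_params()], or anything
#'   with a `thresholds` component.
#' @return numeric vector of length `K + 1` with the category
#'   probabilities for scores `0..K`; sums to 1.
#' @export
pcm_probs <- function(theta, item) {
  if (!is.finite(theta)) stop("theta must be finite", call. = FALSE)
  delta <- item$thresholds
  # cumulative log-numerators: 0, theta-d1, (theta-d1)+(theta-d2), ...
  lognum <- c(0, cumsum(theta - delta))
  lognum <- lognum - max(lognum)
  p <- exp(lognum)
  p / sum(p)
}

#' Expected item score under the PCM
#'
#' The model-expected score \eqn{E = \sum_k k P(X=k \mid \theta)},
#' strictly increasing in `theta` with range `(0, K)`. This is the
#' value imputed for unanswered items when an adaptive test stops.
#'
#' @inheritParams pcm_probs
#' @return scalar expected score.
#' @export
pcm_expected <- function(theta, item) {
  p <- pcm_probs(theta, item)
  sum((seq_along(p) - 1) * p)
}

#' Item information under the PCM
#'
#' The Fisher information an item contributes at ability `theta`: the
#' conditional variance of the item score,
#' \eqn{\mathrm{Var}(X \mid \theta) = E[X^2] - E[X]^2}, which equals
#' the first derivative of the expected score with respect to `theta`.
#' Always strictly positive; it peaks where the item is best targeted.
#'
#' @inheritParams pcm_probs
#' @return scalar information (score variance).
#' @export
pcm_information <- function(theta, item) {
  p <- pcm_probs(theta, item)
  k <- seq_along(p) - 1
  ex <- sum(k * p)
  sum(k^2 * p) - ex^2
}

#' Sample item responses under the PCM
#'
#' Draws category scores from the PCM category distribution at `theta`.
#' Randomness comes from R's global stream: callers seed with
#' `set.seed()` (or pass `seed` to the higher-level simulators) for
#' reproducibility.
#'
#' @inheritParams pcm_probs
#' @param n number of draws.
#' @return integer vector of category scores in `0..K`.
#' @export
pcm_sample <- function(theta, item, n = 1L) {
  p <- pcm_probs(theta, item)
  sample.int(length(p), size = n, replace = TRUE, prob = p) - 1L
}
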