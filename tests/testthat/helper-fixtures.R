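# In-code fixtures shared across test files.

# a bare item parameter list (what item_params() returns), enough for
# the pcm_* functions
mk_item <- function(overall, steps, id = 1L) {
  list(item_id = id, text = paste0("item ", id),
       overall_difficulty = overall, steps = steps,
       thresholds = overall + steps, n_categories = length(steps) + 1L)
}

# small all-dichotomous bank from a vector of overall difficulties
mk_dichotomous_bank <- function(deltas, name = "toy") {
  items <- data.frame(item_id = seq_along(deltas),
                      text = paste("toy item", seq_along(deltas)),
                      overall_difficulty = deltas,
                      step1 = 0, step2 = NA_real_, step3 = NA_real_,
                      step4 = NA_real_)
  item_bank(items, name = name)
}

# independent PCM oracle: direct evaluation of the category-probability
# numerators, no log-sum-exp, no shared code with pcm_probs()
oracle_pcm_probs <- function(theta, thresholds) {
  K <- length(thresholds)
  numerators <- numeric(K + 1)
  numerators[1] <- exp(0)
  for (k in seq_len(K)) {
    numerators[k + 1] <- exp(sum(theta - thresholds[seq_len(k)]))
  }
  numerators / sum(numerators)
}

the_bank <- skin_item_bank()

# round-half-up to `digits` decimals (the convention of the printed
# tables; base round() rounds half to even)
round_half_up <- function(x, digits = 2) floor(x * 10^digits + 0.5) / 10^digits
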