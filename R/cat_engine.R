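#' Standard error of measurement
#'
#' The classical-test-theory SEM, `SD * sqrt(1 - reliability)`, used as
#' the adaptive test's precision target: the test stops once the CAT
#' standard error falls below it. With SD 1.0 logits and Cronbach's
#' alpha .78 the SEM is 0.469, the default stopping threshold.
#'
#' @param sd scale standard deviation in logits.
#' @param reliability reliability coefficient (Cronbach's alpha),
#'   strictly between 0 and 1.
#' @return SEM in logits.
#' @export
sem <- function(sd = 1, reliability = 0.78) {
  stopifnot(reliability > 0, reliability < 1, sd > 0)
  sd * sqrt(1 - reliability)
}

#' Stopping rule for the adaptive test
#'
#' The test stops when any of: (1) the CAT standard error drops below
#' `sem_threshold`; (2) at least `min_items` have been administered and
#' the last ability update moved less than `theta_residual_tol`;
#' (3) the bank is exhausted (`max_items` administered).
#'
#' @param sem_threshold SE threshold in logits. Default 0.469
#'   (= `sem(1, 0.78)`). If `NULL`, derived from `sd` and `reliability`.
#' @param reliability,sd used to derive the threshold when
#'   `sem_threshold` is `NULL`.
#' @param theta_residual_tol convergence tolerance on consecutive
#'   ability estimates (logits), default 0.05.
#' @param min_items minimum items before the convergence stop can fire.
#' @param max_items maximum items (default `Inf`, i.e. the bank size).
#' @return an object of class `stop_rule`.
#' @export
stop_rule <- function(sem_threshold = 0.469, reliability = 0.78, sd = 1,
                      theta_residual_tol = 0.05, min_items = 5L,
                      max_items = Inf) {
  if (is.null(sem_threshold)) sem_threshold <- sem(sd, reliability)
  stopifnot(sem_threshold > 0, theta_residual_tol >= 0, min_items >= 1L)
  structure(
    list(sem_threshold = sem_threshold, reliability = reliability,
         sd = sd, theta_residual_tol = theta_residual_tol,
         min_items = as.integer(min_items), max_items = max_items),
    class = "stop_rule"
  )
}

#' Newton-Raphson ability update
#'
#' One step of the maximum-likelihood score equation for the person
#' ability given the administered items:
#' \deqn{\theta_{m+1} = \theta_m + \frac{\sum_i (O_i - E_i(\theta_m))}
#'   {\sum_i \mathrm{Var}_i(\theta_m)}}
#' where `O` are observed category scores and `E` and `Var` the PCM
#' expected score and information at the current estimate. The raw step
#' diverges on all-minimum or all-maximum response patterns, so the
#' step magnitude is capped (default 1 logit) and the result clamped to
#' `[-6, 6]`; pass `step_cap = Inf, clamp = c(-Inf, Inf)` for the raw
#' formula.
#'
#' @param theta current ability estimate (logits).
#' @param items list of item parameter lists ([item_params()]).
#' @param observed numeric vector of observed scores, same length.
#' @param step_cap maximum |update| in logits (default 1).
#' @param clamp length-2 ability bounds (default `c(-6, 6)`).
#' @return updated ability estimate.
#' @export
theta_update <- function(theta, items, observed, step_cap = 1,
                         clamp = c(-6, 6)) {
  stopifnot(length(items) == length(observed), length(items) >= 1L)
  resid <- 0
  info <- 0
  for (i in seq_along(items)) {
    resid <- resid + (observed[i] - pcm_expected(theta, items[[i]]))
    info <- info + pcm_information(theta, items[[i]])
  }
  step <- resid / info
  if (is.finite(step_cap)) step <- sign(step) * min(abs(step), step_cap)
  min(max(theta + step, clamp[1]), clamp[2])
}

# iterate theta_update to a fixed point (used for the final estimate)
theta_converge <- function(theta, items, observed, tol = 1e-6,
                           max_iter = 100L) {
  for (it in seq_len(max_iter)) {
    new_theta <- theta_update(theta, items, observed)
    if (abs(new_theta - theta) < tol) return(new_theta)
    theta <- new_theta
  }
  theta
}

#' CAT standard error
#'
#' `1 / sqrt(sum of item information)` at the current ability over the
#' administered items; monotone non-increasing as items accrue at a
#' fixed ability.
#'
#' @param theta ability estimate (logits).
#' @param items list of administered item parameter lists.
#' @return standard error in logits.
#' @export
cat_standard_error <- function(theta, items) {
  stopifnot(length(items) >= 1L)
  info <- sum(vapply(items, function(it) pcm_information(theta, it),
                     numeric(1)))
  1 / sqrt(info)
}

#' Maximum-information item selection
#'
#' Returns the id of the unadministered item with the largest Fisher
#' information at the current ability estimate; ties go to the lowest
#' item id.
#'
#' @param bank an [item_bank()].
#' @param theta current ability estimate.
#' @param administered integer vector of already-administered item ids.
#' @return selected item id.
#' @export
select_next_item <- function(bank, theta, administered = integer(0)) {
  remaining <- setdiff(bank$items$item_id, administered)
  if (length(remaining) == 0L) stop("item bank exhausted", call. = FALSE)
  info <- vapply(remaining, function(id) {
    pcm_information(theta, item_params(bank, id))
  }, numeric(1))
  remaining[which.max(info)]
}

should_stop_ <- function(se, theta_traj, n_administered, n_bank, rule) {
  if (se < rule$sem_threshold) return("sem_reached")
  if (n_administered >= rule$min_items && length(theta_traj) >= 2L) {
    resid <- abs(theta_traj[length(theta_traj)] -
                 theta_traj[length(theta_traj) - 1L])
    if (resid < rule$theta_residual_tol) return("theta_converged")
  }
  if (n_administered >= min(rule$max_items, n_bank)) {
    return("items_exhausted")
  }
  NULL
}

#' Responders for simulated and replayed adaptive tests
#'
#' A responder is a function `(item_params) -> category score` supplied
#' to [run_cat()]. `responder_theta` answers probabilistically from a
#' true latent ability via the PCM; `responder_replay` answers from a
#' fixed full response vector indexed by item id.
#'
#' @param theta true latent ability (logits).
#' @return a responder function.
#' @export
responder_theta <- function(theta) {
  force(theta)
  function(item) pcm_sample(theta, item)
}

#' @rdname responder_theta
#' @param responses integer vector of category scores, one per bank
#'   item, indexed by item id.
#' @export
responder_replay <- function(responses) {
  force(responses)
  function(item) responses[item$item_id]
}

#' Run one adaptive test
#'
#' The adaptive loop: start at an initial ability of 0 with a uniformly
#' random (seeded) first item; then repeatedly collect the response,
#' apply one Newton-Raphson ability update, check the stopping rule,
#' and administer the most informative remaining item. On stopping, the
#' final ability is iterated to convergence, unanswered items are
#' imputed with their model-expected scores at that ability, and
#' person-fit statistics are computed.
#'
#' @param bank an [item_bank()].
#' @param responder a function `(item_params) -> category` (see
#'   [responder_theta()], [responder_replay()]), or a single numeric
#'   taken as a true ability, or an integer vector of length
#'   `n_items(bank)` replayed as fixed responses.
#' @param rule a [stop_rule()].
#' @param seed integer seed covering the first-item draw and any
#'   simulated responses.
#' @param initial_theta starting ability (default 0 logits).
#' @return an object of class `cat_session`: administered item ids and
#'   observed scores, per-step ability and SE trajectories,
#'   `final_theta`, `final_se`, the imputed full response vector,
#'   `stopped_because`, and a `fit` report (see [fit_statistics()]).
#' @export
run_cat <- function(bank, responder, rule = stop_rule(), seed = 1L,
                    initial_theta = 0) {
  if (is.numeric(responder) && length(responder) == 1L) {
    responder <- responder_theta(responder)
  } else if (is.numeric(responder)) {
    if (length(responder) != n_items(bank)) {
      stop("replay vector must have one response per bank item",
           call. = FALSE)
    }
    responder <- responder_replay(responder)
  }
  set.seed(seed)
  n_bank <- n_items(bank)
  administered <- integer(0)
  observed <- numeric(0)
  items <- list()
  theta_traj <- numeric(0)
  se_traj <- numeric(0)
  theta <- initial_theta
  next_id <- sample(bank$items$item_id, 1L)
  reason <- NULL
  repeat {
    itm <- item_params(bank, next_id)
    resp <- responder(itm)
    if (!is.numeric(resp) || length(resp) != 1L || is.na(resp) ||
        resp < 0 || resp > itm$n_categories - 1L) {
      stop("responder returned an out-of-range category for item ",
           next_id, call. = FALSE)
    }
    administered <- c(administered, next_id)
    observed <- c(observed, resp)
    items <- c(items, list(itm))
    theta <- theta_update(theta, items, observed)
    theta_traj <- c(theta_traj, theta)
    se_traj <- c(se_traj, cat_standard_error(theta, items))
    reason <- should_stop_(se_traj[length(se_traj)], theta_traj,
                           length(administered), n_bank, rule)
    if (!is.null(reason)) break
    next_id <- select_next_item(bank, theta, administered)
  }
  final_theta <- theta_converge(theta, items, observed)
  final_se <- cat_standard_error(final_theta, items)
  session <- structure(
    list(bank = bank, administered = administered, observed = observed,
         theta_trajectory = theta_traj, se_trajectory = se_traj,
         final_theta = final_theta, final_se = final_se,
         stopped_because = reason, rule = rule, seed = seed),
    class = "cat_session"
  )
  session$imputed <- impute_unanswered(session)
  session$fit <- fit_statistics(session)
  session
}

#' @export
print.cat_session <- function(x, ...) {
  n_adm <- length(x$administered)
  n_bank <- n_items(x$bank)
  cat("CAT session: ", n_adm, " of ", n_bank, " items administered (",
      sprintf("%.0f", 100 * (n_bank - n_adm) / n_bank),
      "% saved); stopped: ", x$stopped_because, "\n", sep = "")
  cat("Final ability: ", sprintf("%.2f", x$final_theta), " logits (SE ",
      sprintf("%.3f", x$final_se), ")\n", sep = "")
  if (!is.null(x$fit)) {
    cat("Person fit: infit ", sprintf("%.2f", x$fit$infit_mnsq),
        ", outfit ", sprintf("%.2f", x$fit$outfit_mnsq),
        if (isTRUE(x$fit$aberrant)) "  ** aberrant (outfit > 2.0) **",
        "\n", sep = "")
  }
  invisible(x)
}

#' Impute unanswered items with expected scores
#'
#' Builds the complete feature vector a classifier needs: administered
#' positions keep the observed category score; every unanswered item
#' gets its PCM expected score at the session's final ability (a real
#' value, not a rounded category).
#'
#' @param session a `cat_session`.
#' @return numeric vector of length `n_items(bank)`, named
#'   `item_1..item_N`.
#' @export
impute_unanswered <- function(session) {
  bank <- session$bank
  out <- vapply(bank$items$item_id, function(id) {
    pos <- match(id, session$administered)
    if (!is.na(pos)) session$observed[pos]
    else pcm_expected(session$final_theta, item_params(bank, id))
  }, numeric(1))
  names(out) <- paste0("item_", bank$items$item_id)
  out
}

#' Person-fit statistics for a CAT session
#'
#' Standardized residuals and mean-square fit statistics over the
#' administered items, evaluated at the final ability:
#' `Z_i = (O_i - E_i) / sqrt(Var_i)`; outfit MNSQ is the unweighted
#' mean of `Z^2`; infit MNSQ is the information-weighted version
#' `sum((O-E)^2) / sum(Var)`. The degrees-of-freedom-adjusted mean
#' square is `v = outfit * n / (n - 1)` with `df = n - 1`, and the
#' `t` statistic is `ln(v) + v - 1` (approximately standard normal; a
#' Wilson-Hilferty cube-root variant is available via
#' `wilson_hilferty = TRUE`). Outfit above 2.0 flags an aberrant
#' response pattern.
#'
#' @param session a `cat_session` with at least 2 administered items,
#'   or a list with components `observed`, `expected`, `variance`.
#' @param wilson_hilferty use the cube-root normalizing transform for
#'   `t` instead of the direct `ln(v) + v - 1` form.
#' @return list with `infit_mnsq`, `outfit_mnsq`, `z_scores`, `v`,
#'   `t_statistic`, `df`, `aberrant`.
#' @export
fit_statistics <- function(session, wilson_hilferty = FALSE) {
  if (inherits(session, "cat_session")) {
    items <- lapply(session$administered,
                    function(id) item_params(session$bank, id))
    observed <- session$observed
    theta <- session$final_theta
    expected <- vapply(items, function(it) pcm_expected(theta, it),
                       numeric(1))
    variance <- vapply(items, function(it) pcm_information(theta, it),
                       numeric(1))
  } else {
    observed <- session$observed
    expected <- session$expected
    variance <- session$variance
  }
  n <- length(observed)
  if (n < 2L) stop("fit statistics need at least 2 items", call. = FALSE)
  z <- (observed - expected) / sqrt(variance)
  outfit <- mean(z^2)
  infit <- sum((observed - expected)^2) / sum(variance)
  df <- n - 1L
  v <- outfit * n / df
  t_stat <- if (wilson_hilferty) {
    (v^(1 / 3) - 1) * 3 / sqrt(2 / df) + sqrt(2 / df) / 3
  } else {
    log(v) + v - 1
  }
  list(infit_mnsq = infit, outfit_mnsq = outfit, z_scores = z,
       v = v, t_statistic = t_stat, df = df, aberrant = outfit > 2.0)
}

#' Convergence diagnostic on the ability trajectory
#'
#' Correlation between the last `k` provisional ability estimates and
#' their step numbers; values near 0 indicate a flat trajectory, i.e. a
#' converged estimate. Diagnostic only — it is not part of the stopping
#' rule.
#'
#' @param session a `cat_session`.
#' @param k number of trailing estimates to use (default 5).
#' @return correlation coefficient, or `NA` if fewer than `k` steps or
#'   the trailing estimates are constant.
#' @export
theta_trend <- function(session, k = 5L) {
  traj <- session$theta_trajectory
  if (length(traj) < k) return(NA_real_)
  tail_traj <- traj[(length(traj) - k + 1L):length(traj)]
  if (stats::sd(tail_traj) == 0) return(NA_real_)
  stats::cor(tail_traj, seq_len(k))
}
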