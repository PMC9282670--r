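test_that("SEM formula and stop-rule derivation agree", {
  expect_equal(sem(1, 0.78), sqrt(1 - 0.78))
  rule <- stop_rule(sem_threshold = NULL, reliability = 0.78, sd = 1)
  expect_equal(rule$sem_threshold, sem(1, 0.78))
})

test_that("Newton update reproduces forced arithmetic and fixed points", {
  itm <- mk_item(0, 0)
  # raw formula: theta 0, O = 1 -> 0 + (1 - 0.5)/0.25 = 2
  expect_equal(theta_update(0, list(itm), 1, step_cap = Inf,
                            clamp = c(-Inf, Inf)), 2)
  # capped default limits the step to 1 logit
  expect_equal(theta_update(0, list(itm), 1), 1)
  # real-valued probe with O = E: update of exactly 0
  e <- pcm_expected(0.7, itm)
  expect_equal(theta_update(0.7, list(itm), e, step_cap = Inf,
                            clamp = c(-Inf, Inf)), 0.7)
  # clamp on a perfect pattern
  items <- lapply(c(0, 0.5, -0.3), mk_item, steps = 0)
  th <- 0
  for (i in 1:20) th <- theta_update(th, items, c(1, 1, 1))
  expect_lte(th, 6)
})

test_that("iterated updates solve the score equation found by grid search", {
  ids <- c(2, 5, 9, 13, 17)
  items <- lapply(ids, function(id) item_params(the_bank, id))
  observed <- c(2, 1, 0, 3, 1)
  th <- 0
  for (i in 1:200) th <- theta_update(th, items, observed)
  # oracle: fine grid search for the root of sum(O - E) = 0
  grid <- seq(-6, 6, by = 1e-4)
  score <- vapply(grid, function(g) {
    sum(observed - vapply(items, function(it) pcm_expected(g, it),
                          numeric(1)))
  }, numeric(1))
  root <- grid[which.min(abs(score))]
  expect_equal(th, root, tolerance = 1e-3)
})

test_that("standard error follows 1/sqrt(information) and shrinks", {
  items <- lapply(c(1, 3, 5), function(id) item_params(the_bank, id))
  total_info <- sum(vapply(items, function(it) pcm_information(0.2, it),
                           numeric(1)))
  expect_equal(cat_standard_error(0.2, items), 1 / sqrt(total_info))
  # total information 4 -> SE 0.5 (forced via identical dichotomous items)
  four <- rep(list(mk_item(0, 0)), 16)  # 16 x 0.25 = 4
  expect_equal(cat_standard_error(0, four), 0.5)
  # adding an item strictly decreases SE at fixed theta
  expect_lt(cat_standard_error(0.2, c(items, list(mk_item(1, 0)))),
            cat_standard_error(0.2, items))
  # SE below 0.469 once information exceeds 1/0.469^2
  expect_lt(cat_standard_error(0, rep(list(mk_item(0, 0)), 19)), 0.469)
  expect_gt(cat_standard_error(0, rep(list(mk_item(0, 0)), 18)), 0.469)
})

test_that("item selection is the exhaustive information argmax", {
  bank2 <- mk_dichotomous_bank(c(0, 3))
  expect_equal(select_next_item(bank2, 0), 1L)
  set.seed(21)
  for (rep in 1:10) {
    theta <- rnorm(1)
    administered <- sample(1:30, sample(1:28, 1))
    pick <- select_next_item(the_bank, theta, administered)
    expect_false(pick %in% administered)
    remaining <- setdiff(1:30, administered)
    info <- vapply(remaining, function(id) {
      pcm_information(theta, item_params(the_bank, id))
    }, numeric(1))
    expect_equal(pick, remaining[which.max(info)])
  }
  expect_error(select_next_item(the_bank, 0, 1:30), "exhausted")
})

test_that("stopping rule fires for each reason with correct precedence", {
  rule <- stop_rule()
  expect_equal(sccat:::should_stop_(0.45, c(1, 1), 2, 30, rule),
               "sem_reached")
  expect_equal(sccat:::should_stop_(0.60, c(1.00, 1.01), 6, 30, rule),
               "theta_converged")
  # convergence stop needs min_items
  expect_null(sccat:::should_stop_(0.60, c(1.00, 1.01), 4, 30, rule))
  expect_equal(sccat:::should_stop_(0.60, c(1, 2), 30, 30, rule),
               "items_exhausted")
})

test_that("a full CAT run stops per rule, is seeded, and imputes", {
  s <- run_cat(the_bank, responder = 1.0, seed = 3)
  expect_true(s$stopped_because %in%
                c("sem_reached", "theta_converged", "items_exhausted"))
  if (s$stopped_because == "sem_reached") {
    expect_lt(s$se_trajectory[length(s$se_trajectory)], 0.469)
  }
  expect_false(anyDuplicated(s$administered) > 0)
  expect_equal(length(s$theta_trajectory), length(s$administered))
  expect_equal(s$final_se,
               cat_standard_error(s$final_theta,
                 lapply(s$administered,
                        function(id) item_params(the_bank, id))))
  # determinism
  s2 <- run_cat(the_bank, responder = 1.0, seed = 3)
  expect_identical(s$administered, s2$administered)
  expect_identical(s$observed, s2$observed)
  expect_equal(s$final_theta, s2$final_theta)

  # imputation: administered keep observations, others = expected score
  imp <- s$imputed
  for (j in 1:30) {
    pos <- match(j, s$administered)
    target <- if (!is.na(pos)) s$observed[pos] else
      pcm_expected(s$final_theta, item_params(the_bank, j))
    expect_equal(unname(imp[j]), target)
  }
  expect_error(run_cat(the_bank, responder = function(item) 99, seed = 1),
               "out-of-range")
})

test_that("replaying a full response vector answers every item the same", {
  set.seed(6)
  responses <- vapply(1:30, function(j) {
    pcm_sample(0.5, item_params(the_bank, j))
  }, integer(1))
  s <- run_cat(the_bank, responder = responses, seed = 2,
               rule = stop_rule(sem_threshold = 1e-6,
                                theta_residual_tol = 0))
  expect_equal(s$stopped_because, "items_exhausted")
  expect_equal(length(s$administered), 30L)
  # all answered: imputed vector equals the observations, bank order
  expect_equal(unname(s$imputed), as.numeric(responses))
})

test_that("fit statistics reproduce hand arithmetic and flag misfit", {
  # uniform residual pattern forcing outfit exactly 0.52 over 9 items
  z2 <- 0.52
  probe <- list(observed = rep(sqrt(z2), 9), expected = rep(0, 9),
                variance = rep(1, 9))
  fr <- fit_statistics(probe)
  expect_equal(fr$outfit_mnsq, 0.52)
  expect_equal(fr$v, 0.52 * 9 / 8)
  expect_equal(fr$t_statistic, log(0.585) + 0.585 - 1)
  expect_equal(round(fr$t_statistic, 2), -0.95)
  expect_equal(fr$df, 8L)
  expect_false(fr$aberrant)

  # zero residuals: both mean squares 0
  zero <- fit_statistics(list(observed = c(0.4, 1.1), expected = c(0.4, 1.1),
                              variance = c(0.2, 0.3)))
  expect_equal(zero$outfit_mnsq, 0)
  expect_equal(zero$infit_mnsq, 0)

  # brute-force oracle on a real session
  s <- run_cat(the_bank, responder = -0.5, seed = 10)
  items <- lapply(s$administered, function(id) item_params(the_bank, id))
  z <- e <- v <- numeric(length(items))
  for (i in seq_along(items)) {
    e[i] <- pcm_expected(s$final_theta, items[[i]])
    v[i] <- pcm_information(s$final_theta, items[[i]])
    z[i] <- (s$observed[i] - e[i]) / sqrt(v[i])
  }
  expect_equal(s$fit$outfit_mnsq, mean(z^2))
  expect_equal(s$fit$infit_mnsq, sum((s$observed - e)^2) / sum(v))
  expect_equal(s$fit$z_scores, z)

  # outfit > 2 flags an aberrant pattern
  wild <- fit_statistics(list(observed = rep(3, 5), expected = rep(0, 5),
                              variance = rep(1, 5)))
  expect_true(wild$aberrant)
})

test_that("CAT is efficient and recovers abilities across respondents", {
  set.seed(11)
  thetas <- rnorm(200)
  est <- n_used <- numeric(200)
  for (i in 1:200) {
    s <- run_cat(the_bank, responder = thetas[i], seed = 5000 + i)
    est[i] <- s$final_theta
    n_used[i] <- length(s$administered)
  }
  expect_lt(mean(n_used), 30)
  expect_gte(cor(est, thetas), 0.85)
})

test_that("theta trajectory converges when replaying fixed responses", {
  set.seed(14)
  for (rep in 1:5) {
    responses <- vapply(1:30, function(j) {
      pcm_sample(rnorm(1), item_params(the_bank, j))
    }, integer(1))
    s <- run_cat(the_bank, responder = responses, seed = rep,
                 rule = stop_rule(sem_threshold = 1e-6,
                                  theta_residual_tol = 0))
    traj <- s$theta_trajectory
    late <- tail(abs(diff(traj)), 3)
    expect_lt(max(late), 1)  # no late oscillation beyond the step cap
    expect_false(is.na(theta_trend(s)))
  }
})
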