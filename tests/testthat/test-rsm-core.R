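test_that("category probabilities match independent enumeration", {
  # equal location, flat thresholds: all six categories equally likely
  expect_equal(category_probabilities(1.3, 1.3, rep(0, 5)), rep(1 / 6, 6))
  # dichotomous identity
  expect_equal(category_probabilities(0, 0, 0), c(0.5, 0.5))
  # m = 3, c - d = 1, F = (-0.5, 0.5): weights 1, e^1.5, e^2 normalized
  w <- c(1, exp(1.5), exp(2))
  expect_equal(category_probabilities(1, 0, c(-0.5, 0.5)), w / sum(w),
               tolerance = 1e-12)
  # general agreement with the enumeration oracle across locations
  for (th in c(-2, -0.3, 0.8)) {
    expect_equal(category_probabilities(th, 0, c(-0.74, -0.66, 0.60, 0.19, 0.61)),
                 enum_rsm_probs(th, c(-0.74, -0.66, 0.60, 0.19, 0.61)),
                 tolerance = 1e-12)
  }
})

test_that("expected score and variance obey the moment identities", {
  es <- expected_score(0, 0, 0)
  expect_equal(es$expected, 0.5)
  expect_equal(es$variance, 0.25)
  # moments recomputed from the probability vector itself
  F <- c(-0.5, 0.5)
  p <- category_probabilities(1, 0, F)
  es <- expected_score(1, 0, F)
  expect_equal(es$expected, sum((0:2) * p))
  expect_equal(es$variance, sum((0:2)^2 * p) - sum((0:2) * p)^2)
  expect_equal(es$m4, sum((0:2 - es$expected)^4 * p))
  # degenerate limit: huge positive location pins the top category
  es <- expected_score(40, 0, rep(0, 5))
  expect_equal(es$expected, 5, tolerance = 1e-6)
  expect_equal(es$variance, 0, tolerance = 1e-6)
})

test_that("JMLE recovers flat difficulties as zeros", {
  sim <- simulate_responses(sim_spec(2000, 10, 6,
                                     item_difficulties = rep(0, 10),
                                     seed = 42))
  fit <- fit_jmle(sim$responses)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$difficulty)), 0.1)
})

test_that("JMLE recovers a known difficulty grid and thresholds", {
  sim <- clean_sim(500, 20, seed = 101)
  fit <- fit_jmle(sim$responses)
  expect_true(fit$converged)
  expect_gt(cor(fit$difficulty, sim$truth$items$difficulty), 0.98)
  expect_lt(sqrt(mean((fit$thresholds - sim$truth$thresholds)^2)), 0.1)
  # identification constraints hold
  expect_lt(abs(mean(fit$difficulty[fit$active_items])), 1e-6)
  expect_lt(abs(sum(fit$thresholds)), 1e-6)
  expect_true(all(fit$se_difficulty > 0))
  expect_true(all(fit$se_measure[fit$active_persons] > 0))
})

test_that("dichotomous JMLE agrees with a brute-force grid maximizer", {
  set.seed(5)
  repeat {  # draw until no extreme rows/columns
    X <- matrix(rbinom(5 * 3, 1, 0.5), 5, 3)
    r <- rowSums(X); s <- colSums(X)
    if (all(r > 0 & r < 3) && all(s > 0 & s < 5)) break
  }
  oracle <- grid_jmle_dichotomous(X)
  fit <- fit_jmle(response_matrix(X + 1L, 2),
                  estimation_config(convergence_tol = 1e-6))
  expect_lt(max(abs(fit$difficulty - oracle$D)), 0.02)
  expect_lt(max(abs(fit$measure - oracle$C)), 0.02)
})

test_that("log-likelihood never decreases across accepted iterations", {
  sim <- clean_sim(150, 8, seed = 9)
  fit <- fit_jmle(sim$responses)
  expect_true(all(diff(fit$log$loglik) >= -1e-7))
})

test_that("equal raw scores with equal missingness get equal measures", {
  sim <- clean_sim(300, 10, seed = 55)
  fit <- fit_jmle(sim$responses)
  raw <- rowSums(sim$responses$X)
  act <- sim$responses$persons %in% fit$active_persons
  for (rv in unique(raw[act])) {
    ms <- fit$measure[act & raw == rv]
    if (length(ms) > 1) expect_lt(max(ms) - min(ms), 1e-6)
  }
})

test_that("estimation is invariant to person and item order", {
  sim <- clean_sim(200, 8, seed = 13)
  rm <- sim$responses
  fit <- fit_jmle(rm)
  perm_p <- sample(rm$persons)
  perm_i <- sample(rm$items)
  fit2 <- fit_jmle(subset_items(subset_persons(rm, perm_p), perm_i))
  expect_equal(fit2$difficulty[rm$items], fit$difficulty, tolerance = 1e-8)
  expect_equal(fit2$measure[rm$persons], fit$measure, tolerance = 1e-8)
})

test_that("extreme persons get finite extrapolated measures beyond the rest", {
  sim <- clean_sim(100, 8, seed = 33)
  X <- sim$responses$X
  X[1, ] <- 6L  # perfect
  X[2, ] <- 1L  # zero
  fit <- fit_jmle(response_matrix(X, 6))
  expect_true(all(c("P1", "P2") %in% fit$extreme_persons))
  expect_true(is.finite(fit$measure["P1"]))
  act <- setdiff(names(fit$measure), fit$extreme_persons)
  expect_gt(fit$measure["P1"], max(fit$measure[act]))
  expect_lt(fit$measure["P2"], min(fit$measure[act]))
  # extrapolated measure reproduces the one-dimensional adjusted-score solve
  d <- fit$difficulty[fit$active_items]
  byhand <- person_measures(X[1, fit$active_items, drop = FALSE], d,
                            fit$thresholds, adjustment = 0.3)
  expect_equal(unname(fit$measure["P1"]), byhand$measure, tolerance = 1e-6)
})

test_that("unobserved categories and degenerate matrices are rejected", {
  X <- matrix(c(1L, 2L, 2L, 1L, 1L, 2L, 2L, 1L), 4, 2)
  expect_error(fit_jmle(response_matrix(X, 6)), "collapse categories")
  expect_error(fit_jmle(response_matrix(matrix(1L, 1, 5), 6)),
               "at least 2 persons")
})

test_that("anchored person measures are monotone in the raw score", {
  sim <- clean_sim(80, 12, seed = 71)
  fit <- fit_jmle(sim$responses)
  d <- fit$difficulty
  # symmetric instrument: midpoint raw score maps to measure 0
  inst_d <- seq(-1, 1, length.out = 12)
  Fsym <- seq(-0.8, 0.8, length.out = 5)
  mid <- person_measures(matrix(rep(c(1L, 6L), 6), nrow = 1), inst_d,
                         Fsym - mean(Fsym))
  expect_equal(mid$measure, 0, tolerance = 1e-6)
  # strictly higher raw scores yield strictly higher measures
  pm <- person_measures(sim$responses, d, fit$thresholds)
  ord <- order(pm$raw)
  expect_true(all(diff(pm$measure[ord]) >= -1e-9))
  agg <- tapply(pm$measure, pm$raw, mean)
  expect_true(all(diff(agg[order(as.numeric(names(agg)))]) > 0))
  # all-missing person flagged undefined
  um <- person_measures(matrix(NA_integer_, 1, 12), inst_d, fit$thresholds)
  expect_false(um$defined)
})
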