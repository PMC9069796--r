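test_that("fit statistics center near 1 on clean model data", {
  sim <- clean_sim(2000, 20, seed = 201)
  fit <- fit_jmle(sim$responses)
  fr <- fit_statistics(sim$responses, fit)
  expect_gt(mean(fr$item$infit), 0.95)
  expect_lt(mean(fr$item$infit), 1.05)
  expect_true(all(fr$item$infit > 0 & fr$item$outfit > 0))
  # under the null, few items stray outside the conventional bounds
  frac_out <- mean(fr$item$infit < 0.5 | fr$item$infit > 1.5 |
                     fr$item$outfit < 0.5 | fr$item$outfit > 1.5)
  expect_lt(frac_out, 0.10)
})

test_that("infit numerator equals the raw squared residual sum (identity)", {
  sim <- clean_sim(300, 10, seed = 17)
  fit <- fit_jmle(sim$responses)
  fr <- fit_statistics(sim$responses, fit)
  obs <- !is.na(fr$Z)
  lhs <- sum((fr$W * fr$Z^2)[obs])
  x0 <- sim$responses$X - 1L
  rhs <- sum(((x0 - fr$E)^2)[obs])
  expect_equal(lhs, rhs, tolerance = 1e-8)
  # Z is zero exactly where the observation equals its expectation
  expect_identical(fr$Z == 0, (x0 - fr$E) == 0)
})

test_that("a noise item shows large outfit while clean items stay in bounds", {
  sim <- simulate_responses(sim_spec(1000, 20, 6,
                                     misfit = list(list(item = "I11", noise_rate = 1)),
                                     seed = 207))
  fit <- fit_jmle(sim$responses)
  fr <- fit_statistics(sim$responses, fit)
  expect_gt(fr$item$outfit[fr$item$item_id == "I11"], 1.5)
  clean <- fr$item[fr$item$item_id != "I11", ]
  expect_true(all(clean$infit > 0.5 & clean$infit < 1.5))
  expect_true(all(clean$outfit > 0.5 & clean$outfit < 1.5))
})

test_that("a constant responder is muted (person infit below 1)", {
  # constant mid-category responding is *less* variable than the model
  # expects when the items span a moderate difficulty range
  sim <- clean_sim(400, 15, seed = 219, difficulty_range = c(-0.5, 0.5))
  X <- sim$responses$X
  X[1, ] <- 3L
  fit <- fit_jmle(response_matrix(X, 6))
  fr <- fit_statistics(response_matrix(X, 6), fit)
  expect_lt(fr$person$infit[fr$person$person_id == "P1"], 1)
})

test_that("outfit is invariant to person ordering", {
  sim <- clean_sim(150, 8, seed = 23)
  fit <- fit_jmle(sim$responses)
  a <- fit_statistics(sim$responses, fit)$item$outfit
  perm <- sample(sim$responses$persons)
  rm2 <- subset_persons(sim$responses, perm)
  fit2 <- fit_jmle(rm2)
  b <- fit_statistics(rm2, fit2)$item$outfit
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("clean data survives removal untouched; noisy items are excised", {
  sim <- clean_sim(600, 15, seed = 231)
  res <- iterative_misfit_removal(sim$responses)
  expect_length(res$rounds, 1)
  expect_identical(res$retained, sim$responses$items)
  expect_length(res$removed, 0)

  noisy <- simulate_responses(sim_spec(1000, 20, 6,
                                       misfit = list(list(item = "I3", noise_rate = 0.8),
                                                     list(item = "I17", noise_rate = 0.8)),
                                       seed = 233))
  res <- iterative_misfit_removal(noisy$responses,
                                  removal_rule(mode = "either"))
  expect_setequal(res$removed, c("I3", "I17"))
  final <- res$report$item
  expect_true(all(final$infit >= 0.5 & final$infit <= 1.5))
  expect_true(all(final$outfit >= 0.5 & final$outfit <= 1.5))
  # audit trail: disjoint removals, terminal round has no removable flag
  all_removed <- unlist(lapply(res$rounds, `[[`, "removed"))
  expect_false(anyDuplicated(all_removed) > 0)
  expect_length(res$rounds[[length(res$rounds)]]$removed, 0)
})

test_that("exempt items are flagged in the log but retained", {
  noisy <- simulate_responses(sim_spec(800, 15, 6,
                                       misfit = list(list(item = "I5", noise_rate = 0.9)),
                                       seed = 239))
  res <- iterative_misfit_removal(noisy$responses,
                                  removal_rule(mode = "either", exempt = "I5"))
  expect_true("I5" %in% res$retained)
  expect_true("I5" %in% res$rounds[[1]]$flagged)
  expect_true("I5" %in% res$rounds[[1]]$exempt_retained)
  expect_length(res$removed, 0)
})

test_that("clean simulations pass the unidimensionality screen", {
  sim <- clean_sim(1000, 20, seed = 241)
  fit <- fit_jmle(sim$responses)
  rep <- pca_of_residuals(fit_statistics(sim$responses, fit))
  expect_lte(rep$first_contrast, 2.0)
  expect_true(rep$unidimensional)
  expect_true(rep$locally_independent)
  expect_true(all(diff(rep$eigenvalues) <= 1e-9))
  expect_true(all(rep$eigenvalues >= 0))
})

test_that("a second dimension on half the items trips the first contrast", {
  sim <- simulate_responses(sim_spec(1000, 20, 6,
                                     second_dimension = list(items = paste0("I", 1:10),
                                                             loading_sd = 1),
                                     seed = 247))
  fit <- fit_jmle(sim$responses)
  rep <- pca_of_residuals(fit_statistics(sim$responses, fit))
  expect_gt(rep$first_contrast, 2.0)
  expect_false(rep$unidimensional)
})

test_that("duplicated items violate local independence", {
  sim <- clean_sim(500, 10, seed = 251)
  X <- cbind(sim$responses$X, twin = sim$responses$X[, "I1"])
  colnames(X)[11] <- "I1twin"
  rm <- response_matrix(X, 6)
  fit <- fit_jmle(rm)
  rep <- pca_of_residuals(fit_statistics(rm, fit))
  expect_gt(rep$max_residual_correlation, 0.7)
  expect_false(rep$locally_independent)
  expect_true(any(rep$dependent_pairs$item_a == "I1" &
                    rep$dependent_pairs$item_b == "I1twin"))
})

test_that("category diagnostics summarize usage, measures and thresholds", {
  sim <- clean_sim(1000, 15, seed = 261)
  fit <- fit_jmle(sim$responses)
  cd <- rating_scale_diagnostics(sim$responses, fit)
  act_cells <- sum(!is.na(sim$responses$X[sim$responses$persons %in% fit$active_persons, ]))
  expect_equal(sum(cd$table$count), act_cells)
  expect_equal(sum(cd$table$percent), 100, tolerance = 0.01)
  # on clean data the average measures advance strictly with category
  expect_true(all(diff(cd$table$average_measure) > 0))
  expect_true(cd$criteria[["advancing_measures"]])
  expect_true(all(cd$table$outfit < 2))
  # curve samples are proper distributions along the grid
  expect_equal(unname(rowSums(cd$curves)), rep(1, length(cd$grid)),
               tolerance = 1e-9)
})

test_that("threshold ordering verdicts match the advancing-step rule", {
  expect_true(thresholds_ordered(c(-2, -1, 0, 1, 2)))
  disc <- thresholds_ordered(c(-0.74, -0.66, 0.60, 0.19, 0.61))
  expect_false(disc)
  expect_equal(attr(disc, "first_violation"), 4L)
})
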