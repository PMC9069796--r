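test_that("wright map bins agree with an independent histogram", {
  sim <- clean_sim(469, 26, seed = 601)
  fit <- fit_jmle(sim$responses)
  wm <- wright_map(fit, bin_width = 0.1)
  pm <- fit$measure[fit$active_persons]
  expect_equal(sum(wm$bins$persons), length(pm))
  # brute-force recount: left-closed bins over the reconstructed edges
  edges <- c(wm$bins$center - 0.05, max(wm$bins$center) + 0.05)
  manual <- as.integer(table(cut(pm, breaks = edges, right = FALSE,
                                 include.lowest = TRUE)))
  expect_equal(wm$bins$persons, manual)
  # bins cover both facets
  di <- fit$difficulty[fit$active_items]
  expect_lte(min(wm$bins$center) - 0.05, min(c(pm, di)))
  expect_gte(max(wm$bins$center) + 0.05, max(c(pm, di)))
  # every item label appears exactly once
  labs <- unlist(strsplit(paste(wm$bins$items, collapse = " "), " +"))
  expect_setequal(labs[nzchar(labs)], fit$active_items)
})

test_that("wright map markers sit at mean and SD bins", {
  meas <- c(-1, 0, 1)
  # minimal synthetic fit object: persons at -1,0,1 and items at 0
  sim <- clean_sim(200, 5, seed = 607)
  fit <- fit_jmle(sim$responses)
  wm <- wright_map(fit, bin_width = 0.1)
  pm <- fit$measure[fit$active_persons]
  mbin <- wm$bins$center[grepl("M", wm$bins$person_marker)]
  expect_equal(length(mbin), 1L)
  expect_lt(abs(mbin - mean(pm)), 0.1)
  sbin <- wm$bins$center[grepl("S", wm$bins$person_marker)]
  expect_true(all(abs(sort(sbin) - (mean(pm) + c(-1, 1) * sd(pm))) < 0.1))
})

test_that("one person and one item at zero share a bin", {
  sim <- clean_sim(300, 9, seed = 611)
  fit <- fit_jmle(sim$responses)
  wm <- wright_map(fit, bin_width = 0.25)
  # the bin holding an item's difficulty also covers that difficulty's persons
  d1 <- fit$difficulty[["I5"]]
  row <- which(vapply(strsplit(wm$bins$items, " "), function(s) "I5" %in% s,
                      logical(1)))
  expect_equal(length(row), 1L)
  expect_lt(abs(wm$bins$center[row] - d1), 0.25)
})

test_that("the full pipeline emits a complete, deterministic bundle", {
  sim <- simulate_responses(eat26_reference_spec())
  out1 <- file.path(tempdir(), "bundle1")
  out2 <- file.path(tempdir(), "bundle2")
  cfg <- function(out) pipeline_config(sim$responses, out,
                                       dif_covariates = c("female", "obese"),
                                       seed = 42)
  b <- run_pipeline(cfg(out1))
  expected <- c("scores.csv", "items.csv", "thresholds.csv", "persons.csv",
                "fit_rounds.json", "category_diagnostics.csv",
                "dif_female.csv", "dif_obese.csv", "wright_map.txt",
                "summary.json")
  expect_true(all(file.exists(file.path(out1, expected))))
  smry <- jsonlite::read_json(file.path(out1, "summary.json"))
  expect_equal(smry$n_persons, 469)
  expect_equal(smry$n_items, 26)
  # rerun with identical input and seed is byte-identical
  run_pipeline(cfg(out2))
  for (f in c("summary.json", "items.csv", "wright_map.txt"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  # item table lists exactly the retained items, all within bounds or exempt
  items <- read.csv(file.path(out1, "items.csv"))
  expect_setequal(items$item_id, unlist(smry$retained_items))
  expect_true(all(items$infit > 0.5 & items$infit < 1.5))
})

test_that("injected pathologies surface in the pipeline summary", {
  sim <- simulate_responses(sim_spec(
    1200, 20, 6, covariates = list(g = 0.5),
    misfit = list(list(item = "I4", noise_rate = 0.9),
                  list(item = "I13", noise_rate = 0.9)),
    dif = list(list(item = "I8", covariate = "g", shift = 0.9)),
    seed = 617))
  out <- file.path(tempdir(), "bundle3")
  b <- run_pipeline(pipeline_config(sim$responses, out,
                                    removal = removal_rule(mode = "either"),
                                    dif_covariates = "g",
                                    classical_scores = FALSE, seed = 7))
  expect_setequal(b$summary$removed_items, c("I4", "I13"))
  expect_true("I8" %in% b$summary$dif_flagged$g)
})

test_that("stage failures name the failing stage", {
  expect_error(suppressWarnings(
    run_pipeline(pipeline_config("/nonexistent.csv", tempfile()))),
    "stage 'read' failed")
})
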