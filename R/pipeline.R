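#' Configure the calibration pipeline
#'
#' @param input Path to a response CSV (read with [read_responses()]) or a
#'   [response_matrix()].
#' @param out_dir Output directory for the report bundle.
#' @param instrument The [instrument()] definition.
#' @param estimation An [estimation_config()].
#' @param removal A [removal_rule()].
#' @param dif_covariates Covariate names to run DIF on.
#' @param collapse Category treatment passed to [collapse_for_rasch()].
#' @param classical_scores Also compute and write the classical 0-3 scores
#'   (requires the matrix to be on the instrument's category scale).
#' @param bin_width Wright map bin width in logits.
#' @param seed Seed recorded in the summary and set before the run.
#' @param verbose Print stage progress.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input, out_dir,
                            instrument = eat26_instrument(),
                            estimation = estimation_config(),
                            removal = removal_rule(),
                            dif_covariates = character(),
                            collapse = c("six_category", "scored_four_category"),
                            classical_scores = TRUE,
                            bin_width = 0.1, seed = 1L, verbose = FALSE) {
  structure(list(input = input, out_dir = out_dir, instrument = instrument,
                 estimation = estimation, removal = removal,
                 dif_covariates = as.character(dif_covariates),
                 collapse = match.arg(collapse),
                 classical_scores = isTRUE(classical_scores),
                 bin_width = bin_width, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Run the full calibration pipeline
#'
#' Executes the six-step validation workflow end to end: read (or accept)
#' the response matrix, optionally compute classical scores, calibrate the
#' rating scale model, run iterative misfit removal and recalibrate,
#' evaluate rating-scale category functioning, check dimensionality and
#' local independence, draw the Wright map, and compute item/person
#' tables, separation for both facets, and DIF for each requested
#' covariate. All artifacts are written under `out_dir` with fixed names
#' (`scores.csv`, `items.csv`, `thresholds.csv`, `persons.csv`,
#' `fit_rounds.json`, `category_diagnostics.csv`, `curves.csv`,
#' `dif_<covariate>.csv`, `wright_map.txt`, `summary.json`); nothing is
#' timestamped, so a rerun with identical input, config and seed
#' reproduces the bundle byte for byte. Any stage failure halts with the
#' stage name and cause.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every intermediate object (`responses`,
#'   `scores`, `removal`, `fit`, `fit_report`, `categories`,
#'   `dimensionality`, `wright`, `separation_person`, `separation_item`,
#'   `targeting`, `dif`, `summary`, `files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (config$verbose) message(...)
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  set.seed(config$seed)
  paths <- list()
  out <- function(f) file.path(config$out_dir, f)

  rm0 <- stage("read", {
    if (inherits(config$input, "response_matrix")) config$input
    else read_responses(config$input, config$instrument)
  })

  scores <- NULL
  if (config$classical_scores &&
      rm0$n_categories == config$instrument$n_categories &&
      all(config$instrument$item_ids %in% rm0$items)) {
    scores <- stage("classical scoring", score_eat26(rm0, config$instrument))
    utils::write.csv(scores, out("scores.csv"), row.names = FALSE, na = "")
    paths$scores <- out("scores.csv")
  }

  rm <- stage("category treatment",
              collapse_for_rasch(rm0, config$collapse, config$instrument))

  removal <- stage("calibration and misfit removal",
                   iterative_misfit_removal(rm, config$removal,
                                            config$estimation))
  fit <- removal$fit
  freport <- removal$report
  rm_final <- if (length(removal$retained) == length(rm$items)) rm
              else subset_items(rm, removal$retained)

  jsonlite::write_json(removal_log_json(removal), out("fit_rounds.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  paths$fit_rounds <- out("fit_rounds.json")

  cats <- stage("rating scale diagnostics",
                rating_scale_diagnostics(rm_final, fit))
  utils::write.csv(cats$table, out("category_diagnostics.csv"),
                   row.names = FALSE, na = "")
  paths$category_diagnostics <- out("category_diagnostics.csv")
  curves <- data.frame(logit = cats$grid, cats$curves, check.names = FALSE)
  utils::write.csv(curves, out("curves.csv"), row.names = FALSE)
  paths$curves <- out("curves.csv")

  dimrep <- stage("dimensionality", pca_of_residuals(freport))

  wm <- stage("wright map", wright_map(fit, bin_width = config$bin_width))
  writeLines(wm$text, out("wright_map.txt"))
  paths$wright_map <- out("wright_map.txt")

  items_tab <- stage("item table", {
    it <- freport$item
    data.frame(item_id = it$item_id,
               difficulty = fit$difficulty[it$item_id],
               se = fit$se_difficulty[it$item_id],
               infit = it$infit, outfit = it$outfit,
               row.names = NULL)
  })
  utils::write.csv(items_tab, out("items.csv"), row.names = FALSE)
  paths$items <- out("items.csv")
  utils::write.csv(data.frame(step = seq_along(fit$thresholds) + 1L,
                              threshold = fit$thresholds,
                              se = fit$se_thresholds),
                   out("thresholds.csv"), row.names = FALSE)
  paths$thresholds <- out("thresholds.csv")

  persons_tab <- stage("person table", {
    pr <- freport$person
    data.frame(person_id = rm$persons,
               measure = fit$measure[rm$persons],
               se = fit$se_measure[rm$persons],
               extreme = rm$persons %in% fit$extreme_persons,
               infit = pr$infit[match(rm$persons, pr$person_id)],
               outfit = pr$outfit[match(rm$persons, pr$person_id)],
               row.names = NULL)
  })
  utils::write.csv(persons_tab, out("persons.csv"), row.names = FALSE, na = "")
  paths$persons <- out("persons.csv")

  sep_p <- stage("person separation",
                 separation(fit$measure[fit$active_persons],
                            fit$se_measure[fit$active_persons], "person"))
  sep_i <- stage("item separation",
                 separation(fit$difficulty[fit$active_items],
                            fit$se_difficulty[fit$active_items], "item"))
  targ <- stage("targeting",
                targeting_gap(fit$measure[fit$active_persons],
                              fit$difficulty[fit$active_items]))

  dif_res <- list()
  for (cv in config$dif_covariates) {
    dif_res[[cv]] <- stage(paste0("DIF (", cv, ")"), {
      res <- dif_analysis(rm_final, fit, cv)
      dif_report(res, out(paste0("dif_", cv, ".csv")))
      paths[[paste0("dif_", cv)]] <- out(paste0("dif_", cv, ".csv"))
      res
    })
  }

  summary <- list(
    n_persons = nrow(rm$X), n_items = ncol(rm$X),
    n_categories = rm$n_categories,
    seed = config$seed, collapse = config$collapse,
    converged = fit$converged, iterations = fit$iterations,
    removed_items = removal$removed, retained_items = removal$retained,
    removal_rounds = length(removal$rounds),
    extreme_persons = length(fit$extreme_persons),
    thresholds = fit$thresholds,
    thresholds_ordered = cats$ordered,
    category_criteria = as.list(cats$criteria),
    first_contrast = dimrep$first_contrast,
    unidimensional = dimrep$unidimensional,
    max_residual_correlation = dimrep$max_residual_correlation,
    locally_independent = dimrep$locally_independent,
    person_mean = mean(fit$measure[fit$active_persons]),
    person_sd = stats::sd(fit$measure[fit$active_persons]),
    difficulty_range = range(fit$difficulty[fit$active_items]),
    person_separation = sep_p$separation,
    person_reliability = sep_p$reliability,
    person_strata = sep_p$strata,
    item_separation = sep_i$separation,
    item_reliability = sep_i$reliability,
    targeting = targ,
    dif_flagged = lapply(dif_res, function(r)
      r$item_id[!is.na(r$flagged) & r$flagged])
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = 10, null = "list")
  paths$summary <- out("summary.json")

  invisible(list(responses = rm0, matrix = rm, scores = scores,
                 removal = removal, fit = fit, fit_report = freport,
                 categories = cats, dimensionality = dimrep, wright = wm,
                 separation_person = sep_p, separation_item = sep_i,
                 targeting = targ, dif = dif_res, summary = summary,
                 files = paths))
}
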