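#' Misfit-removal rule
#'
#' Configures how [iterative_misfit_removal()] flags and removes items.
#' With `mode = "both"` an item is flagged only when Infit *and* Outfit
#' fall outside `[lower, upper]`; `"either"` flags on one violation.
#' Exempt items are reported when flagged but never removed (the judgment
#' call validation studies make for substantively essential items).
#'
#' @param lower,upper Acceptable mean-square bounds (defaults 0.5 / 1.5).
#' @param mode `"both"` or `"either"`.
#' @param exempt Character vector of item ids never removed.
#' @param max_rounds Safety cap on refit rounds.
#' @return An object of class `"removal_rule"`.
#' @export
removal_rule <- function(lower = 0.5, upper = 1.5,
                         mode = c("both", "either"),
                         exempt = character(), max_rounds = 25L) {
  mode <- match.arg(mode)
  stopifnot(lower > 0, upper > lower)
  structure(list(lower = lower, upper = upper, mode = mode,
                 exempt = as.character(exempt),
                 max_rounds = as.integer(max_rounds)),
            class = "removal_rule")
}

#' Iterative removal of misfitting items
#'
#' The standard calibrate-flag-remove loop: fit the model, flag items whose
#' mean squares violate the rule, remove the whole non-exempt flagged batch,
#' refit, and repeat until no removable item remains. Every round is logged
#' with the items flagged, removed and retained by exemption plus the fit
#' table, giving a full audit trail.
#'
#' @param rm A [response_matrix()].
#' @param rule A [removal_rule()].
#' @param config An [estimation_config()] used for every refit.
#' @return An object of class `"removal_log"`: `retained` and `removed`
#'   item ids, the per-round `rounds` list, and the final `fit` and
#'   `report` on the retained item set.
#' @export
iterative_misfit_removal <- function(rm, rule = removal_rule(),
                                     config = estimation_config()) {
  kept <- rm$items
  removed_all <- character()
  rounds <- list()
  for (round in seq_len(rule$max_rounds)) {
    sub <- if (length(kept) == length(rm$items)) rm else subset_items(rm, kept)
    fit <- fit_jmle(sub, config)
    rep <- fit_statistics(sub, fit)
    it <- rep$item
    bad_in <- it$infit < rule$lower | it$infit > rule$upper
    bad_out <- it$outfit < rule$lower | it$outfit > rule$upper
    flagged <- it$item_id[if (rule$mode == "both") bad_in & bad_out
                          else bad_in | bad_out]
    removable <- setdiff(flagged, rule$exempt)
    rounds[[round]] <- list(round = round,
                            flagged = flagged,
                            removed = removable,
                            exempt_retained = intersect(flagged, rule$exempt),
                            fit_table = it)
    if (!length(removable)) break
    if (length(kept) - length(removable) < 2L) {
      res <- structure(list(retained = kept, removed = removed_all,
                            rounds = rounds, fit = fit, report = rep,
                            rule = rule, aborted = TRUE),
                       class = "removal_log")
      stop("removing ", paste(removable, collapse = ", "),
           " would leave fewer than 2 items; aborting (see attached log)",
           call. = FALSE)
    }
    kept <- setdiff(kept, removable)
    removed_all <- c(removed_all, removable)
  }
  structure(list(retained = kept, removed = removed_all, rounds = rounds,
                 fit = fit, report = rep, rule = rule, aborted = FALSE),
            class = "removal_log")
}

#' @export
print.removal_log <- function(x, ...) {
  cat(sprintf("<removal_log> %d round(s): %d removed, %d retained\n",
              length(x$rounds), length(x$removed), length(x$retained)))
  for (r in x$rounds) {
    cat(sprintf("  round %d: flagged [%s] removed [%s]%s\n", r$round,
                paste(r$flagged, collapse = " "),
                paste(r$removed, collapse = " "),
                if (length(r$exempt_retained))
                  paste0(" exempt [", paste(r$exempt_retained, collapse = " "), "]")
                else ""))
  }
  invisible(x)
}

# Serialize a removal log to plain JSON (round-by-round audit trail).
removal_log_json <- function(x) {
  rounds <- lapply(x$rounds, function(r) {
    list(round = r$round, flagged = r$flagged, removed = r$removed,
         exempt_retained = r$exempt_retained,
         fit_table = r$fit_table[c("item_id", "infit", "outfit")])
  })
  list(rule = unclass(x$rule), retained = x$retained,
       removed = x$removed, rounds = rounds)
}
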