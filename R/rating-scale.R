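#' Category usage percentages
#'
#' @param counts Integer vector of per-category observation counts.
#' @return Percentages summing to 100.
#' @export
category_percentages <- function(counts) {
  stopifnot(all(counts >= 0), sum(counts) > 0)
  100 * counts / sum(counts)
}

#' Are Andrich thresholds ordered?
#'
#' Thresholds are "ordered" (advancing) when strictly increasing; a
#' disordered sequence signals that some category is never the most
#' probable anywhere on the latent continuum and the rating scale may need
#' restructuring.
#'
#' @param thresholds Andrich thresholds `F_1..F_(m-1)`.
#' @return Logical scalar, with attribute `first_violation` (index of the
#'   first non-advancing step, or `NA`).
#' @export
thresholds_ordered <- function(thresholds) {
  d <- diff(thresholds)
  viol <- which(d <= 0)
  structure(length(viol) == 0L,
            first_violation = if (length(viol)) viol[1] + 1L else NA_integer_)
}

#' Rating-scale category diagnostics
#'
#' The category-functioning table of a rating-scale calibration: per
#' category the count and percentage of (non-extreme) observations, the
#' average measure of the persons producing them, the category Outfit mean
#' square, and the Andrich threshold entered from below. Four conventional
#' criteria are evaluated: (a) regular observation distribution (every
#' category used at least `min_count` times), (b) average measures
#' strictly advancing with category, (c) all category Outfits below 2.0,
#' and (d) strictly advancing thresholds. Category probability curves are
#' sampled on a logit grid for plotting.
#'
#' @param rm The calibrated [response_matrix()].
#' @param fit The [fit_jmle()] result.
#' @param min_count Minimum per-category count for criterion (a)
#'   (default 10).
#' @param grid Logit grid (relative measure `c - d`) for the probability
#'   curves.
#' @return An object of class `"category_diagnostics"`: data frame
#'   `table` (category, label-free), `thresholds`, `ordered` verdict,
#'   `criteria` (named logical vector a-d), and `curves` (grid x m matrix
#'   of category probabilities).
#' @export
rating_scale_diagnostics <- function(rm, fit, min_count = 10L,
                                     grid = seq(-6, 6, by = 0.1)) {
  stopifnot(inherits(rm, "response_matrix"), inherits(fit, "rsm_fit"))
  m <- rm$n_categories
  act_p <- rm$persons %in% fit$active_persons
  act_i <- rm$items %in% fit$active_items
  X <- rm$X[act_p, act_i, drop = FALSE]
  C <- fit$measure[rm$persons[act_p]]
  D <- fit$difficulty[rm$items[act_i]]
  mo <- rsm_moments(outer(C, D, "-"), fit$thresholds)
  obs <- !is.na(X)
  Cmat <- matrix(C, nrow(X), ncol(X))
  counts <- integer(m); avg <- rep(NA_real_, m); outfit <- rep(NA_real_, m)
  Xz <- X; Xz[!obs] <- 0L
  z2 <- ((Xz - 1L - mo$E)^2 / pmax(mo$W, 1e-12))
  for (k in seq_len(m)) {
    sel <- obs & X == k
    counts[k] <- sum(sel)
    if (counts[k]) {
      avg[k] <- mean(Cmat[sel])
      outfit[k] <- mean(z2[sel])
    }
  }
  tab <- data.frame(category = seq_len(m),
                    count = counts,
                    percent = category_percentages(counts),
                    average_measure = avg,
                    outfit = outfit,
                    threshold = c(NA_real_, fit$thresholds))
  ordered <- thresholds_ordered(fit$thresholds)
  criteria <- c(
    regular_distribution = all(counts >= min_count),
    advancing_measures = all(counts > 0) && !is.unsorted(avg, strictly = TRUE),
    outfit_below_2 = all(outfit < 2, na.rm = TRUE) && !anyNA(outfit),
    advancing_thresholds = as.logical(ordered)
  )
  curves <- vapply(rsm_category_probs(grid, fit$thresholds),
                   as.numeric, numeric(length(grid)))
  colnames(curves) <- paste0("cat", seq_len(m))
  structure(list(table = tab, thresholds = fit$thresholds,
                 ordered = as.logical(ordered),
                 first_violation = attr(ordered, "first_violation"),
                 criteria = criteria,
                 grid = grid, curves = curves),
            class = "category_diagnostics")
}

#' @export
print.category_diagnostics <- function(x, ...) {
  cat("<category_diagnostics>\n")
  print(x$table, row.names = FALSE, digits = 3)
  cat(sprintf("  thresholds %s; criteria passed: %s\n",
              if (x$ordered) "ordered" else
                sprintf("DISORDERED (first violation at step %d)", x$first_violation),
              paste(names(x$criteria)[x$criteria], collapse = ", ")))
  invisible(x)
}
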