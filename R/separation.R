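#' Separation index, reliability and strata for a facet
#'
#' Decomposes the observed spread of measures into true spread and
#' measurement error: with observed SD `SD_obs` and error
#' `RMSE = sqrt(mean(se^2))`, the true SD is
#' `sqrt(max(0, SD_obs^2 - RMSE^2))`, the separation index is
#' `G = trueSD / RMSE`, the separation reliability
#' `R = trueSD^2 / SD_obs^2` (identically `G^2 / (1 + G^2)`), and the
#' number of statistically distinct strata `H = (4G + 1) / 3`. When the
#' error variance exceeds the observed variance the true SD clamps at
#' zero (`G = 0`, `R = 0`). Separation above 2 is conventionally called
#' acceptable.
#'
#' @param measures Logit measures of the facet (extremes excluded by
#'   convention).
#' @param ses Matching standard errors (> 0).
#' @param facet `"person"` or `"item"` (label only).
#' @return An object of class `"separation_report"` with `sd_obs`, `rmse`,
#'   `true_sd`, `separation`, `reliability`, `strata`, `strata_floor`, and
#'   `acceptable` (`G > 2`).
#' @export
separation <- function(measures, ses, facet = c("person", "item")) {
  facet <- match.arg(facet)
  keep <- !is.na(measures) & !is.na(ses)
  measures <- measures[keep]; ses <- ses[keep]
  if (length(measures) < 2L)
    stop("separation needs at least 2 measures", call. = FALSE)
  if (any(ses <= 0)) stop("standard errors must be positive", call. = FALSE)
  sd_obs <- stats::sd(measures)
  rmse <- sqrt(mean(ses^2))
  true_sd <- sqrt(max(0, sd_obs^2 - rmse^2))
  G <- true_sd / rmse
  R <- if (sd_obs > 0) true_sd^2 / sd_obs^2 else 0
  structure(list(facet = facet, n = length(measures),
                 sd_obs = sd_obs, rmse = rmse, true_sd = true_sd,
                 separation = G, reliability = R,
                 strata = (4 * G + 1) / 3,
                 strata_floor = floor((4 * G + 1) / 3),
                 acceptable = G > 2),
            class = "separation_report")
}

#' @export
print.separation_report <- function(x, ...) {
  cat(sprintf("<separation_report> %s facet (n = %d)\n", x$facet, x$n))
  cat(sprintf("  SD(obs) %.3f, RMSE %.3f, true SD %.3f\n",
              x$sd_obs, x$rmse, x$true_sd))
  cat(sprintf("  separation G = %.2f (%s), reliability R = %.2f, strata %.2f\n",
              x$separation, if (x$acceptable) "acceptable" else "low",
              x$reliability, x$strata))
  invisible(x)
}

#' Targeting gap between persons and items
#'
#' How much of the person distribution lies below the instrument's reach:
#' the share of persons below the easiest item, and below a fixed floor of
#' -1 logit (the conventional "low risk" region a screening instrument
#' should still cover).
#'
#' @param person_measures Person measures in logits.
#' @param item_difficulties Item difficulties in logits.
#' @return List with `min_item_difficulty`, `share_below_min_item`, and
#'   `share_below_minus1`.
#' @export
targeting_gap <- function(person_measures, item_difficulties) {
  person_measures <- person_measures[!is.na(person_measures)]
  item_difficulties <- item_difficulties[!is.na(item_difficulties)]
  stopifnot(length(person_measures) > 0, length(item_difficulties) > 0)
  lo <- min(item_difficulties)
  list(min_item_difficulty = lo,
       share_below_min_item = mean(person_measures < lo),
       share_below_minus1 = mean(person_measures < -1))
}
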