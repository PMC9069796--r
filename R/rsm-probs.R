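# Rating scale model category machinery.
#
# Parameterization: for person measure c, item difficulty d and Andrich
# thresholds F_1..F_{m-1}, the adjacent-category log-odds are
#   ln(P_k / P_{k-1}) = (c - d) - F_k,   k = 2..m (categories scored 0..m-1)
# so category k (0-based score s = k-1) has unnormalized log-weight
#   s * (c - d) - sum_{j<=s} F_j.
# Higher measures therefore endorse higher categories.

# Internal: list of m probability matrices, one per category, for a matrix
# (or vector) of person-minus-item locations `theta`. Numerically safe via
# max-subtraction before exponentiation.
rsm_category_probs <- function(theta, thresholds) {
  m <- length(thresholds) + 1L
  cs <- c(0, cumsum(thresholds))
  th <- as.matrix(theta)
  logw <- lapply(seq_len(m) - 1L, function(s) s * th - cs[s + 1L])
  mx <- Reduce(pmax, logw)
  w <- lapply(logw, function(l) exp(l - mx))
  z <- Reduce(`+`, w)
  lapply(w, function(wk) wk / z)
}

# Internal: probabilities plus first/second (and optionally fourth central)
# moments of the 0-based category score, elementwise over theta.
rsm_moments <- function(theta, thresholds, fourth = FALSE) {
  P <- rsm_category_probs(theta, thresholds)
  m <- length(P)
  E <- 0; E2 <- 0
  for (k in seq_len(m)) {
    s <- k - 1
    E <- E + s * P[[k]]
    E2 <- E2 + s * s * P[[k]]
  }
  W <- pmax(E2 - E * E, 0)
  out <- list(P = P, E = E, W = W)
  if (fourth) {
    C4 <- 0
    for (k in seq_len(m)) C4 <- C4 + (k - 1 - E)^4 * P[[k]]
    out$C4 <- C4
  }
  out
}

# Internal: joint log-likelihood of observed 0-based scores Xa (with
# observation mask Oa) at locations theta.
rsm_loglik <- function(theta, thresholds, Xa, Oa) {
  P <- rsm_category_probs(theta, thresholds)
  ll <- 0
  for (k in seq_along(P)) {
    sel <- Oa & !is.na(Xa) & Xa == (k - 1L)
    if (any(sel)) ll <- ll + sum(log(pmax(P[[k]][sel], 1e-300)))
  }
  ll
}

#' Rating-scale category probabilities
#'
#' Probability of each response category for one person-item encounter under
#' the rating scale model, with adjacent-category log-odds
#' `ln(P_k / P_(k-1)) = (person - item) - F_k`.
#'
#' @param person Person measure in logits.
#' @param item Item difficulty in logits.
#' @param thresholds Andrich thresholds `F_1..F_(m-1)`.
#' @return Numeric vector of `m` probabilities summing to 1 (categories low
#'   to high).
#' @examples
#' category_probabilities(0, 0, rep(0, 5))  # all 1/6
#' @export
category_probabilities <- function(person, item, thresholds) {
  stopifnot(length(person) == 1L, length(item) == 1L)
  vapply(rsm_category_probs(person - item, thresholds), as.numeric, numeric(1))
}

#' Expected score and variance under the rating scale model
#'
#' Moments of the 0-based item score (0..m-1) for one person-item
#' encounter; the variance is the information weight used by the Infit
#' statistic, and the fourth central moment feeds standardized fit.
#'
#' @inheritParams category_probabilities
#' @return List with `expected`, `variance`, and `m4` (fourth central
#'   moment), all in score-point units.
#' @export
expected_score <- function(person, item, thresholds) {
  mo <- rsm_moments(person - item, thresholds, fourth = TRUE)
  list(expected = as.numeric(mo$E), variance = as.numeric(mo$W),
       m4 = as.numeric(mo$C4))
}
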