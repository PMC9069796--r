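#' Infit and Outfit mean-square fit statistics
#'
#' Standardized residuals `z = (x - E) / sqrt(W)` are computed for every
#' observed non-extreme cell at the fitted parameters, where `E` and `W`
#' are the model's expected score and score variance. Outfit is the plain
#' mean of `z^2` over a facet; Infit is the information-weighted version
#' `sum(W z^2) / sum(W)`, equal to `sum((x - E)^2) / sum(W)`. Values near 1
#' indicate model-data fit; above 1.5 noisy misfit, below 0.5 muted
#' (overfitting) responses. Standardized (ZSTD) versions via the
#' Wilson-Hilferty cube-root transform are reported alongside but play no
#' part in removal decisions.
#'
#' @param rm The [response_matrix()] the parameters were estimated on (or
#'   anchored to).
#' @param fit An [fit_jmle()] result.
#' @return An object of class `"fit_report"`: data frames `item` and
#'   `person` (id, raw count, infit, outfit, infit_z, outfit_z), the full
#'   standardized-residual matrix `Z` (`NA` at missing or extreme cells),
#'   and the expectation/variance matrices `E`, `W` on the same layout.
#' @export
fit_statistics <- function(rm, fit) {
  stopifnot(inherits(rm, "response_matrix"), inherits(fit, "rsm_fit"))
  m <- rm$n_categories
  act_p <- rm$persons %in% fit$active_persons
  act_i <- rm$items %in% fit$active_items
  if (!any(act_p) || !any(act_i))
    stop("no non-extreme persons/items to compute fit for", call. = FALSE)
  C <- fit$measure[rm$persons[act_p]]
  D <- fit$difficulty[rm$items[act_i]]
  Xa <- rm$X[act_p, act_i, drop = FALSE] - 1L
  Oa <- !is.na(Xa)
  mo <- rsm_moments(outer(C, D, "-"), fit$thresholds, fourth = TRUE)
  Xz <- Xa; Xz[!Oa] <- 0L
  res <- (Xz - mo$E) * Oa
  z2 <- res^2 / pmax(mo$W, 1e-12) * Oa

  item_stats <- function() {
    nobs <- colSums(Oa)
    infit <- colSums(res^2) / pmax(colSums(mo$W * Oa), 1e-12)
    outfit <- colSums(z2) / pmax(nobs, 1)
    qi2 <- (colSums(mo$C4 * Oa) - colSums((mo$W^2) * Oa)) /
      pmax(colSums(mo$W * Oa), 1e-12)^2
    qo2 <- colSums((mo$C4 / pmax(mo$W, 1e-12)^2) * Oa) / pmax(nobs, 1)^2 -
      1 / pmax(nobs, 1)
    data.frame(item_id = colnames(Xa), n = nobs,
               infit = infit, outfit = outfit,
               infit_z = zstd(infit, qi2), outfit_z = zstd(outfit, qo2))
  }
  person_stats <- function() {
    nobs <- rowSums(Oa)
    infit <- rowSums(res^2) / pmax(rowSums(mo$W * Oa), 1e-12)
    outfit <- rowSums(z2) / pmax(nobs, 1)
    qi2 <- (rowSums(mo$C4 * Oa) - rowSums((mo$W^2) * Oa)) /
      pmax(rowSums(mo$W * Oa), 1e-12)^2
    qo2 <- rowSums((mo$C4 / pmax(mo$W, 1e-12)^2) * Oa) / pmax(nobs, 1)^2 -
      1 / pmax(nobs, 1)
    data.frame(person_id = rownames(Xa), n = nobs,
               infit = infit, outfit = outfit,
               infit_z = zstd(infit, qi2), outfit_z = zstd(outfit, qo2))
  }

  pad <- function(M) {
    full <- matrix(NA_real_, nrow(rm$X), ncol(rm$X),
                   dimnames = dimnames(rm$X))
    full[act_p, act_i] <- M
    full
  }
  Zfull <- pad(ifelse(Oa, res / sqrt(pmax(mo$W, 1e-12)), NA_real_))
  structure(list(item = item_stats(), person = person_stats(),
                 Z = Zfull,
                 E = pad(ifelse(Oa, mo$E, NA_real_)),
                 W = pad(ifelse(Oa, mo$W, NA_real_))),
            class = "fit_report")
}

# Wilson-Hilferty standardization of a mean-square with variance q2.
zstd <- function(mnsq, q2) {
  q <- sqrt(pmax(q2, 0))
  out <- (mnsq^(1 / 3) - 1) * (3 / q) + q / 3
  out[!is.finite(out)] <- NA_real_
  out
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> %d items, %d persons\n",
              nrow(x$item), nrow(x$person)))
  cat(sprintf("  item infit  %.2f-%.2f, outfit %.2f-%.2f\n",
              min(x$item$infit), max(x$item$infit),
              min(x$item$outfit), max(x$item$outfit)))
  invisible(x)
}
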