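#' Dimensionality and local independence from standardized residuals
#'
#' After the Rasch dimension is removed by residualization, remaining
#' structure among items signals a secondary dimension. The check is a
#' principal component analysis of the item-by-item correlation matrix of
#' standardized residuals (pairwise complete cells); eigenvalues are in
#' item units, so the largest one — the "first contrast" — is compared to
#' the conventional ceiling of 2.0 items. Local independence is judged from
#' the residual correlations themselves: any pair with `|r|` above 0.7 is
#' flagged as locally dependent.
#'
#' @param report A [fit_statistics()] result (supplies the residual
#'   matrix `Z`).
#' @param unidim_limit First-contrast ceiling (default 2.0 items).
#' @param dependence_limit Residual-correlation ceiling (default 0.7).
#' @return An object of class `"dimensionality_report"`: `eigenvalues`,
#'   `first_contrast`, `unidimensional`, `max_residual_correlation`, the
#'   offending `dependent_pairs` (if any), `locally_independent`, and any
#'   `dropped` zero-variance items.
#' @export
pca_of_residuals <- function(report, unidim_limit = 2.0,
                             dependence_limit = 0.7) {
  stopifnot(inherits(report, "fit_report"))
  Z <- report$Z
  keep <- colSums(!is.na(Z)) >= 2L
  sds <- apply(Z, 2L, stats::sd, na.rm = TRUE)
  keep <- keep & !is.na(sds) & sds > 0
  dropped <- colnames(Z)[!keep]
  Z <- Z[, keep, drop = FALSE]
  if (ncol(Z) < 2L)
    stop("need at least 2 items with residual variance", call. = FALSE)
  R <- suppressWarnings(stats::cor(Z, use = "pairwise.complete.obs"))
  R[is.na(R)] <- 0
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)  # pairwise correlation matrices can be slightly non-PSD
  offdiag <- R; diag(offdiag) <- NA
  mx <- max(abs(offdiag), na.rm = TRUE)
  pairs <- which(abs(offdiag) > dependence_limit, arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  dep <- if (nrow(pairs)) data.frame(item_a = colnames(R)[pairs[, 1]],
                                     item_b = colnames(R)[pairs[, 2]],
                                     r = offdiag[pairs])
         else data.frame(item_a = character(), item_b = character(),
                         r = numeric())
  structure(list(eigenvalues = ev,
                 first_contrast = ev[1],
                 unidimensional = ev[1] <= unidim_limit,
                 max_residual_correlation = mx,
                 dependent_pairs = dep,
                 locally_independent = mx <= dependence_limit,
                 dropped = dropped,
                 limits = c(unidimensional = unidim_limit,
                            dependence = dependence_limit)),
            class = "dimensionality_report")
}

#' @export
print.dimensionality_report <- function(x, ...) {
  cat(sprintf("<dimensionality_report> first contrast %.2f (%s), max |residual r| %.2f (%s)\n",
              x$first_contrast,
              if (x$unidimensional) "unidimensional" else "secondary dimension suspected",
              x$max_residual_correlation,
              if (x$locally_independent) "locally independent" else "dependent pair(s)"))
  invisible(x)
}
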