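#' Estimation settings for the JMLE engine
#'
#' @param max_iterations Maximum alternating Newton cycles.
#' @param convergence_tol Convergence on the maximum absolute parameter
#'   change, in logits.
#' @param extreme_adjustment Fractional score offset applied to perfect and
#'   zero raw scores so extreme facets get finite extrapolated measures;
#'   must lie in (0, 0.5].
#' @param damping Initial step multiplier; halved whenever a cycle would
#'   decrease the joint log-likelihood.
#' @param bias_correction Apply the first-order `(L-1)/L` spread correction
#'   for the joint-likelihood bias of item (and `(N-1)/N` of person)
#'   estimates. Off by default; the reported conventions assume raw JMLE.
#' @return An object of class `"estimation_config"`.
#' @export
estimation_config <- function(max_iterations = 200L, convergence_tol = 0.005,
                              extreme_adjustment = 0.3, damping = 1.0,
                              bias_correction = FALSE) {
  stopifnot(convergence_tol > 0,
            extreme_adjustment > 0, extreme_adjustment <= 0.5,
            damping > 0, max_iterations >= 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 extreme_adjustment = extreme_adjustment,
                 damping = damping,
                 bias_correction = isTRUE(bias_correction)),
            class = "estimation_config")
}

# Internal: iteratively mark persons/items whose raw score is at the floor
# or ceiling of what their observed cells allow (no finite MLE). Returns
# logical vectors (TRUE = active / non-extreme).
find_extremes <- function(x0, obs, m) {
  n <- nrow(x0); I <- ncol(x0)
  act_p <- rep(TRUE, n); act_i <- rep(TRUE, I)
  x0z <- x0; x0z[!obs] <- 0L
  repeat {
    oi <- obs[, act_i, drop = FALSE]
    r <- rowSums(x0z[, act_i, drop = FALSE])
    rmax <- (m - 1L) * rowSums(oi)
    new_p <- rmax > 0L & r > 0L & r < rmax
    op <- obs[new_p, , drop = FALSE]
    s <- colSums(x0z[new_p, , drop = FALSE])
    smax <- (m - 1L) * colSums(op)
    new_i <- smax > 0L & s > 0L & s < smax
    if (identical(new_p, act_p) && identical(new_i, act_i)) break
    act_p <- new_p; act_i <- new_i
  }
  list(persons = act_p, items = act_i)
}

# Internal: one-dimensional Newton solve of the person score equation
# sum_i E(c - d_i) = target, given anchored difficulties and thresholds.
solve_measure <- function(target, d, thresholds) {
  c <- 0
  for (i in 1:200) {
    mo <- rsm_moments(c - d, thresholds)
    g <- target - sum(mo$E)
    W <- max(sum(mo$W), 1e-10)
    step <- clamp(g / W, 2)
    c <- c + step
    if (abs(step) < 1e-9) break
  }
  list(measure = c, se = 1 / sqrt(max(sum(mo$W), 1e-10)))
}

# Internal: Newton solve of the item score equation over anchored persons.
solve_difficulty <- function(target, C, thresholds) {
  d <- 0
  for (i in 1:200) {
    mo <- rsm_moments(C - d, thresholds)
    g <- target - sum(mo$E)
    W <- max(sum(mo$W), 1e-10)
    step <- clamp(g / W, 2)
    d <- d - step
    if (abs(step) < 1e-9) break
  }
  list(difficulty = d, se = 1 / sqrt(max(sum(mo$W), 1e-10)))
}

#' Joint maximum likelihood estimation of the rating scale model
#'
#' Alternating Newton-Raphson updates of person measures, item difficulties
#' and shared Andrich thresholds, maximizing the joint likelihood of the
#' observed categories. Identification follows the usual convention: item
#' difficulties are mean-centered over non-extreme items, thresholds sum to
#' zero, person measures are free. Persons and items with perfect or zero
#' raw scores have no finite maximizer; they are excluded from the
#' iteration and afterwards given extrapolated measures by shifting their
#' raw score `extreme_adjustment` points inward and solving the anchored
#' score equation. Steps are capped at one logit and damped whenever a
#' cycle would decrease the joint log-likelihood, so the likelihood is
#' non-decreasing across accepted iterations.
#'
#' @param rm A [response_matrix()] with at least two non-extreme persons
#'   and items; every category `1..m` must be observed at least once among
#'   non-extreme cells (otherwise collapse categories first).
#' @param config An [estimation_config()].
#' @return An object of class `"rsm_fit"`: per-item `difficulty` and
#'   `se_difficulty`, per-person `measure` and `se_measure` (extrapolated
#'   values for extreme facets, flagged in `extreme_items` /
#'   `extreme_persons`), `thresholds` and `se_thresholds`, the iteration
#'   `log` (log-likelihood, max change, damping per cycle), `converged`,
#'   and the identification record `centering`.
#' @export
fit_jmle <- function(rm, config = estimation_config()) {
  stopifnot(inherits(rm, "response_matrix"))
  X <- rm$X; m <- rm$n_categories
  n <- nrow(X); I <- ncol(X)
  if (n < 2L || I < 2L)
    stop("estimation needs at least 2 persons and 2 items", call. = FALSE)
  obs <- !is.na(X)
  x0 <- X - 1L
  ext <- find_extremes(x0, obs, m)
  act_p <- ext$persons; act_i <- ext$items
  if (sum(act_p) < 2L || sum(act_i) < 2L)
    stop("fewer than 2 non-extreme persons or items; cannot calibrate",
         call. = FALSE)
  Xa <- x0[act_p, act_i, drop = FALSE]
  Oa <- obs[act_p, act_i, drop = FALSE]
  Xz <- Xa; Xz[!Oa] <- 0L
  seen <- tabulate(Xa[Oa] + 1L, nbins = m)
  if (any(seen == 0L))
    stop("category ", which(seen == 0L)[1], " is never observed among ",
         "non-extreme responses; collapse categories before calibrating",
         call. = FALSE)
  na <- nrow(Xa); Ia <- ncol(Xa)
  r <- rowSums(Xz); rmax <- (m - 1L) * rowSums(Oa)
  s <- colSums(Xz); smax <- (m - 1L) * colSums(Oa)

  C <- log((r + 0.5) / (rmax - r + 0.5))
  D <- log((smax - s + 0.5) / (s + 0.5))
  D <- D - mean(D)
  Fk <- rep(0, m - 1L)

  cycle <- function(C, D, Fk, lam) {
    mo <- rsm_moments(outer(C, D, "-"), Fk)
    C <- C + lam * clamp((r - rowSums(mo$E * Oa)) /
                           pmax(rowSums(mo$W * Oa), 1e-8), 1)
    mo <- rsm_moments(outer(C, D, "-"), Fk)
    D <- D - lam * clamp((s - colSums(mo$E * Oa)) /
                           pmax(colSums(mo$W * Oa), 1e-8), 1)
    if (m > 2L) {
      mo <- rsm_moments(outer(C, D, "-"), Fk)
      for (k in seq_len(m - 1L)) {
        Pge <- Reduce(`+`, mo$P[(k + 1L):m])
        Tk <- sum(Xa >= k & Oa)
        ETk <- sum(Pge[Oa])
        Vk <- max(sum((Pge * (1 - Pge))[Oa]), 1e-8)
        Fk[k] <- Fk[k] - lam * clamp((Tk - ETk) / Vk, 1)
      }
    }
    # identification: thresholds sum-zero (absorbed by item shift), items
    # mean-zero (absorbed by person shift); both preserve the likelihood
    nu <- mean(Fk); Fk <- Fk - nu; D <- D + nu
    mu <- mean(D); D <- D - mu; C <- C - mu
    list(C = C, D = D, Fk = Fk)
  }

  lam <- config$damping
  ll <- rsm_loglik(outer(C, D, "-"), Fk, Xa, Oa)
  log_rows <- list()
  converged <- FALSE
  for (it in seq_len(config$max_iterations)) {
    repeat {
      new <- cycle(C, D, Fk, lam)
      lln <- rsm_loglik(outer(new$C, new$D, "-"), new$Fk, Xa, Oa)
      if (lln >= ll - 1e-9) break
      lam <- lam / 2
      if (lam < 1e-4) break
    }
    if (lln < ll - 1e-9) break  # stalled; keep the last accepted state
    delta <- max(abs(c(new$C - C, new$D - D, new$Fk - Fk)))
    C <- new$C; D <- new$D; Fk <- new$Fk; ll <- lln
    log_rows[[it]] <- c(iteration = it, loglik = ll, max_change = delta,
                        damping = lam)
    lam <- min(config$damping, lam * 2)
    if (delta < config$convergence_tol) { converged <- TRUE; break }
  }

  if (config$bias_correction) {
    D <- D * (Ia - 1) / Ia
    C <- C * (na - 1) / na
    mu <- mean(D); D <- D - mu; C <- C - mu
  }

  mo <- rsm_moments(outer(C, D, "-"), Fk)
  se_C <- 1 / sqrt(pmax(rowSums(mo$W * Oa), 1e-10))
  se_D <- 1 / sqrt(pmax(colSums(mo$W * Oa), 1e-10))
  se_F <- rep(NA_real_, m - 1L)
  for (k in seq_len(m - 1L)) {
    Pge <- Reduce(`+`, mo$P[(k + 1L):m])
    se_F[k] <- 1 / sqrt(max(sum((Pge * (1 - Pge))[Oa]), 1e-10))
  }

  measure <- rep(NA_real_, n); se_measure <- rep(NA_real_, n)
  measure[act_p] <- C; se_measure[act_p] <- se_C
  difficulty <- rep(NA_real_, I); se_difficulty <- rep(NA_real_, I)
  difficulty[act_i] <- D; se_difficulty[act_i] <- se_D

  adj <- config$extreme_adjustment
  for (j in which(!act_p)) {
    oj <- obs[j, ] & act_i
    if (!any(oj)) next
    rj <- sum(x0[j, oj])
    rmx <- (m - 1L) * sum(oj)
    target <- if (rj <= 0L) adj else if (rj >= rmx) rmx - adj else rj
    sol <- solve_measure(target, difficulty[oj], Fk)
    measure[j] <- sol$measure; se_measure[j] <- sol$se
  }
  for (i in which(!act_i)) {
    oi <- obs[, i] & act_p
    if (!any(oi)) next
    si <- sum(x0[oi, i])
    smx <- (m - 1L) * sum(oi)
    target <- if (si <= 0L) adj else if (si >= smx) smx - adj else si
    sol <- solve_difficulty(target, measure[oi], Fk)
    difficulty[i] <- sol$difficulty; se_difficulty[i] <- sol$se
  }

  names(measure) <- names(se_measure) <- rm$persons
  names(difficulty) <- names(se_difficulty) <- rm$items
  log_df <- if (length(log_rows)) as.data.frame(do.call(rbind, log_rows))
            else data.frame(iteration = numeric(), loglik = numeric(),
                            max_change = numeric(), damping = numeric())
  structure(list(
    difficulty = difficulty, se_difficulty = se_difficulty,
    measure = measure, se_measure = se_measure,
    thresholds = Fk, se_thresholds = se_F,
    extreme_persons = rm$persons[!act_p],
    extreme_items = rm$items[!act_i],
    active_persons = rm$persons[act_p],
    active_items = rm$items[act_i],
    centering = list(items = "mean zero over non-extreme items",
                     thresholds = "sum zero", persons = "free"),
    converged = converged, iterations = nrow(log_df),
    loglik = ll, log = log_df,
    n_categories = m, config = config
  ), class = "rsm_fit")
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat(sprintf("<rsm_fit> %d persons x %d items, %d categories\n",
              length(x$measure), length(x$difficulty), x$n_categories))
  cat(sprintf("  %s after %d iterations (logLik %.2f)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$loglik))
  cat(sprintf("  difficulty range: [%.2f, %.2f] logits\n",
              min(x$difficulty, na.rm = TRUE), max(x$difficulty, na.rm = TRUE)))
  cat("  thresholds:", paste(sprintf("%.2f", x$thresholds), collapse = ", "), "\n")
  if (length(x$extreme_persons))
    cat("  extreme persons:", length(x$extreme_persons), "\n")
  if (length(x$extreme_items))
    cat("  extreme items:", length(x$extreme_items), "\n")
  invisible(x)
}

#' Person measures under anchored item parameters
#'
#' Maximum-likelihood person measures given difficulties and thresholds
#' from a prior calibration. Extreme raw scores (zero or perfect) are
#' shifted `adjustment` score points inward so the measure is finite;
#' persons with no observed responses are returned undefined.
#'
#' @param responses A [response_matrix()], an integer matrix of category
#'   codes, or a single response vector.
#' @param difficulty Named (or positionally matching) anchored item
#'   difficulties in logits.
#' @param thresholds Anchored Andrich thresholds.
#' @param adjustment Extreme-score adjustment in score points.
#' @return Data frame: `person_id`, `raw`, `raw_max`, `measure`, `se`,
#'   `extreme`, `defined`.
#' @export
person_measures <- function(responses, difficulty, thresholds,
                            adjustment = 0.3) {
  X <- if (inherits(responses, "response_matrix")) responses$X
       else if (is.matrix(responses)) responses
       else matrix(responses, nrow = 1L,
                   dimnames = list(NULL, names(responses)))
  if (!is.null(colnames(X)) && !is.null(names(difficulty)))
    difficulty <- difficulty[colnames(X)]
  if (ncol(X) != length(difficulty))
    stop("difficulty must supply one value per item", call. = FALSE)
  m <- length(thresholds) + 1L
  persons <- rownames(X) %||% paste0("P", seq_len(nrow(X)))
  out <- data.frame(person_id = persons, raw = NA_real_, raw_max = NA_real_,
                    measure = NA_real_, se = NA_real_,
                    extreme = NA, defined = FALSE)
  for (j in seq_len(nrow(X))) {
    oj <- !is.na(X[j, ]) & !is.na(difficulty)
    if (!any(oj)) next
    rj <- sum(X[j, oj] - 1L)
    rmx <- (m - 1L) * sum(oj)
    extreme <- rj <= 0L || rj >= rmx
    target <- if (rj <= 0L) adjustment
              else if (rj >= rmx) rmx - adjustment else rj
    sol <- solve_measure(target, difficulty[oj], thresholds)
    out$raw[j] <- rj; out$raw_max[j] <- rmx
    out$measure[j] <- sol$measure; out$se[j] <- sol$se
    out$extreme[j] <- extreme; out$defined[j] <- TRUE
  }
  out
}
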