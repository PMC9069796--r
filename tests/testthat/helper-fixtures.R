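# Shared fixtures and independent oracles for the suite.

# Small clean simulation used by several files.
clean_sim <- function(n = 500, I = 20, m = 6, seed = 101, ...) {
  simulate_responses(sim_spec(n, I, m, seed = seed, ...))
}

# Write a response matrix to a temp CSV and return the path.
tmp_csv <- function(rm) {
  path <- tempfile(fileext = ".csv")
  write_responses(rm, path)
  path
}

# Independent oracle for the dichotomous Rasch joint MLE: exhaustive
# coordinate-wise grid ascent of the joint log-likelihood on a 0.01-logit
# grid, no derivatives. X is a 0/1 matrix with no extreme rows/columns.
grid_jmle_dichotomous <- function(X, grid = seq(-4, 4, by = 0.01)) {
  n <- nrow(X); I <- ncol(X)
  ll_person <- function(c, d, x) sum(x * (c - d) - log1p(exp(c - d)))
  C <- rep(0, n); D <- rep(0, I)
  for (sweep in 1:100) {
    old <- c(C, D)
    for (j in 1:n) {
      lls <- vapply(grid, function(c) ll_person(c, D, X[j, ]), numeric(1))
      C[j] <- grid[which.max(lls)]
    }
    for (i in 1:I) {
      lls <- vapply(grid, function(d) ll_person(C, d, X[, i]), numeric(1))
      D[i] <- grid[which.max(lls)]
    }
    if (max(abs(c(C, D) - old)) < 1e-9) break
  }
  mu <- mean(D)
  list(C = C - mu, D = D - mu)
}

# Closed-form unnormalized RSM category weights for a scalar encounter,
# computed by direct enumeration (independent of rsm_category_probs).
enum_rsm_probs <- function(theta, F) {
  m <- length(F) + 1
  w <- numeric(m)
  w[1] <- 1
  for (k in 2:m) w[k] <- w[k - 1] * exp(theta - F[k - 1])
  w / sum(w)
}
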