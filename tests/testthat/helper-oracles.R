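# Independent oracles used across the test files.  These are deliberately
# naive (enumeration, quadrature, 1-D optimization) and share no code with
# the estimation paths they check.

# Exact weighted check-loss regression by basic-solution enumeration: some
# optimum interpolates p observations, so scanning all p-subsets of rows is
# exhaustive for small problems.
enum_check_regression <- function(X, y, w = rep(1, length(y)), tau = 0.5) {
  n <- nrow(X)
  p <- ncol(X)
  best <- Inf
  best_beta <- NULL
  idx <- utils::combn(n, p)
  for (k in seq_len(ncol(idx))) {
    Xi <- X[idx[, k], , drop = FALSE]
    if (abs(det(Xi)) < 1e-10) next
    b <- solve(Xi, y[idx[, k]])
    obj <- sum(w * check_loss(y - as.numeric(X %*% b), tau))
    if (obj < best) {
      best <- obj
      best_beta <- b
    }
  }
  list(coefficients = best_beta, objective = best)
}

# Log joint density of (y_i, b) for a single random effect, vectorized in b.
.quad_logjoint <- function(b, o, z1, sigma, psi11, tau) {
  sapply(b, function(bb) {
    sum(ald_logpdf(o - z1 * bb, 0, sigma, tau)) +
      stats::dnorm(bb, 0, sqrt(psi11), log = TRUE)
  })
}

# Fine deterministic quadrature of the joint density: a coarse scan locates
# the mode and effective support (log-density within 45 of the maximum), a
# dense trapezoid grid integrates over it.  Returns the grid, stabilized
# density values and the log normalizing shift.
.quad_grid <- function(o, z1, sigma, psi11, tau, half = 12, n_fine = 20001) {
  w <- sqrt(psi11)
  coarse <- seq(-half * w, half * w, length.out = 2001)
  lc <- .quad_logjoint(coarse, o, z1, sigma, psi11, tau)
  keep <- range(coarse[lc > max(lc) - 45])
  pad <- diff(keep) * 0.05 + 1e-8
  grid <- seq(keep[1] - pad, keep[2] + pad, length.out = n_fine)
  lg <- .quad_logjoint(grid, o, z1, sigma, psi11, tau)
  m0 <- max(lg)
  list(grid = grid, dens = exp(lg - m0), m0 = m0, h = grid[2] - grid[1])
}

.trapz <- function(h, v) h * (sum(v) - (v[1] + v[length(v)]) / 2)

# Marginal log-likelihood oracle for a single subject with one random
# effect, by quadrature over b.
quad_subject_loglik <- function(y, X, Z, beta, sigma, psi, tau) {
  stopifnot(ncol(Z) == 1)
  o <- y - as.numeric(X %*% beta)
  q <- .quad_grid(o, Z[, 1], sigma, psi[1, 1], tau)
  q$m0 + log(.trapz(q$h, q$dens))
}

# Conditional posterior mean of a single random effect by quadrature.
quad_subject_postmean <- function(y, X, Z, beta, sigma, psi, tau) {
  o <- y - as.numeric(X %*% beta)
  q <- .quad_grid(o, Z[, 1], sigma, psi[1, 1], tau)
  .trapz(q$h, q$grid * q$dens) / .trapz(q$h, q$dens)
}

# Small balanced panel with a single random intercept and known truth.
make_small_panel <- function(n_subj = 30, n_i = 8, beta = c(2, 0.5),
                             sigma = 0.6, psi11 = 0.8, tau = 0.5, seed = 1) {
  set.seed(seed)
  subj <- rep(sprintf("P%02d", seq_len(n_subj)), each = n_i)
  tim <- rep(seq_len(n_i) - 1, n_subj)
  b <- rnorm(n_subj, 0, sqrt(psi11))
  y <- beta[1] + beta[2] * tim + rep(b, each = n_i) +
    ald_sample(n_subj * n_i, 0, sigma, tau)
  ds <- longitudinal_dataset(data.frame(subject_id = subj, time = tim,
                                        response = y))
  attr(ds, "b_true") <- b
  ds
}

# statsmodels QuantReg (through the system python) as an independent
# large-problem quantile-regression oracle; returns its attained objective.
python_quantreg_objective <- function(X, y, tau) {
  csv <- tempfile(fileext = ".csv")
  df <- as.data.frame(X)
  names(df) <- paste0("x", seq_len(ncol(X)))
  df$y <- y
  utils::write.csv(df, csv, row.names = FALSE)
  script <- system.file("oracle", "quantreg_oracle.py", package = "qrsaem")
  out <- suppressWarnings(system2("python", c(script, csv, format(tau, digits = 10)),
                                  stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) return(NULL)
  as.numeric(out[length(out)])
}
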