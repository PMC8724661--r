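#' SAEM configuration
#'
#' Tuning parameters of the stochastic approximation EM run.  The smoothing
#' weights follow the two-phase schedule of [delta_schedule()]: no memory for
#' the first `c * W` iterations, then weights `1/(k - c*W)` that average the
#' simulated-data batches.
#'
#' @param W maximum number of iterations (>= 2).
#' @param c cut point in (0, 1): fraction of initial iterations run without
#'   memory.
#' @param m Markov-chain draws kept per subject per iteration; values above
#'   20 trigger a warning (little is gained beyond small simulation sizes).
#' @param burn_in discarded Metropolis-Hastings steps per subject per
#'   iteration before the `m` retained draws.
#' @param mh_proposal_scale initial random-walk proposal scale, multiplying
#'   the Cholesky factor of the current random-effects covariance.
#' @param tune_proposal if `TRUE`, the proposal scale is adapted during the
#'   memory phase toward a 20-40\% acceptance rate, then frozen.
#' @param pool_weight_floor pool entries whose smoothing weight falls below
#'   this floor are pruned.
#' @param convergence_tol,convergence_window early stop when the maximum
#'   relative parameter change stays below `convergence_tol` for
#'   `convergence_window` consecutive iterations.
#' @param sigma_floor lower clamp for the ALD scale.
#' @param seed integer seed controlling every random element of the fit.
#' @return a list of class `saem_config`.
#' @export
saem_config <- function(W = 500L, c = 0.25, m = 20L, burn_in = 10L,
                        mh_proposal_scale = 1, tune_proposal = TRUE,
                        pool_weight_floor = 1e-4,
                        convergence_tol = 1e-4, convergence_window = 10L,
                        sigma_floor = 1e-8, seed = 1L) {
  stopifnot(W >= 2, c > 0, c < 1, m >= 1, burn_in >= 0,
            mh_proposal_scale > 0, pool_weight_floor > 0,
            convergence_tol > 0, convergence_window >= 1, sigma_floor > 0)
  if (m > 20) warning("`m` > 20: SAEM is designed for small simulation sizes")
  structure(list(W = as.integer(W), c = c, m = as.integer(m),
                 burn_in = as.integer(burn_in),
                 mh_proposal_scale = mh_proposal_scale,
                 tune_proposal = tune_proposal,
                 pool_weight_floor = pool_weight_floor,
                 convergence_tol = convergence_tol,
                 convergence_window = as.integer(convergence_window),
                 sigma_floor = sigma_floor, seed = as.integer(seed)),
            class = "saem_config")
}

#' SAEM smoothing-weight schedule
#'
#' Piecewise schedule \eqn{\delta_k = 1} for \eqn{1 \le k \le cW} (no
#' memory) and \eqn{\delta_k = 1/(k - cW)} for \eqn{cW < k \le W}.
#'
#' @param k iteration index, `1 <= k <= W`.
#' @param c cut point in (0, 1).
#' @param W maximum number of iterations.
#' @return the smoothing weight in (0, 1].
#' @examples
#' delta_schedule(10, 0.25, 400)   # 1
#' delta_schedule(150, 0.25, 400)  # 0.02
#' @export
delta_schedule <- function(k, c, W) {
  stopifnot(c > 0, c < 1, W >= 1)
  if (any(k < 1) || any(k > W)) stop("`k` must lie in [1, W]", call. = FALSE)
  # for non-integer cW the reciprocal exceeds 1 just past the cut; clamp so
  # the schedule stays a nonincreasing sequence of smoothing weights
  ifelse(k <= c * W, 1, pmin(1, 1 / (k - c * W)))
}

#' Stochastic-approximation update
#'
#' The smoothing recursion `S_k = S_{k-1} + delta * (batch - S_{k-1})`:
#' `delta = 1` returns the batch (memoryless phase), `delta = 0` keeps the
#' previous accumulator.
#'
#' @param prev,batch accumulators of identical shape (numeric vector, matrix
#'   or array).
#' @param delta smoothing weight in `[0, 1]`.
#' @return the updated accumulator.
#' @export
sa_update <- function(prev, batch, delta) {
  if (!identical(dim(prev), dim(batch)) || length(prev) != length(batch))
    stop("shape mismatch between `prev` and `batch`", call. = FALSE)
  prev + delta * (batch - prev)
}

#' Complete-data log-likelihood of one subject
#'
#' \eqn{\sum_j [\log\{\tau(1-\tau)\} - \log\sigma -
#' \rho_\tau((y_{ij} - x_{ij}'\beta - z_{ij}'b)/\sigma)] + \log N_r(b; 0, \Psi)}.
#'
#' @param y,X,Z the subject's responses and design matrices (possibly with
#'   zero rows, in which case only the Gaussian prior term remains).
#' @param b random-effect vector of length `r`.
#' @param beta,sigma,psi,tau model parameters.
#' @return a single log-likelihood value.
#' @export
complete_loglik <- function(y, X, Z, b, beta, sigma, psi, tau) {
  .check_tau(tau)
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  ald <- if (length(y)) {
    res <- y - as.numeric(X %*% beta) - as.numeric(Z %*% b)
    sum(ald_logpdf(res, 0, sigma, tau))
  } else 0
  ald + .dmvnorm_log(b, psi)
}

# log N_r(b; 0, Psi) via Cholesky; errors on non-SPD Psi
.dmvnorm_log <- function(b, psi) {
  r <- length(b)
  if (r == 0) return(0)
  L <- tryCatch(t(chol(psi)), error = function(e)
    stop("random-effects covariance is not positive definite", call. = FALSE))
  u <- forwardsolve(L, b)
  -0.5 * r * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(u^2)
}

#' Initialize SAEM parameters
#'
#' Fixed effects from a fixed-effects-only check-loss regression, the ALD
#' scale from the mean check loss of its residuals, and the random-effects
#' covariance as `0.1 * sigma0^2 * I` (scaled so the whole algorithm is
#' equivariant under rescaling of the response).
#'
#' @param designs a `qrsaem_designs` object.
#' @param tau quantile level.
#' @param sigma_floor lower clamp for the scale.
#' @return a list of class `qrsaem_theta` with elements `beta`, `sigma`,
#'   `psi` and `alpha` (the distinct elements of `psi`, by column within the
#'   lower triangle).
#' @export
initialize_params <- function(designs, tau, sigma_floor = 1e-8) {
  beta0 <- weighted_check_regression(designs$X, designs$y, tau = tau)
  res <- designs$y - as.numeric(designs$X %*% beta0)
  sigma0 <- max(mean(check_loss(res, tau)), sigma_floor)
  psi0 <- diag(0.1 * sigma0^2, designs$r)
  .theta(as.numeric(beta0), sigma0, psi0, designs$fixed, designs$random)
}

.theta <- function(beta, sigma, psi, fixed = NULL, random = NULL) {
  names(beta) <- fixed
  if (length(random)) dimnames(psi) <- list(random, random)
  structure(list(beta = beta, sigma = sigma, psi = psi,
                 alpha = psi[lower.tri(psi, diag = TRUE)]),
            class = "qrsaem_theta")
}

.theta_vec <- function(th) c(th$beta, th$sigma, th$alpha)

#' Sample a subject's random effects from their conditional distribution
#'
#' Random-walk Metropolis-Hastings targeting
#' \eqn{f(b | y_i, \theta) \propto \exp\{-\sum_j
#' \rho_\tau((y_{ij} - x_{ij}'\beta - z_{ij}'b)/\sigma)\} N_r(b; 0, \Psi)},
#' with proposal \eqn{N(b, \mathrm{scale}^2 \Psi)} — the E-step draw of the
#' SAEM loop, exposed for diagnostics.  Draws are reproducible under
#' `set.seed()`.
#'
#' @param y,X,Z the subject's responses and design matrices (zero rows
#'   allowed, in which case the chain samples the Gaussian prior).
#' @param theta a `qrsaem_theta` parameter state (`beta`, `sigma`, `psi`).
#' @param tau quantile level.
#' @param m number of retained draws.
#' @param burn_in discarded leading steps.
#' @param scale proposal scale factor.
#' @param start chain starting value (defaults to zero).
#' @return a list with `draws` (m x r matrix), `acceptance_rate`, and the
#'   chain's final state `last`.
#' @export
mh_sample_subject <- function(y, X, Z, theta, tau, m = 20L, burn_in = 10L,
                              scale = 1, start = NULL) {
  .check_tau(tau)
  Z <- as.matrix(Z)
  r <- ncol(Z)
  if (is.null(start)) start <- rep(0, r)
  stopifnot(length(start) == r, nrow(Z) == length(y))
  resid_fixed <- if (length(y)) y - as.numeric(as.matrix(X) %*% theta$beta)
                 else numeric(0)
  es <- mh_estep_cpp(resid_fixed, Z, 0L, length(y), matrix(start, 1, r),
                     t(chol(theta$psi)), theta$sigma, tau,
                     as.integer(m), as.integer(burn_in), scale)
  if (mean(es$accept) == 0) warning("all proposals rejected")
  list(draws = t(matrix(es$draws[, , 1], r, m)),
       acceptance_rate = as.numeric(es$accept),
       last = drop(es$last))
}

#' M-step for the fixed effects
#'
#' Minimizes the pool-weighted check loss
#' \eqn{\sum_{(d)} w_d \sum_{ij} \rho_\tau(y_{ij} - x_{ij}'\beta -
#' z_{ij}'b^{(d)}_i)} by weighted check regression on the stacked
#' pseudo-responses (one column per pooled draw).
#'
#' @param X fixed design (N x p).
#' @param pseudo_y matrix (N x D) of pseudo-responses `y - Z b` for the `D`
#'   pooled draws.
#' @param weights pool weights, one per column of `pseudo_y`.
#' @param tau quantile level.
#' @return coefficient vector of length `p` (attribute `"objective"` holds
#'   the attained weighted loss).
#' @export
mstep_beta <- function(X, pseudo_y, weights, tau) {
  pseudo_y <- as.matrix(pseudo_y)
  if (length(weights) != ncol(pseudo_y))
    stop("one weight per pooled draw column required", call. = FALSE)
  if (!sum(weights) > 0) stop("empty pool", call. = FALSE)
  if (qr(X)$rank < ncol(X)) stop("singular design", call. = FALSE)
  fit <- rqfn_multi_cpp(X, pseudo_y, rep(1, nrow(X)), weights, tau)
  beta <- drop(fit$coefficients)
  names(beta) <- colnames(X)
  attr(beta, "objective") <- fit$objective
  beta
}

#' M-step for the ALD scale
#'
#' Closed-form maximizer of the complete-data ALD likelihood in
#' \eqn{\sigma} for fixed residuals: the pool-weighted mean per-observation
#' check loss.  Weights are normalized internally, so rescaling all weights
#' leaves the result unchanged.
#'
#' @param residuals matrix (N x D) of pooled residuals
#'   `y - X beta - Z b^(d)` (a plain vector is treated as one column).
#' @param weights pool weights, one per column.
#' @param tau quantile level.
#' @param sigma_floor returned when the weighted mean loss underflows it.
#' @return the updated scale, a positive number.
#' @export
mstep_sigma <- function(residuals, weights = NULL, tau = 0.5, sigma_floor = 1e-8) {
  residuals <- as.matrix(residuals)
  if (is.null(weights)) weights <- rep(1, ncol(residuals))
  if (length(weights) != ncol(residuals))
    stop("one weight per residual column required", call. = FALSE)
  tw <- sum(weights)
  if (!tw > 0) stop("zero total weight", call. = FALSE)
  rho <- check_loss(residuals, tau)
  max(sum(colSums(rho) * (weights / tw)) / nrow(residuals), sigma_floor)
}

#' M-step for the random-effects covariance
#'
#' Average of the smoothed per-subject second moments, symmetrized and
#' projected to the positive-definite cone by flooring eigenvalues at
#' `1e-8`.
#'
#' @param S2 array (r x r x n) of smoothed second moments, or a list of
#'   r x r matrices.
#' @return a symmetric positive-definite r x r matrix.
#' @export
mstep_psi <- function(S2) {
  if (is.list(S2)) S2 <- array(unlist(S2), dim = c(dim(S2[[1]]), length(S2)))
  psi <- apply(S2, c(1, 2), mean)
  psi <- (psi + t(psi)) / 2
  e <- eigen(psi, symmetric = TRUE)
  if (any(e$values < 1e-8))
    psi <- e$vectors %*% diag(pmax(e$values, 1e-8), nrow(psi)) %*% t(e$vectors)
  (psi + t(psi)) / 2
}

# pool-weighted complete-data negative objective (ALD part on the draw pool +
# Gaussian part through the smoothed second moments); the M-step minimizes it
.pool_objective <- function(X, pseudo_y, weights, beta, sigma, psi, S2, tau, N, n) {
  res <- pseudo_y - as.numeric(X %*% beta)
  w <- weights / sum(weights)
  ald <- N * log(sigma) - N * (log(tau) + log1p(-tau)) +
    sum(colSums(check_loss(res, tau)) * w) / sigma
  r <- nrow(psi)
  gauss <- if (r > 0) {
    S2bar <- apply(S2, c(1, 2), mean)
    0.5 * n * (r * log(2 * pi) + determinant(psi)$modulus[1]) +
      0.5 * n * sum(diag(solve(psi, S2bar)))
  } else 0
  ald + gauss
}

#' Fit a quantile regression linear mixed model by SAEM
#'
#' Maximum-likelihood estimation of \eqn{(\beta_\tau, \sigma, \Psi)} in the
#' quantile linear mixed model with asymmetric Laplace errors.  Each
#' iteration (i) simulates the subject random effects by random-walk
#' Metropolis-Hastings warm-started at the previous iteration's final state,
#' (ii) smooths a weighted pool of simulated draws and the per-subject
#' second moments with the [delta_schedule()] weights, and (iii) maximizes
#' the smoothed complete-data likelihood: weighted check regression for
#' \eqn{\beta}, the closed-form weighted mean check loss for \eqn{\sigma},
#' and the averaged second moments for \eqn{\Psi}.
#'
#' With an empty random structure the SAEM loop is bypassed and the model is
#' solved directly as a fixed-effects quantile regression.
#'
#' @param ds a `qrsaem_data` object.
#' @param spec a `qrsaem_spec` object (its `tau` is used).
#' @param cfg a [saem_config()].
#' @param compute_se compute Louis-type standard errors (default `TRUE`).
#' @param loglik_draws importance-sampling draws per subject for the marginal
#'   log-likelihood.
#' @param count_sigma whether the scale parameter is counted in `n_params`
#'   for information criteria.
#' @return an object of class `qrsaem_fit`; see [fit_result_fields].
#' @export
fit_qrlmm <- function(ds, spec, cfg = saem_config(), compute_se = TRUE,
                      loglik_draws = 1000L, count_sigma = TRUE) {
  stopifnot(inherits(ds, "qrsaem_data"), inherits(spec, "qrsaem_spec"),
            inherits(cfg, "saem_config"))
  tau <- spec$tau
  if (tau < 0.01 || tau > 0.99) stop("`tau` restricted to [0.01, 0.99]", call. = FALSE)
  if (tau < 0.05 || tau > 0.95)
    warning("extreme quantile level; estimates may be unstable")
  db <- build_designs(ds, spec)
  set.seed(cfg$seed)

  if (db$r == 0) return(.fit_fixed_only(db, cfg, compute_se, count_sigma))

  theta <- initialize_params(db, tau, cfg$sigma_floor)
  n <- db$n; N <- db$N; r <- db$r; m <- cfg$m
  subj_of_row <- rep(seq_len(n), db$subj_len)
  bcur <- matrix(0, n, r)
  scale <- cfg$mh_proposal_scale

  memlen <- floor(cfg$c * cfg$W)
  maxD <- m * (cfg$W - memlen + 1L)
  pool_y <- matrix(NA_real_, N, maxD)   # pseudo-responses y - Z b, one col/draw
  pool_w <- numeric(0)
  S2 <- array(0, dim = c(r, r, n))
  S1 <- matrix(0, n, r)

  traces <- vector("list", cfg$W)
  ok_run <- 0L
  converged <- FALSE
  last_k <- cfg$W

  for (k in seq_len(cfg$W)) {
    delta <- delta_schedule(k, cfg$c, cfg$W)

    resid_fixed <- db$y - as.numeric(db$X %*% theta$beta)
    es <- mh_estep_cpp(resid_fixed, db$Z, db$subj_start, db$subj_len,
                       bcur, t(chol(theta$psi)), theta$sigma, tau,
                       m, cfg$burn_in, scale)
    bcur <- es$last
    acc <- mean(es$accept)
    if (cfg$tune_proposal && k <= cfg$c * cfg$W) {
      scale <- scale * exp(0.8 * (acc - 0.3))
      scale <- min(max(scale, 1e-3), 1e3)
    }
    if (acc == 0) warning(sprintf("iteration %d: all MH proposals rejected", k))

    # new batch of pseudo-response columns and batch moments
    nb <- matrix(NA_real_, N, m)
    bS2 <- array(0, dim = c(r, r, n))
    bS1 <- matrix(0, n, r)
    for (l in seq_len(m)) {
      bmat <- t(es$draws[, l, , drop = FALSE][, 1, ])  # n x r
      if (r == 1) bmat <- matrix(es$draws[1, l, ], n, 1)
      nb[, l] <- db$y - rowSums(db$Z * bmat[subj_of_row, , drop = FALSE])
      bS1 <- bS1 + bmat / m
      for (i in seq_len(n)) bS2[, , i] <- bS2[, , i] + tcrossprod(bmat[i, ]) / m
    }

    # stochastic approximation: decay old pool entries, admit the new batch
    D_old <- length(pool_w)
    if (D_old > 0) pool_w <- pool_w * (1 - delta)
    pool_y[, D_old + seq_len(m)] <- nb
    pool_w <- c(pool_w, rep(delta / m, m))
    keep <- pool_w >= cfg$pool_weight_floor
    if (!all(keep)) {
      D_new <- sum(keep)
      pool_y[, seq_len(D_new)] <- pool_y[, which(keep), drop = FALSE]
      pool_w <- pool_w[keep]
    }
    pool_w <- pool_w / sum(pool_w)
    D <- length(pool_w)
    Yp <- pool_y[, seq_len(D), drop = FALSE]

    S2 <- sa_update(S2, bS2, delta)
    S1 <- sa_update(S1, bS1, delta)

    obj_pre <- .pool_objective(db$X, Yp, pool_w, theta$beta, theta$sigma,
                               theta$psi, S2, tau, N, n)

    beta_new <- mstep_beta(db$X, Yp, pool_w, tau)
    res_pool <- Yp - as.numeric(db$X %*% beta_new)
    sigma_new <- mstep_sigma(res_pool, pool_w, tau, cfg$sigma_floor)
    psi_new <- mstep_psi(S2)
    theta_new <- .theta(as.numeric(beta_new), sigma_new, psi_new,
                        db$fixed, db$random)

    obj_post <- .pool_objective(db$X, Yp, pool_w, theta_new$beta,
                                theta_new$sigma, theta_new$psi, S2, tau, N, n)

    relchg <- max(abs(.theta_vec(theta_new) - .theta_vec(theta)) /
                    (abs(.theta_vec(theta)) + 1e-3))
    theta <- theta_new

    traces[[k]] <- c(iteration = k, delta = delta,
                     stats::setNames(theta$beta, paste0("beta_", db$fixed)),
                     sigma = theta$sigma,
                     stats::setNames(theta$alpha, paste0("alpha_", seq_along(theta$alpha))),
                     accept = acc, mh_scale = scale, pool_batches = D / m,
                     obj_pre = obj_pre, obj_post = obj_post, rel_change = relchg)

    if (k > cfg$c * cfg$W && relchg < cfg$convergence_tol) {
      ok_run <- ok_run + 1L
      if (ok_run >= cfg$convergence_window) { converged <- TRUE; last_k <- k; break }
    } else ok_run <- 0L
  }

  traces <- as.data.frame(do.call(rbind, traces[seq_len(last_k)]))
  rownames(S1) <- db$subject

  # smoothed posterior covariances, V_i = E[b b'] - E[b] E[b]'
  Vpost <- array(0, dim = c(r, r, n))
  for (i in seq_len(n)) Vpost[, , i] <- S2[, , i] - tcrossprod(S1[i, ])
  ll <- marginal_loglik(ds, spec, theta, M = loglik_draws,
                        subject_effects = S1, subject_effect_cov = Vpost)
  n_params <- db$p + r * (r + 1) / 2 + as.integer(count_sigma)
  ic <- information_criteria(ll, n_params, N)

  fit <- structure(list(theta = theta, tau = tau, loglik = ll,
                        n_params = n_params, N = N, n_subjects = n,
                        se = NULL, ci_low = NULL, ci_high = NULL,
                        AIC = ic[["AIC"]], BIC = ic[["BIC"]], HQC = ic[["HQC"]],
                        traces = traces, converged = converged,
                        iterations = last_k, seed = cfg$seed,
                        subject_effects = S1, mh_scale = scale,
                        spec = spec, config = cfg, designs = db,
                        count_sigma = count_sigma),
                   class = "qrsaem_fit")
  if (compute_se) fit <- .attach_se(fit, standard_errors(fit))
  fit
}

# degenerate no-random-effects fit: direct check regression, exact loglik
.fit_fixed_only <- function(db, cfg, compute_se, count_sigma) {
  beta <- weighted_check_regression(db$X, db$y, tau = db$tau)
  res <- db$y - as.numeric(db$X %*% beta)
  sigma <- max(mean(check_loss(res, db$tau)), cfg$sigma_floor)
  theta <- .theta(as.numeric(beta), sigma, matrix(0, 0, 0), db$fixed, NULL)
  ll <- sum(ald_logpdf(res, 0, sigma, db$tau))
  n_params <- db$p + as.integer(count_sigma)
  ic <- information_criteria(ll, n_params, db$N)
  fit <- structure(list(theta = theta, tau = db$tau, loglik = ll,
                        n_params = n_params, N = db$N, n_subjects = db$n,
                        se = NULL, ci_low = NULL, ci_high = NULL,
                        AIC = ic[["AIC"]], BIC = ic[["BIC"]], HQC = ic[["HQC"]],
                        traces = NULL, converged = TRUE, iterations = 0L,
                        seed = cfg$seed,
                        subject_effects = matrix(0, db$n, 0),
                        objective = attr(beta, "objective"),
                        spec = NULL, config = cfg, designs = db,
                        count_sigma = count_sigma),
                   class = "qrsaem_fit")
  if (compute_se) fit <- .attach_se(fit, standard_errors(fit))
  fit
}

.attach_se <- function(fit, se) {
  fit$se <- se
  fit$ci_low <- fit$theta$beta - 1.96 * se
  fit$ci_high <- fit$theta$beta + 1.96 * se
  fit
}

#' @export
print.qrsaem_fit <- function(x, ...) {
  cat(sprintf("Quantile linear mixed model (tau = %.2f), SAEM fit\n", x$tau))
  cat(sprintf("  %d subjects, %d observations, %s\n", x$n_subjects, x$N,
              if (x$converged) sprintf("converged in %d iterations", x$iterations)
              else sprintf("not converged after %d iterations", x$iterations)))
  est <- x$theta$beta
  tab <- data.frame(estimate = est)
  if (!is.null(x$se)) {
    tab$se <- x$se
    tab$ci_low <- x$ci_low
    tab$ci_high <- x$ci_high
  }
  print(round(tab, 4))
  cat(sprintf("  sigma = %.4f\n", x$theta$sigma))
  if (length(x$theta$alpha)) {
    cat("  random-effects covariance Psi:\n")
    print(round(x$theta$psi, 4))
  }
  cat(sprintf("  logLik = %.2f  AIC = %.2f  BIC = %.2f  HQC = %.2f\n",
              x$loglik, x$AIC, x$BIC, x$HQC))
  invisible(x)
}

#' Fields of a fitted QR-LMM
#'
#' A `qrsaem_fit` carries: `theta` (estimates `beta`, `sigma`, `psi`,
#' `alpha`), `tau`, the importance-sampled marginal `loglik`, `n_params`,
#' `N`, `se`/`ci_low`/`ci_high` (95\% normal bands), `AIC`/`BIC`/`HQC`,
#' per-iteration `traces` (parameters, smoothing weight, acceptance rate,
#' pool size, pre/post M-step objective), `converged`, `seed`, and
#' `subject_effects` (smoothed posterior means of the random effects).
#'
#' @name fit_result_fields
NULL

#' Export SAEM convergence traces
#'
#' Writes the per-iteration trace table (parameters, smoothing weight,
#' acceptance rates, objective) to CSV so convergence can also be judged
#' graphically.
#'
#' @param fit a `qrsaem_fit`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(fit, path) {
  if (is.null(fit$traces)) stop("fit has no SAEM traces", call. = FALSE)
  utils::write.csv(fit$traces, path, row.names = FALSE)
  invisible(path)
}
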