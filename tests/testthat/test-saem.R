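test_that("smoothing schedule follows the two-phase form", {
  expect_equal(delta_schedule(10, 0.25, 400), 1)
  expect_equal(delta_schedule(101, 0.25, 400), 1)
  expect_equal(delta_schedule(150, 0.25, 400), 0.02)
  # memoryless up to the cut, then exact reciprocal decay, nonincreasing
  for (c in c(0.1, 0.25, 0.6)) {
    for (W in c(20, 173)) {
      k <- seq_len(W)
      d <- delta_schedule(k, c, W)
      expect_true(all(d[k <= c * W] == 1))
      kp <- k[k > c * W]
      expect_equal(d[k > c * W], pmin(1, 1 / (kp - c * W)))
      expect_true(all(diff(d) <= 0))
    }
  }
  expect_error(delta_schedule(401, 0.25, 400), "k")
  expect_error(delta_schedule(0, 0.25, 400), "k")
})

test_that("stochastic approximation update is a convex combination", {
  expect_equal(sa_update(10, 20, 0.5), 15)
  expect_equal(sa_update(10, 20, 1), 20)
  expect_equal(sa_update(10, 20, 0), 10)
  A <- matrix(1:6, 2, 3)
  B <- matrix(7:12, 2, 3)
  expect_equal(sa_update(A, B, 0.25), A + 0.25 * (B - A))
  expect_error(sa_update(A, t(B), 0.5), "shape")
  expect_error(sa_update(1:3, 1:4, 0.5), "shape")
})

test_that("complete-data log-likelihood composes ALD and Gaussian parts", {
  set.seed(20)
  n_i <- 6
  X <- cbind(1, rnorm(n_i))
  Z <- cbind(1, runif(n_i))
  beta <- c(1, -0.5)
  psi <- matrix(c(1, 0.3, 0.3, 0.5), 2)
  b <- c(0.4, -0.2)
  y <- as.numeric(X %*% beta + Z %*% b) + rnorm(n_i)
  got <- complete_loglik(y, X, Z, b, beta, 0.7, psi, 0.3)
  # independent composition: ALD densities + multivariate normal density
  res <- y - as.numeric(X %*% beta) - as.numeric(Z %*% b)
  mvn <- -log(2 * pi) - 0.5 * log(det(psi)) -
    0.5 * as.numeric(t(b) %*% solve(psi) %*% b)
  expect_equal(got, sum(ald_logpdf(res, 0, 0.7, 0.3)) + mvn, tolerance = 1e-12)
  # no observations: just the Gaussian prior
  expect_equal(complete_loglik(numeric(0), X[0, ], Z[0, ], b, beta, 0.7, psi, 0.3),
               mvn, tolerance = 1e-12)
  # zero residuals at b = 0: the ALD mode value n_i times
  y0 <- as.numeric(X %*% beta)
  expect_equal(complete_loglik(y0, X, Z, c(0, 0), beta, 2, psi, 0.3),
               n_i * log(0.3 * 0.7 / 2) + .25 * 0 +
                 (-log(2 * pi) - 0.5 * log(det(psi))), tolerance = 1e-12)
  expect_error(complete_loglik(y, X, Z, b, beta, 0.7,
                               matrix(c(1, 2, 2, 1), 2), 0.3),
               "positive definite")
})

test_that("scale M-step matches 1-D likelihood maximization", {
  expect_equal(mstep_sigma(c(-1, 0, 2), tau = 0.5), 0.5)
  set.seed(21)
  for (tau in c(0.25, 0.5, 0.85)) {
    res <- matrix(rnorm(40 * 3, sd = 2), 40, 3)
    w <- runif(3)
    got <- mstep_sigma(res, w, tau)
    # oracle: maximize the pool-weighted ALD likelihood in sigma numerically
    obj <- function(s) sum(sapply(seq_len(3), function(d)
      (w[d] / sum(w)) * sum(ald_logpdf(res[, d], 0, s, tau))))
    num <- optimize(obj, c(1e-3, 30), maximum = TRUE, tol = 1e-12)$maximum
    expect_equal(got, num, tolerance = 1e-6)
    expect_gte(obj(got), obj(num) - 1e-8)
    # invariance to weight rescaling
    expect_equal(mstep_sigma(res, 17.3 * w, tau), got, tolerance = 1e-14)
  }
  expect_equal(mstep_sigma(rep(0, 10), tau = 0.5, sigma_floor = 1e-8), 1e-8)
  expect_error(mstep_sigma(matrix(1, 2, 2), c(0, 0), 0.5), "zero total weight")
})

test_that("covariance M-step averages smoothed moments onto the SPD cone", {
  S2 <- array(0, c(2, 2, 5))
  for (i in 1:5) S2[, , i] <- diag(2)
  expect_equal(mstep_psi(S2), diag(2))
  # hand-computed average of two exact moments
  A <- matrix(c(2, 0.5, 0.5, 1), 2)
  B <- matrix(c(1, -0.1, -0.1, 3), 2)
  got <- mstep_psi(list(A, B))
  expect_equal(got, (A + B) / 2)
  expect_identical(got, t(got))
  # rank-deficient input gets floored eigenvalues
  C <- tcrossprod(c(1, 1))
  flo <- mstep_psi(list(C))
  expect_true(all(eigen(flo, symmetric = TRUE)$values >= 1e-8 - 1e-12))
})

test_that("fixed-effect M-step reduces to direct regression at zero draws", {
  set.seed(22)
  n <- 60
  X <- cbind(1, rnorm(n), runif(n))
  y <- as.numeric(X %*% c(1, 2, -1)) + rnorm(n)
  # a pool holding a single all-zero draw leaves pseudo-responses = y
  b1 <- mstep_beta(X, cbind(y), 1, tau = 0.3)
  direct <- weighted_check_regression(X, y, tau = 0.3)
  expect_equal(attr(b1, "objective"), attr(direct, "objective"), tolerance = 1e-8)
  # two equally weighted copies of one pool entry = the entry itself
  b2 <- mstep_beta(X, cbind(y, y), c(0.5, 0.5), tau = 0.3)
  expect_equal(unname(b2), unname(b1), tolerance = 1e-6)
})

test_that("initialization is deterministic and respects the degenerate fit", {
  ds <- make_small_panel(seed = 23)
  db <- build_designs(ds, model_spec(fixed = c("intercept", "time"),
                                     random = "intercept"))
  th1 <- initialize_params(db, 0.5)
  th2 <- initialize_params(db, 0.5)
  expect_identical(th1, th2)
  expect_gt(th1$sigma, 0)
  expect_equal(th1$psi, diag(0.1 * th1$sigma^2, 1), ignore_attr = TRUE)
  # no-random-effects: beta0 is already the final degenerate answer
  db0 <- build_designs(ds, model_spec(fixed = c("intercept", "time"),
                                      random = character(0)))
  fit0 <- fit_qrlmm(ds, model_spec(fixed = c("intercept", "time"),
                                   random = character(0)),
                    saem_config(W = 10, seed = 1), compute_se = FALSE)
  expect_equal(unname(fit0$theta$beta),
               unname(initialize_params(db0, 0.5)$beta), tolerance = 1e-10)
})

test_that("conditional sampler recovers the prior when data carry no signal", {
  # a nearly flat likelihood (huge sigma) leaves the N(0, Psi) prior
  ds <- make_small_panel(n_subj = 4, n_i = 3, seed = 24)
  db <- build_designs(ds, model_spec(fixed = c("intercept", "time"),
                                     random = "intercept"))
  psi <- matrix(1.44, 1, 1)
  set.seed(25)
  es <- qrsaem:::mh_estep_cpp(db$y * 0, db$Z, db$subj_start, db$subj_len,
                              matrix(0, db$n, 1), t(chol(psi)),
                              1e6, 0.5, 4000L, 500L, 2)
  draws <- as.numeric(es$draws)
  expect_gt(mean(es$accept), 0)
  expect_lte(max(es$accept), 1)
  expect_lt(abs(sd(draws) - 1.2), 0.1)
  expect_lt(abs(mean(draws)), 0.1)
})

test_that("the subject sampler is reproducible and honours its contracts", {
  th <- qrsaem:::.theta(c(1, 0.2), 0.6, diag(c(1, 0.25)),
                        c("intercept", "time"), c("intercept", "time"))
  X <- cbind(1, 0:5)
  y <- 1 + 0.2 * (0:5) + rnorm(6)
  set.seed(61)
  a <- mh_sample_subject(y, X, X, th, 0.5, m = 50, burn_in = 10)
  set.seed(61)
  b <- mh_sample_subject(y, X, X, th, 0.5, m = 50, burn_in = 10)
  expect_identical(a, b)
  expect_equal(dim(a$draws), c(50, 2))
  expect_gt(a$acceptance_rate, 0)
  expect_lte(a$acceptance_rate, 1)
  # with no observations the chain samples the prior
  set.seed(62)
  p <- mh_sample_subject(numeric(0), matrix(0, 0, 2), matrix(0, 0, 2), th,
                         0.5, m = 20000, burn_in = 500, scale = 1.5)
  expect_lt(max(abs(cov(p$draws) - diag(c(1, 0.25)))), 0.08)
})

test_that("whole fits are reproducible from the seed", {
  ds <- make_small_panel(n_subj = 12, n_i = 5, seed = 26)
  sp <- model_spec(fixed = c("intercept", "time"), random = "intercept")
  cfg <- saem_config(W = 30, c = 0.3, m = 5, burn_in = 3, seed = 77,
                     convergence_window = 1000)
  f1 <- fit_qrlmm(ds, sp, cfg, compute_se = FALSE, loglik_draws = 100)
  f2 <- fit_qrlmm(ds, sp, cfg, compute_se = FALSE, loglik_draws = 100)
  expect_identical(f1$traces, f2$traces)
  expect_identical(f1$theta, f2$theta)
  expect_identical(as.numeric(f1$loglik), as.numeric(f2$loglik))
})

test_that("memoryless phase equals Monte Carlo EM on the current batch", {
  # with the cut point covering every iteration, delta_k = 1 throughout:
  # the pool must hold exactly the current batch and the smoothed moments
  # must equal the batch moments (an MCEM iteration)
  ds <- make_small_panel(n_subj = 10, n_i = 4, seed = 27)
  sp <- model_spec(fixed = c("intercept", "time"), random = "intercept")
  cfg <- saem_config(W = 12, c = 0.99, m = 4, burn_in = 2, seed = 5,
                     convergence_window = 1000)
  f <- fit_qrlmm(ds, sp, cfg, compute_se = FALSE, loglik_draws = 100)
  expect_true(all(f$traces$delta == 1))
  expect_true(all(f$traces$pool_batches == 1))
})

test_that("each M-step improves the pooled complete-data objective", {
  ds <- make_small_panel(n_subj = 15, n_i = 6, seed = 28)
  sp <- model_spec(fixed = c("intercept", "time"), random = "intercept")
  cfg <- saem_config(W = 40, c = 0.25, m = 5, burn_in = 3, seed = 6,
                     convergence_window = 1000)
  f <- fit_qrlmm(ds, sp, cfg, compute_se = FALSE, loglik_draws = 100)
  expect_true(all(f$traces$obj_post <= f$traces$obj_pre + 1e-6))
})

test_that("fits are equivariant under shifting and scaling the response", {
  ds <- make_small_panel(n_subj = 12, n_i = 5, seed = 29)
  sp <- model_spec(fixed = c("intercept", "time"), random = "intercept")
  cfg <- saem_config(W = 30, c = 0.3, m = 5, burn_in = 3, seed = 8,
                     convergence_window = 1000)
  base <- fit_qrlmm(ds, sp, cfg, compute_se = FALSE, loglik_draws = 100)
  shifted <- ds
  shifted$response <- ds$response + 11.5
  fs <- fit_qrlmm(shifted, sp, cfg, compute_se = FALSE, loglik_draws = 100)
  expect_equal(unname(fs$theta$beta[1]), unname(base$theta$beta[1]) + 11.5,
               tolerance = 1e-5)
  expect_equal(unname(fs$theta$beta[2]), unname(base$theta$beta[2]),
               tolerance = 1e-5)
  scaled <- ds
  scaled$response <- ds$response * 3
  fc <- fit_qrlmm(scaled, sp, cfg, compute_se = FALSE, loglik_draws = 100)
  expect_equal(unname(fc$theta$beta), unname(base$theta$beta) * 3,
               tolerance = 1e-4)
  expect_equal(fc$theta$sigma, base$theta$sigma * 3, tolerance = 1e-4)
})

test_that("the degenerate model equals the LP quantile regression", {
  ds <- make_small_panel(n_subj = 20, n_i = 6, psi11 = 1e-10, seed = 30)
  sp0 <- model_spec(fixed = c("intercept", "time"), random = character(0))
  f <- fit_qrlmm(ds, sp0, saem_config(W = 10, seed = 2), compute_se = FALSE)
  db <- build_designs(ds, sp0)
  direct <- weighted_check_regression(db$X, db$y, tau = 0.5)
  expect_equal(f$objective, attr(direct, "objective"),
               tolerance = 1e-6 * abs(attr(direct, "objective")))
  expect_true(f$converged)
})

test_that("smoothed posterior means track exact conditional means", {
  # single random intercept: quadrature gives the exact posterior mean
  ds <- make_small_panel(n_subj = 25, n_i = 12, sigma = 0.5, psi11 = 1,
                         seed = 31)
  sp <- model_spec(fixed = c("intercept", "time"), random = "intercept")
  cfg <- saem_config(W = 100, c = 0.2, m = 10, burn_in = 5, seed = 9,
                     convergence_window = 1000)
  f <- fit_qrlmm(ds, sp, cfg, compute_se = FALSE, loglik_draws = 100)
  db <- build_designs(ds, sp)
  exact <- sapply(seq_len(db$n), function(i) {
    rows <- db$subj_start[i] + seq_len(db$subj_len[i])
    quad_subject_postmean(db$y[rows], db$X[rows, , drop = FALSE],
                          db$Z[rows, , drop = FALSE], f$theta$beta,
                          f$theta$sigma, f$theta$psi, 0.5)
  })
  spread <- sd(exact)
  err <- abs(f$subject_effects[, 1] - exact)
  expect_lt(mean(err), 0.02 * spread)
  expect_gt(cor(f$subject_effects[, 1], exact), 0.99)
})
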