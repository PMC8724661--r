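test_that("information criteria implement the three penalties", {
  set.seed(40)
  for (i in 1:5) {
    ll <- rnorm(1, -500, 100)
    p <- sample(1:12, 1)
    N <- sample(50:5000, 1)
    ic <- information_criteria(ll, p, N)
    expect_equal(unname(ic["AIC"]), -2 * ll + 2 * p)
    expect_equal(unname(ic["BIC"]), -2 * ll + p * log(N))
    expect_equal(unname(ic["HQC"]), -2 * ll + 2 * p * log(log(N)))
  }
  expect_equal(unname(information_criteria(0, 0, 10)), c(0, 0, 0))
  expect_error(information_criteria(0, 1, 2), "HQC")
})

test_that("marginal likelihood is exact without random effects", {
  ds <- make_small_panel(n_subj = 10, n_i = 4, seed = 41)
  sp <- model_spec(fixed = c("intercept", "time"), random = character(0))
  db <- build_designs(ds, sp)
  th <- initialize_params(db, 0.5)
  ll <- marginal_loglik(ds, sp, th, M = 100)
  expect_equal(as.numeric(ll),
               sum(ald_logpdf(db$y - as.numeric(db$X %*% th$beta), 0,
                              th$sigma, 0.5)))
  expect_equal(attr(ll, "mc_se"), 0)
})

test_that("importance sampling matches quadrature on single random effects", {
  ds <- make_small_panel(n_subj = 12, n_i = 6, sigma = 0.5, psi11 = 0.6,
                         seed = 42)
  sp <- model_spec(fixed = c("intercept", "time"), random = "intercept",
                   tau = 0.5)
  db <- build_designs(ds, sp)
  th <- qrsaem:::.theta(c(2, 0.5), 0.5, matrix(0.6, 1, 1),
                        c("intercept", "time"), "intercept")
  ll <- marginal_loglik(ds, sp, th, M = 4000, seed = 43)
  exact <- sum(sapply(seq_len(db$n), function(i) {
    rows <- db$subj_start[i] + seq_len(db$subj_len[i])
    quad_subject_loglik(db$y[rows], db$X[rows, , drop = FALSE],
                        db$Z[rows, , drop = FALSE], th$beta, th$sigma,
                        th$psi, 0.5)
  }))
  expect_lt(abs(as.numeric(ll) - exact) / abs(exact), 0.005)
  # doubling M moves the estimate by less than the reported MC error
  ll2 <- marginal_loglik(ds, sp, th, M = 8000, seed = 44)
  expect_lt(abs(as.numeric(ll2) - as.numeric(ll)),
            3 * (attr(ll, "mc_se") + attr(ll2, "mc_se")) + 0.5)
})

test_that("Louis standard errors approach the quantile-regression sandwich", {
  # no random effects, ALD errors: the asymptotic sandwich is
  # tau(1-tau)/f(0)^2 * (X'X)^-1 with f(0) = tau(1-tau)/sigma
  set.seed(45)
  n <- 2500
  X <- cbind(1, rnorm(n), runif(n))
  tau <- 0.5
  sigma <- 0.8
  y <- as.numeric(X %*% c(1, 2, -1)) + ald_sample(n, 0, sigma, tau)
  ds <- longitudinal_dataset(data.frame(subject_id = sprintf("i%04d", 1:n),
                                        time = 0, response = y,
                                        v1 = X[, 2], v2 = X[, 3]))
  sp <- model_spec(tau = tau, fixed = c("intercept", "v1", "v2"),
                   random = character(0))
  f <- fit_qrlmm(ds, sp, saem_config(W = 10, seed = 3))
  sandwich <- sqrt(diag(sigma^2 / (tau * (1 - tau)) * solve(crossprod(X))))
  expect_true(all(abs(f$se - sandwich) / sandwich < 0.15))
  expect_true(all(f$se > 0))
  expect_true(all(f$ci_low < f$theta$beta & f$theta$beta < f$ci_high))
})

test_that("bootstrap and Louis standard errors are mutually consistent", {
  ds <- make_small_panel(n_subj = 25, n_i = 5, sigma = 0.6, psi11 = 0.5,
                         seed = 46)
  sp <- model_spec(fixed = c("intercept", "time"), random = "intercept")
  cfg <- saem_config(W = 60, c = 0.25, m = 5, burn_in = 3, seed = 4,
                     convergence_window = 1000)
  f <- fit_qrlmm(ds, sp, cfg, loglik_draws = 100)
  bse <- standard_errors(f, method = "bootstrap", B = 20, boot_W = 40)
  expect_true(all(bse > 0))
  ratio <- f$se / bse
  expect_true(all(ratio < 1.5 & ratio > 1 / 1.5))
})

test_that("a one-point grid equals the single fit", {
  ds <- make_small_panel(n_subj = 10, n_i = 4, seed = 47)
  sp <- model_spec(fixed = c("intercept", "time"), random = "intercept")
  cfg <- saem_config(W = 20, c = 0.3, m = 4, burn_in = 2, seed = 12,
                     convergence_window = 1000)
  g <- fit_quantile_grid(ds, sp, taus = 0.5, cfg = cfg, loglik_draws = 100)
  single <- fit_qrlmm(ds, sp, cfg, loglik_draws = 100)
  est <- g$estimate[g$term != "sigma"]
  expect_equal(est, unname(single$theta$beta))
  expect_equal(g$estimate[g$term == "sigma"], single$theta$sigma)
  expect_true(all(g$ci_low[g$term != "sigma"] < g$ci_high[g$term != "sigma"]))
})

test_that("grids have one block per quantile level and keep going on failure", {
  ds <- make_small_panel(n_subj = 10, n_i = 4, seed = 48)
  sp <- model_spec(fixed = c("intercept", "time"), random = "intercept")
  cfg <- saem_config(W = 16, c = 0.3, m = 3, burn_in = 2, seed = 13,
                     convergence_window = 1000)
  g <- fit_quantile_grid(ds, sp, taus = c(0.25, 0.5, 0.75), cfg = cfg,
                         compute_se = FALSE, loglik_draws = 100)
  expect_equal(nrow(g), 3 * (2 + 1))  # p terms + sigma per tau
  expect_equal(sort(unique(g$tau)), c(0.25, 0.5, 0.75))
  expect_error(fit_quantile_grid(ds, sp, taus = c(0.5, 0.5)), "distinct")
})

test_that("location-scale data yield slopes monotone in the quantile level", {
  # y = 1 + x + (1 + 0.5 x) * eps: the true tau-slope 1 + 0.5 q_eps(tau)
  # increases in tau, so estimated slopes must follow
  set.seed(49)
  n <- 900
  x <- runif(n, 0, 4)
  y <- 1 + x + (1 + 0.5 * x) * rnorm(n)
  ds <- longitudinal_dataset(data.frame(subject_id = sprintf("i%04d", 1:n),
                                        time = 0, response = y, x = x))
  sp <- model_spec(fixed = c("intercept", "x"), random = character(0))
  g <- fit_quantile_grid(ds, sp, taus = c(0.1, 0.3, 0.5, 0.7, 0.9),
                         cfg = saem_config(W = 10, seed = 14))
  slopes <- g$estimate[g$term == "x"]
  expect_true(all(diff(slopes) > 0))
})

test_that("structure comparison ranks by AIC with reproducible rows", {
  ds <- make_small_panel(n_subj = 15, n_i = 5, seed = 50)
  cfg <- saem_config(W = 20, c = 0.3, m = 3, burn_in = 2, seed = 15,
                     convergence_window = 1000)
  cmp <- compare_random_structures(
    ds, candidates = list(A = "intercept", B = "time", C = "intercept"),
    cfg = cfg, fixed = c("intercept", "time"), loglik_draws = 100)
  expect_named(cmp, c("model", "random", "AIC", "BIC", "HQC", "LL"))
  expect_false(is.unsorted(cmp$AIC))
  # duplicate candidates give identical rows under the common seed
  a <- cmp[cmp$model == "A", -1]
  c_ <- cmp[cmp$model == "C", -1]
  expect_equal(a$AIC, c_$AIC)
  expect_equal(a$LL, c_$LL)
  expect_error(compare_random_structures(ds, candidates = list(A = "time")),
               "2 candidates")
})

test_that("parameter-count conventions shift the criteria coherently", {
  ds <- make_small_panel(n_subj = 10, n_i = 4, seed = 51)
  sp <- model_spec(fixed = c("intercept", "time"), random = "intercept")
  cfg <- saem_config(W = 16, c = 0.3, m = 3, burn_in = 2, seed = 16,
                     convergence_window = 1000)
  f1 <- fit_qrlmm(ds, sp, cfg, compute_se = FALSE, loglik_draws = 100,
                  count_sigma = TRUE)
  f0 <- fit_qrlmm(ds, sp, cfg, compute_se = FALSE, loglik_draws = 100,
                  count_sigma = FALSE)
  expect_equal(f1$n_params, f0$n_params + 1)
  expect_equal(f1$AIC, f0$AIC + 2)
  expect_equal(f1$BIC, f0$BIC + log(f1$N))
})
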