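#' Marginal log-likelihood by importance sampling
#'
#' Integrates the subject random effects out of the asymmetric Laplace
#' likelihood with a per-subject importance sampler:
#' \deqn{\log \hat L = \sum_i \log \frac{1}{M} \sum_{l=1}^M
#'   \frac{\prod_j f_{ALD}(y_{ij} | b^{(l)}) \; \phi(b^{(l)}; 0, \Psi)}
#'        {g_i(b^{(l)})}.}
#' The proposal \eqn{g_i} is a defensive mixture: with probability 0.85 a
#' Gaussian centered at the subject's posterior mean with twice its
#' estimated posterior covariance, otherwise the prior \eqn{N(0, \Psi)}.
#' Matching the proposal to the posterior (rather than the much wider
#' prior) keeps the weight variance bounded for rich random structures;
#' the prior component guards the tails.  With an empty random structure
#' the exact sum of ALD log-densities is returned without sampling.
#'
#' @param ds a `qrsaem_data` object.
#' @param spec a `qrsaem_spec` object.
#' @param theta a `qrsaem_theta` parameter state.
#' @param M importance-sampling draws per subject (>= 100).
#' @param seed optional integer seed (local to this computation).
#' @param subject_effects optional n x r matrix of posterior means
#'   \eqn{\hat b_i} (e.g. the smoothed means of a fit).  When omitted, both
#'   means and covariances are estimated by a Metropolis-Hastings run.
#' @param subject_effect_cov optional r x r x n array of posterior
#'   covariances matching `subject_effects`.
#' @return the marginal log-likelihood (a single number), with the
#'   Monte-Carlo standard error in attribute `"mc_se"`.
#' @export
marginal_loglik <- function(ds, spec, theta, M = 1000L, seed = NULL,
                            subject_effects = NULL,
                            subject_effect_cov = NULL) {
  stopifnot(M >= 100)
  db <- build_designs(ds, spec)
  tau <- spec$tau
  res_fixed <- db$y - as.numeric(db$X %*% theta$beta)
  if (db$r == 0)
    return(structure(sum(ald_logpdf(res_fixed, 0, theta$sigma, tau)), mc_se = 0))

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  r <- db$r
  if (is.null(subject_effects) || is.null(subject_effect_cov)) {
    es <- mh_estep_cpp(res_fixed, db$Z, db$subj_start, db$subj_len,
                       matrix(0, db$n, r), t(chol(theta$psi)),
                       theta$sigma, tau, 400L, 400L, 0.8)
    subject_effects <- matrix(0, db$n, r)
    subject_effect_cov <- array(0, dim = c(r, r, db$n))
    for (i in seq_len(db$n)) {
      Bi <- matrix(es$draws[, , i], r, 400L)
      subject_effects[i, ] <- rowMeans(Bi)
      subject_effect_cov[, , i] <- tcrossprod(Bi - rowMeans(Bi)) / 400L
    }
  }

  Lpri <- tryCatch(t(chol(theta$psi)), error = function(e) NULL)
  if (is.null(Lpri)) {
    warning("degenerate prior covariance; flooring its eigenvalues")
    e <- eigen((theta$psi + t(theta$psi)) / 2, symmetric = TRUE)
    psi_f <- e$vectors %*% diag(pmax(e$values, 1e-8), r) %*% t(e$vectors)
    Lpri <- t(chol(psi_f))
  }
  logdet_pri <- sum(log(diag(Lpri)))
  w_post <- 0.85   # defensive-mixture weight on the posterior component

  ll <- 0
  var_sum <- 0
  const <- log(tau) + log1p(-tau) - log(theta$sigma)
  M1 <- round(w_post * M)
  for (i in seq_len(db$n)) {
    rows <- db$subj_start[i] + seq_len(db$subj_len[i])
    oi <- res_fixed[rows]
    Zi <- db$Z[rows, , drop = FALSE]
    # inflated posterior covariance, eigenvalue-floored
    Vi <- 2 * (subject_effect_cov[, , i] + t(subject_effect_cov[, , i])) / 2
    ev <- eigen(Vi, symmetric = TRUE)
    Vi <- ev$vectors %*% diag(pmax(ev$values, 1e-10), r) %*% t(ev$vectors)
    Lpost <- t(chol(Vi))
    logdet_post <- sum(log(diag(Lpost)))

    B <- cbind(subject_effects[i, ] + Lpost %*% matrix(stats::rnorm(r * M1), r),
               Lpri %*% matrix(stats::rnorm(r * (M - M1)), r))
    R <- matrix(oi, length(oi), M) - Zi %*% B
    log_ald <- length(oi) * const - colSums(check_loss(R, tau)) / theta$sigma
    U <- forwardsolve(Lpri, B)
    log_pri <- -0.5 * r * log(2 * pi) - logdet_pri - 0.5 * colSums(U^2)
    Up <- forwardsolve(Lpost, B - subject_effects[i, ])
    log_post <- -0.5 * r * log(2 * pi) - logdet_post - 0.5 * colSums(Up^2)
    mxc <- pmax(log_post, log_pri)
    log_prop <- mxc + log(w_post * exp(log_post - mxc) +
                            (1 - w_post) * exp(log_pri - mxc))
    lw <- log_ald + log_pri - log_prop
    mx <- max(lw)
    wi <- exp(lw - mx)
    ll <- ll + mx + log(mean(wi))
    var_sum <- var_sum + stats::var(wi) / (M * mean(wi)^2)
  }
  structure(ll, mc_se = sqrt(var_sum))
}

#' Information criteria
#'
#' `AIC = -2 LL + 2 p`, `BIC = -2 LL + p log N`,
#' `HQC = -2 LL + 2 p log(log N)`.
#'
#' @param loglik log-likelihood.
#' @param p number of free parameters.
#' @param N number of observations (>= 1; `HQC` requires `N >= 3`).
#' @return named numeric vector `c(AIC, BIC, HQC)`.
#' @examples
#' information_criteria(-17526.42, 10, 7019)
#' @export
information_criteria <- function(loglik, p, N) {
  stopifnot(N >= 1)
  if (N < 3) stop("HQC undefined for N < 3", call. = FALSE)
  c(AIC = -2 * loglik + 2 * p,
    BIC = -2 * loglik + p * log(N),
    HQC = -2 * loglik + 2 * p * log(log(N)))
}

#' Standard errors of the fixed effects
#'
#' `method = "louis"` approximates the observed information by Louis'
#' identity, averaging complete-data scores and Hessians over fresh
#' Metropolis-Hastings draws of the random effects at the converged
#' parameters; the nondifferentiable check function is kernel-smoothed with
#' a Gaussian kernel of bandwidth `h = 0.5 * sigma_hat * N^(-1/5)`
#' (overridable).  `method = "bootstrap"` refits `B` parametric resamples at
#' a reduced iteration budget and reports the resampling standard deviation.
#'
#' @param fit a `qrsaem_fit`.
#' @param method `"louis"` or `"bootstrap"`.
#' @param h smoothing bandwidth for the Louis method; `NULL` for the default.
#' @param draws posterior draws per subject for the Louis averages.
#' @param B bootstrap resamples.
#' @param boot_W SAEM iteration budget per bootstrap refit.
#' @return vector of positive standard errors, one per fixed effect.
#' @export
standard_errors <- function(fit, method = c("louis", "bootstrap"),
                            h = NULL, draws = 400L, B = 100L, boot_W = 150L) {
  method <- match.arg(method)
  if (method == "bootstrap") return(.se_bootstrap(fit, B, boot_W))
  db <- fit$designs
  beta <- fit$theta$beta
  sigma <- fit$theta$sigma
  tau <- fit$tau
  if (is.null(h)) h <- 0.5 * sigma * db$N^(-1 / 5)
  res_fixed <- db$y - as.numeric(db$X %*% beta)

  if (db$r == 0) {
    phi <- stats::dnorm(res_fixed / h)
    info <- crossprod(db$X * sqrt(phi / (sigma * h)))
    return(.se_from_info(info, db$fixed))
  }

  es <- mh_estep_cpp(res_fixed, db$Z, db$subj_start, db$subj_len,
                     fit$subject_effects, t(chol(fit$theta$psi)),
                     sigma, tau, as.integer(draws), 200L, fit$mh_scale)
  info <- matrix(0, db$p, db$p)
  for (i in seq_len(db$n)) {
    rows <- db$subj_start[i] + seq_len(db$subj_len[i])
    Xi <- db$X[rows, , drop = FALSE]
    Bi <- matrix(es$draws[, , i], db$r, draws)
    Ri <- matrix(res_fixed[rows], length(rows), draws) -
      db$Z[rows, , drop = FALSE] %*% Bi
    Psi_h <- (tau - stats::pnorm(-Ri / h)) / sigma      # smoothed score factor
    Sc <- crossprod(Xi, Psi_h)                          # p x draws scores
    sbar <- rowMeans(Sc)
    Smat <- tcrossprod(Sc) / draws
    phibar <- rowMeans(stats::dnorm(Ri / h))
    Hbar <- crossprod(Xi * sqrt(phibar / (sigma * h)))
    info <- info + Hbar - (Smat - tcrossprod(sbar))
  }
  .se_from_info(info, db$fixed)
}

.se_from_info <- function(info, names) {
  inv <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(inv) || any(diag(inv) <= 0)) {
    warning("observed information not invertible; using pseudo-inverse")
    e <- eigen((info + t(info)) / 2, symmetric = TRUE)
    pos <- pmax(e$values, max(e$values) * 1e-10)
    inv <- e$vectors %*% diag(1 / pos, length(pos)) %*% t(e$vectors)
  }
  stats::setNames(sqrt(pmax(diag(inv), 0)), names)
}

.se_bootstrap <- function(fit, B, boot_W) {
  db <- fit$designs
  cfg <- fit$config
  est <- matrix(NA_real_, B, db$p)
  for (b in seq_len(B)) {
    bseed <- cfg$seed + 7919L * b
    set.seed(bseed)
    yb <- as.numeric(db$X %*% fit$theta$beta)
    if (db$r > 0) {
      bi <- matrix(stats::rnorm(db$n * db$r), db$n, db$r) %*% chol(fit$theta$psi)
      subj <- rep(seq_len(db$n), db$subj_len)
      yb <- yb + rowSums(db$Z * bi[subj, , drop = FALSE])
    }
    yb <- yb + ald_sample(db$N, 0, fit$theta$sigma, fit$tau)
    dsb <- longitudinal_dataset(
      data.frame(subject_id = rep(db$subject, db$subj_len),
                 time = db$X[, "time"], response = yb,
                 .covdata(db)))
    specb <- model_spec(fit$tau, db$fixed, db$random)
    cfgb <- cfg
    cfgb$W <- as.integer(boot_W)
    cfgb$seed <- bseed
    fb <- tryCatch(fit_qrlmm(dsb, specb, cfgb, compute_se = FALSE,
                             loglik_draws = 100L),
                   error = function(e) NULL)
    if (!is.null(fb)) est[b, ] <- fb$theta$beta
  }
  stats::setNames(apply(est, 2, stats::sd, na.rm = TRUE), db$fixed)
}

.covdata <- function(db) {
  extra <- setdiff(db$fixed, c("intercept", "time", "sqrt_time"))
  out <- as.data.frame(db$X[, extra, drop = FALSE])
  names(out) <- extra
  out
}

#' Fit a model across a grid of quantile levels
#'
#' Runs [fit_qrlmm()] at each requested \eqn{\tau} and returns a tidy table
#' of estimates, standard errors and 95\% normal confidence bands
#' (`estimate +/- 1.96 * se`), suitable for quantile-profile plots.
#' Individual \eqn{\tau} failures are recorded and the grid continues.
#'
#' @param ds a `qrsaem_data` object.
#' @param spec a `qrsaem_spec` template (its `tau` is replaced).
#' @param taus distinct quantile levels in (0, 1). Default: the six levels
#'   0.05, 0.25, 0.5, 0.75, 0.85, 0.95.
#' @param cfg a [saem_config()].
#' @param ... passed to [fit_qrlmm()].
#' @return a data.frame of class `qrsaem_grid` with columns `tau`, `term`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, plus `sigma` rows; the fit
#'   objects are in attribute `"fits"` and failures in `"failures"`.
#' @export
fit_quantile_grid <- function(ds, spec, taus = c(0.05, 0.25, 0.5, 0.75, 0.85, 0.95),
                              cfg = saem_config(), ...) {
  if (anyDuplicated(taus)) stop("`taus` must be distinct", call. = FALSE)
  fits <- list()
  failures <- list()
  rows <- list()
  for (tv in taus) {
    sp <- spec
    sp$tau <- tv
    f <- tryCatch(fit_qrlmm(ds, sp, cfg, ...), error = function(e) e)
    key <- sprintf("%g", tv)
    if (inherits(f, "error")) {
      failures[[key]] <- conditionMessage(f)
      next
    }
    fits[[key]] <- f
    se <- if (is.null(f$se)) rep(NA_real_, length(f$theta$beta)) else f$se
    rows[[key]] <- data.frame(tau = tv, term = names(f$theta$beta),
                              estimate = unname(f$theta$beta),
                              se = unname(se),
                              ci_low = unname(f$theta$beta - 1.96 * se),
                              ci_high = unname(f$theta$beta + 1.96 * se),
                              stringsAsFactors = FALSE)
    rows[[key]] <- rbind(rows[[key]],
                         data.frame(tau = tv, term = "sigma",
                                    estimate = f$theta$sigma, se = NA_real_,
                                    ci_low = NA_real_, ci_high = NA_real_))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, fits = fits, failures = failures,
            class = c("qrsaem_grid", "data.frame"))
}

#' Compare random-effects structures by information criteria
#'
#' Fits each candidate random structure at the median (`tau = 0.5`) with a
#' common seed and ranks the candidates by AIC (BIC, HQC and the marginal
#' log-likelihood are reported alongside).  The default candidate set is the
#' usual ladder for a time-course model: a lone time slope; intercept +
#' time; time + sqrt-time; intercept + both slopes.
#'
#' @param ds a `qrsaem_data` object.
#' @param candidates named list of random-term character vectors.
#' @param cfg a [saem_config()].
#' @param fixed fixed-effect terms shared by all candidates.
#' @param tau quantile level of the comparison (default 0.5, median).
#' @param count_sigma convention for the parameter count in the criteria:
#'   `TRUE` counts fixed effects + distinct covariance elements + the scale;
#'   `FALSE` omits the scale.
#' @param ... passed to [fit_qrlmm()].
#' @return a data.frame of class `qrsaem_comparison` with columns `model`,
#'   `random`, `AIC`, `BIC`, `HQC`, `LL`, sorted by AIC ascending; failed
#'   candidates are flagged in attribute `"failures"` and excluded.
#' @export
compare_random_structures <- function(ds,
                                      candidates = list(
                                        `Model 1` = "time",
                                        `Model 2` = c("intercept", "time"),
                                        `Model 3` = c("time", "sqrt_time"),
                                        `Model 4` = c("intercept", "time", "sqrt_time")),
                                      cfg = saem_config(),
                                      fixed = c("intercept", "time", "sqrt_time",
                                                "bmi", "lvl", "art", "age"),
                                      tau = 0.5, count_sigma = TRUE, ...) {
  if (length(candidates) < 2) stop("need at least 2 candidates", call. = FALSE)
  if (is.null(names(candidates)))
    names(candidates) <- paste("Model", seq_along(candidates))
  rows <- list()
  fits <- list()
  failures <- list()
  for (nm in names(candidates)) {
    sp <- model_spec(tau = tau, fixed = fixed, random = candidates[[nm]])
    f <- tryCatch(fit_qrlmm(ds, sp, cfg, compute_se = FALSE,
                            count_sigma = count_sigma, ...),
                  error = function(e) e)
    if (inherits(f, "error")) {
      failures[[nm]] <- conditionMessage(f)
      next
    }
    fits[[nm]] <- f
    rows[[nm]] <- data.frame(model = nm,
                             random = paste(candidates[[nm]], collapse = "+"),
                             AIC = f$AIC, BIC = f$BIC, HQC = f$HQC,
                             LL = f$loglik, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$AIC), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, fits = fits, failures = failures,
            class = c("qrsaem_comparison", "data.frame"))
}
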