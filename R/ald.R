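#' Check (quantile) loss function
#'
#' The asymmetric absolute loss \eqn{\rho_\tau(u) = u(\tau - I\{u < 0\})}
#' whose minimizer over a location parameter is the \eqn{\tau}-th quantile.
#' It is convex and piecewise linear, nonnegative, and zero iff `u == 0`.
#'
#' @param u numeric vector of residuals.
#' @param tau quantile level, a single number in (0, 1).
#' @return numeric vector of losses, same length as `u`.
#' @examples
#' check_loss(2, 0.5)    # 1
#' check_loss(-2, 0.25)  # 1.5
#' @export
check_loss <- function(u, tau) {
  .check_tau(tau)
  u * (tau - (u < 0))
}

.check_tau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0 || tau >= 1)
    stop("`tau` must be a single number in (0, 1)", call. = FALSE)
  invisible(tau)
}

.check_ald <- function(mu, sigma, tau) {
  if (!is.numeric(mu) || anyNA(mu)) stop("`mu` must be numeric", call. = FALSE)
  if (!is.numeric(sigma) || any(is.na(sigma)) || any(sigma <= 0))
    stop("`sigma` must be positive", call. = FALSE)
  .check_tau(tau)
}

#' Asymmetric Laplace distribution
#'
#' Density (log scale), distribution function, quantile function and random
#' generation for the three-parameter asymmetric Laplace law
#' \deqn{f(y) = \frac{\tau(1-\tau)}{\sigma}
#'   \exp\{-\rho_\tau((y - \mu)/\sigma)\},}
#' the error law that ties check-loss minimization to maximum likelihood:
#' its \eqn{\tau}-th quantile is exactly \eqn{\mu}, so `ald_cdf(mu, ...)`
#' equals `tau`.
#'
#' `ald_sample()` uses the inverse-CDF transform on uniform draws, so it is
#' exact and reproducible under a seed.
#'
#' @param y,prob numeric vectors of evaluation points / probabilities.
#' @param mu location parameter (the \eqn{\tau}-th quantile).
#' @param sigma scale parameter, positive. Inside the log-density it is
#'   floored at `1e-10` to avoid overflow cascades from degenerate scales.
#' @param tau skewness / quantile-level parameter in (0, 1).
#' @param n number of draws.
#' @param seed optional integer; when supplied the draw is made reproducible
#'   with a local `set.seed()`.
#' @return `ald_logpdf`: log-density values; `ald_cdf`: probabilities;
#'   `ald_quantile`: quantiles; `ald_sample`: a numeric vector of draws.
#' @examples
#' ald_logpdf(0, 0, 1, 0.5)        # log(0.25)
#' ald_cdf(0, 0, 1, 0.25)          # 0.25
#' ald_quantile(0.25, 0, 1, 0.5)   # 2 * log(0.5)
#' @name ald
NULL

#' @rdname ald
#' @export
ald_logpdf <- function(y, mu = 0, sigma = 1, tau = 0.5) {
  .check_ald(mu, sigma, tau)
  sigma <- pmax(sigma, 1e-10)
  log(tau) + log1p(-tau) - log(sigma) - check_loss((y - mu) / sigma, tau)
}

#' @rdname ald
#' @export
ald_cdf <- function(y, mu = 0, sigma = 1, tau = 0.5) {
  .check_ald(mu, sigma, tau)
  u <- (y - mu) / sigma
  ifelse(u <= 0, tau * exp((1 - tau) * u), 1 - (1 - tau) * exp(-tau * u))
}

#' @rdname ald
#' @export
ald_quantile <- function(prob, mu = 0, sigma = 1, tau = 0.5) {
  .check_ald(mu, sigma, tau)
  if (!is.numeric(prob) || any(is.na(prob)) || any(prob <= 0) || any(prob >= 1))
    stop("`prob` must lie in (0, 1)", call. = FALSE)
  ifelse(prob <= tau,
         mu + sigma / (1 - tau) * log(prob / tau),
         mu - sigma / tau * log((1 - prob) / (1 - tau)))
}

#' @rdname ald
#' @export
ald_sample <- function(n, mu = 0, sigma = 1, tau = 0.5, seed = NULL) {
  .check_ald(mu, sigma, tau)
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  ald_quantile(stats::runif(n), mu, sigma, tau)
}

#' Weighted check-loss (quantile) regression
#'
#' Computes a minimizer of \eqn{\sum_i w_i \rho_\tau(y_i - x_i'\beta)} by a
#' Frisch-Newton primal-dual interior point method on the linear-programming
#' dual (residuals split into positive and negative parts).  With unit
#' weights and `tau = 0.5` this is least-absolute-deviation regression; an
#' intercept-only design returns a sample \eqn{\tau}-quantile of `y`.
#'
#' Quantile-regression solutions can be non-unique on small datasets (any
#' point of a face of the LP polytope is optimal); solutions should therefore
#' be compared through the objective value, not coefficient identity.
#'
#' @param design numeric matrix (N x p), full column rank on the rows with
#'   positive weight.
#' @param response numeric vector of length N.
#' @param weights nonnegative weights of length N (default all one). A row
#'   with weight `w` contributes exactly like `w` duplicated unit-weight rows.
#' @param tau quantile level in (0, 1).
#' @return named numeric vector of `p` coefficients, with the attained
#'   objective value in attribute `"objective"`.
#' @examples
#' x <- cbind(1, 1:10)
#' y <- 2 + 0.5 * (1:10) + rnorm(10)
#' weighted_check_regression(x, y, tau = 0.5)
#' @export
weighted_check_regression <- function(design, response, weights = NULL, tau = 0.5) {
  .check_tau(tau)
  design <- as.matrix(design)
  storage.mode(design) <- "double"
  response <- as.numeric(response)
  n <- nrow(design)
  p <- ncol(design)
  if (length(response) != n)
    stop("`design` and `response` dimensions disagree", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n)
    stop("`weights` must have one entry per row", call. = FALSE)
  if (any(weights < 0) || anyNA(weights))
    stop("`weights` must be nonnegative", call. = FALSE)
  keep <- weights > 0
  if (!any(keep)) stop("empty problem: all weights are zero", call. = FALSE)
  Xk <- design[keep, , drop = FALSE]
  if (qr(Xk)$rank < p)
    stop("singular design: rank-deficient on positively weighted rows", call. = FALSE)
  fit <- rqfn_multi_cpp(Xk, cbind(response[keep]), weights[keep], 1, tau)
  beta <- drop(fit$coefficients)
  names(beta) <- colnames(design)
  attr(beta, "objective") <- fit$objective
  beta
}
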