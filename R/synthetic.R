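#' Cohort configuration for the synthetic generator
#'
#' Describes the study design the generator emulates: an acute-infection
#' HIV cohort of women followed monthly, with per-subject follow-up length
#' (equal to the visit count) between `followup_min` and `followup_max`
#' months and a target median of `followup_median`; baseline covariates with
#' marginals matched to the cohort's published summaries (BMI mean about
#' 28.9 in [17.89, 54.89]; log baseline viral load with median about 10.3,
#' a point mass at 0 for undetectable virus, range [0, 15.52]; integer age
#' 18-59 with median about 25); and therapy initiation at a month drawn
#' uniformly from the middle half of each subject's follow-up.
#'
#' Follow-up lengths are drawn beta-binomially: `followup_min + Bin(size, p)`
#' with `p ~ Beta` centered so the median lands on `followup_median`, and
#' concentration `followup_spread` controlling the overdispersion (smaller
#' values give a wider spread over the admissible range).
#'
#' @param n_subjects number of subjects (default 235).
#' @param followup_min,followup_max,followup_median visit-count distribution
#'   anchors, in months.
#' @param followup_spread beta concentration of the per-subject visit
#'   probability (default 8).
#' @param bmi_mean,bmi_sd,bmi_range truncated-normal parameters for baseline
#'   BMI.
#' @param lvl_median,lvl_sd,lvl_range,lvl_zero_prob log baseline viral load:
#'   truncated normal with a `lvl_zero_prob` point mass at exactly 0
#'   ("not detected").
#' @param age_shape,age_scale,age_range gamma-offset integer age:
#'   `age_min + floor(Gamma(shape, scale))`, truncated to the range.
#' @param art_window fraction interval of follow-up within which therapy
#'   initiation is drawn uniformly.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 235L,
                          followup_min = 2L, followup_max = 61L,
                          followup_median = 29L, followup_spread = 8,
                          bmi_mean = 28.5, bmi_sd = 5.5, bmi_range = c(17.89, 54.89),
                          lvl_median = 10.26, lvl_sd = 2.1,
                          lvl_range = c(0, 15.52), lvl_zero_prob = 0.03,
                          age_shape = 2.2, age_scale = 4.2, age_range = c(18L, 59L),
                          art_window = c(0.25, 0.75)) {
  if (followup_min > followup_max || followup_median < followup_min ||
      followup_median > followup_max)
    stop("config error: infeasible follow-up range/median", call. = FALSE)
  if (bmi_range[1] > bmi_range[2] || lvl_range[1] > lvl_range[2] ||
      age_range[1] > age_range[2])
    stop("config error: min > max in a covariate range", call. = FALSE)
  if (lvl_zero_prob < 0 || lvl_zero_prob >= 1)
    stop("config error: lvl_zero_prob must be in [0, 1)", call. = FALSE)
  structure(as.list(environment()), class = "cohort_config")
}

#' Generating truth for synthetic datasets
#'
#' Parameter values a dataset is generated from, recorded alongside every
#' generated dataset so recovery can be measured.  Defaults are plausible
#' values for a square-root CD4 trajectory model: fixed effects
#' (intercept, time, sqrt-time, BMI, log viral load, therapy, age) =
#' (24.6, 0.056, -0.695, 0.082, -0.641, 2.56, 0.029), unit ALD scale at the
#' median, and a diagonal random-effects covariance diag(1, 0.04, 0.25) for
#' (intercept, time, sqrt-time).
#'
#' @param beta fixed-effect vector (7 values for the default model).
#' @param sigma positive error scale.
#' @param psi symmetric positive-definite random-effects covariance; its
#'   dimension sets the number of random terms used (1: intercept; 2:
#'   intercept + time; 3: intercept + time + sqrt-time).
#' @param tau_gen quantile level of the generating ALD error.
#' @param family error family: `"ald"` (default), or `"gaussian"` / `"t3"`
#'   for misspecification studies; non-ALD errors are shifted so their
#'   `tau_gen`-quantile is zero, keeping the fixed effects identified.
#' @return a list of class `truth_record`.
#' @export
truth_record <- function(beta = c(intercept = 24.6, time = 0.056,
                                  sqrt_time = -0.695, bmi = 0.082,
                                  lvl = -0.641, art = 2.56, age = 0.029),
                         sigma = 1,
                         psi = diag(c(1, 0.04, 0.25)),
                         tau_gen = 0.5,
                         family = c("ald", "gaussian", "t3")) {
  family <- match.arg(family)
  .check_tau(tau_gen)
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  psi <- as.matrix(psi)
  if (!isSymmetric(psi, tol = 1e-10) || any(eigen(psi, symmetric = TRUE,
                                                  only.values = TRUE)$values <= 0))
    stop("`psi` must be symmetric positive definite", call. = FALSE)
  structure(list(beta = beta, sigma = sigma, psi = psi, tau_gen = tau_gen,
                 family = family), class = "truth_record")
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  stats::qnorm(stats::runif(n, stats::pnorm(lo, mean, sd),
                            stats::pnorm(hi, mean, sd)), mean, sd)
}

#' Generate baseline covariates and a visit skeleton
#'
#' Draws per-subject baseline covariates and expands each subject onto a
#' monthly visit grid (months `0, 1, ..., L_i - 1`); the therapy indicator
#' switches from 0 to 1 at the subject's initiation month and never
#' reverts.  The response column is left `NA`.
#'
#' @param cfg a [cohort_config()].
#' @param seed optional integer seed.
#' @return a `qrsaem_data` skeleton with covariates `bmi`, `lvl`, `art`,
#'   `age` and `NA` responses; the configuration is attached as attribute
#'   `"cohort_config"`.
#' @export
generate_covariates <- function(cfg = cohort_config(), seed = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_subjects
  size <- cfg$followup_max - cfg$followup_min
  p_center <- (cfg$followup_median + 0.5 - cfg$followup_min) / size
  p <- stats::rbeta(n, p_center * cfg$followup_spread,
                    (1 - p_center) * cfg$followup_spread)
  L <- cfg$followup_min + stats::rbinom(n, size, p)

  bmi <- .rtruncnorm(n, cfg$bmi_mean, cfg$bmi_sd, cfg$bmi_range[1], cfg$bmi_range[2])
  lvl <- ifelse(stats::runif(n) < cfg$lvl_zero_prob, 0,
                .rtruncnorm(n, cfg$lvl_median, cfg$lvl_sd,
                            max(cfg$lvl_range[1], 0.5), cfg$lvl_range[2]))
  age <- pmin(cfg$age_range[1] + floor(stats::rgamma(n, cfg$age_shape,
                                                     scale = cfg$age_scale)),
              cfg$age_range[2])
  art_start <- floor(cfg$art_window[1] * L +
                       stats::runif(n) * (cfg$art_window[2] - cfg$art_window[1]) * L)

  id <- sprintf("S%03d", seq_len(n))
  rows <- data.frame(subject_id = rep(id, L),
                     time = unlist(lapply(L, function(l) seq_len(l) - 1)),
                     response = NA_real_,
                     bmi = rep(bmi, L), lvl = rep(lvl, L),
                     art = as.numeric(unlist(mapply(function(l, a) seq_len(l) - 1 >= a,
                                                    L, art_start, SIMPLIFY = FALSE))),
                     age = rep(age, L))
  ds <- longitudinal_dataset(rows)
  attr(ds, "cohort_config") <- cfg
  ds
}

.random_terms_for <- function(r) c("intercept", "time", "sqrt_time")[seq_len(r)]

# fixed terms implied by a truth record: its beta names when present,
# otherwise the default seven-term model
.fixed_terms_for <- function(truth) {
  if (!is.null(names(truth$beta))) names(truth$beta)
  else c("intercept", "time", "sqrt_time", "bmi", "lvl", "art", "age")
}

#' Generate responses from known truth
#'
#' Fills the response column of a covariate skeleton from the quantile
#' linear mixed model \eqn{y_{ij} = x_{ij}'\beta + z_{ij}'b_i +
#' \varepsilon_{ij}} with \eqn{b_i \sim N_r(0, \Psi)} and errors from the
#' configured family (ALD(0, `sigma`, `tau_gen`) by default, whose
#' `tau_gen`-quantile is zero by construction).
#'
#' @param skeleton a `qrsaem_data` (response values are overwritten).
#' @param truth a [truth_record()].
#' @param seed optional integer seed.
#' @return the completed `qrsaem_data` with the truth attached as attribute
#'   `"truth"`.
#' @export
generate_responses <- function(skeleton, truth = truth_record(), seed = NULL) {
  stopifnot(inherits(skeleton, "qrsaem_data"), inherits(truth, "truth_record"))
  if (!is.null(seed)) set.seed(seed)
  r <- nrow(truth$psi)
  sp <- model_spec(tau = truth$tau_gen, fixed = .fixed_terms_for(truth),
                   random = .random_terms_for(r))
  db <- build_designs(skeleton, sp)
  if (length(truth$beta) != db$p)
    stop("truth `beta` length does not match the model's fixed terms", call. = FALSE)
  b <- matrix(stats::rnorm(db$n * r), db$n, r) %*% chol(truth$psi)
  subj <- rep(seq_len(db$n), db$subj_len)
  eps <- switch(truth$family,
                ald = ald_sample(db$N, 0, truth$sigma, truth$tau_gen),
                gaussian = truth$sigma * (stats::rnorm(db$N) -
                                            stats::qnorm(truth$tau_gen)),
                t3 = truth$sigma * (stats::rt(db$N, df = 3) -
                                      stats::qt(truth$tau_gen, df = 3)))
  y <- as.numeric(db$X %*% truth$beta) +
    rowSums(db$Z * b[subj, , drop = FALSE]) + eps
  out <- skeleton
  out$response <- y
  attr(out, "truth") <- truth
  attr(out, "random_effects") <- b
  out
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper: [generate_covariates()] then [generate_responses()]
#' under one seed.
#'
#' @param cohort a [cohort_config()].
#' @param truth a [truth_record()].
#' @param seed integer seed.
#' @return a complete `qrsaem_data` with `"truth"` and `"cohort_config"`
#'   attributes.
#' @export
simulate_qrlmm_data <- function(cohort = cohort_config(), truth = truth_record(),
                                seed = 1L) {
  set.seed(seed)
  generate_responses(generate_covariates(cohort), truth)
}

#' Write / read the truth sidecar
#'
#' Serializes a [truth_record()] as JSON next to a dataset CSV so the
#' generating parameters round-trip with the data.
#'
#' @param truth a `truth_record`.
#' @param path JSON path.
#' @return `read_truth_json` returns the reloaded `truth_record`.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(list(beta = truth$beta, sigma = truth$sigma,
                            psi = truth$psi, tau_gen = truth$tau_gen,
                            family = truth$family),
                       path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth_record(beta = unlist(x$beta), sigma = x$sigma,
               psi = matrix(unlist(x$psi), nrow(x$psi), byrow = FALSE),
               tau_gen = x$tau_gen, family = x$family)
}

#' Parameter-recovery experiment
#'
#' Generates `replicates` independent cohorts from known truth, fits each at
#' `tau = tau_gen`, and summarizes per-parameter bias, root-mean-square
#' error, Monte-Carlo standard error of the bias, and empirical coverage of
#' the nominal 95\% confidence bands.  Replicates whose fit fails are
#' recorded and excluded.
#'
#' @param truth a [truth_record()].
#' @param cohort a [cohort_config()].
#' @param replicates number of replicates (>= 2).
#' @param cfg a [saem_config()]; per-replicate seeds are derived from
#'   `cfg$seed`.
#' @param ... passed to [fit_qrlmm()].
#' @return a data.frame of class `qrsaem_recovery` (one row per fixed effect
#'   plus one for `sigma`) with columns `term`, `truth`, `mean_est`, `bias`,
#'   `rmse`, `mcse`, `coverage`; failures in attribute `"failures"`, the
#'   per-replicate estimates in `"estimates"`.
#' @export
recovery_experiment <- function(truth = truth_record(), cohort = cohort_config(),
                                replicates = 20L, cfg = saem_config(), ...) {
  stopifnot(replicates >= 2)
  r <- nrow(truth$psi)
  sp <- model_spec(tau = truth$tau_gen, fixed = .fixed_terms_for(truth),
                   random = .random_terms_for(r))
  p <- length(truth$beta)
  est <- matrix(NA_real_, replicates, p + 1)
  cover <- matrix(NA, replicates, p)
  failures <- list()
  for (rep_i in seq_len(replicates)) {
    ds <- simulate_qrlmm_data(cohort, truth, seed = cfg$seed + 1000L * rep_i)
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + 1000L * rep_i + 1L
    f <- tryCatch(fit_qrlmm(ds, sp, cfg_i, ...), error = function(e) e)
    if (inherits(f, "error")) {
      failures[[as.character(rep_i)]] <- conditionMessage(f)
      next
    }
    est[rep_i, ] <- c(f$theta$beta, f$theta$sigma)
    if (!is.null(f$se))
      cover[rep_i, ] <- truth$beta >= f$ci_low & truth$beta <= f$ci_high
  }
  ok <- !is.na(est[, 1])
  tv <- c(truth$beta, sigma = truth$sigma)
  terms <- c(names(truth$beta), "sigma")
  dev <- sweep(est[ok, , drop = FALSE], 2, tv)
  out <- data.frame(term = terms, truth = unname(tv),
                    mean_est = colMeans(est[ok, , drop = FALSE]),
                    bias = colMeans(dev),
                    rmse = sqrt(colMeans(dev^2)),
                    mcse = apply(est[ok, , drop = FALSE], 2, stats::sd) / sqrt(sum(ok)),
                    coverage = c(colMeans(cover[ok, , drop = FALSE]), NA),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, failures = failures, estimates = est, replicates_used = sum(ok),
            class = c("qrsaem_recovery", "data.frame"))
}
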