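#' Construct a longitudinal dataset
#'
#' A long-format repeated-measures container: one row per subject-visit with
#' a subject identifier, time in months, a continuous response (for CD4-count
#' cohorts, typically the square-root count), and named covariate columns
#' (for the default model: baseline BMI `bmi`, log baseline viral load `lvl`,
#' a 0/1 antiretroviral-therapy indicator `art`, baseline age `age`).
#' Rows are sorted by (subject, time).
#'
#' @param data data.frame holding the columns.
#' @param subject,time,response names of the subject id, time and response
#'   columns in `data`.
#' @param covariates character vector of covariate column names to carry
#'   along (default: every other column).
#' @return an object of class `qrsaem_data` (a sorted data.frame with
#'   standardized columns `subject_id`, `time`, `response` plus covariates).
#' @export
longitudinal_dataset <- function(data, subject = "subject_id", time = "time",
                                 response = "response", covariates = NULL) {
  stopifnot(is.data.frame(data))
  need <- c(subject, time, response)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("schema error: missing column(s) ", paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(covariates)) covariates <- setdiff(names(data), need)
  miss <- setdiff(covariates, names(data))
  if (length(miss))
    stop("schema error: missing covariate column(s) ", paste(miss, collapse = ", "), call. = FALSE)

  out <- data.frame(subject_id = as.character(data[[subject]]),
                    time = .parse_numeric(data[[time]], time),
                    response = .parse_numeric(data[[response]], response, allow_na = TRUE),
                    stringsAsFactors = FALSE)
  for (cv in covariates) out[[cv]] <- .parse_numeric(data[[cv]], cv, allow_na = TRUE)
  if (anyNA(out$subject_id) || any(out$subject_id == ""))
    stop("every row must carry a subject id", call. = FALSE)
  out <- out[order(out$subject_id, out$time), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, covariates = covariates, class = c("qrsaem_data", "data.frame"))
}

.parse_numeric <- function(x, name, allow_na = FALSE) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) & !is.na(x) & !(x %in% c("NA", ""))
  if (any(bad))
    stop(sprintf("parse error: non-numeric `%s` at row %d", name, which(bad)[1]),
         call. = FALSE)
  if (!allow_na && anyNA(v))
    stop(sprintf("parse error: missing `%s` at row %d", name, which(is.na(v))[1]),
         call. = FALSE)
  v
}

#' Read a long-format longitudinal CSV
#'
#' Reads a header-bearing CSV (UTF-8) and maps its columns onto the
#' standardized layout of [longitudinal_dataset()].
#'
#' @param path path to the CSV file.
#' @param column_map named character vector mapping the roles `subject`,
#'   `time`, `response` to column names in the file; defaults to columns
#'   named `subject_id`, `time`, `response`.
#' @param covariates covariate columns to keep (default: all others).
#' @return a `qrsaem_data` object.
#' @examples
#' path <- system.file("extdata", "synthetic_cohort.csv", package = "qrsaem")
#' ds <- load_long_csv(path, covariates = c("bmi", "lvl", "art", "age"))
#' validate_dataset(ds)
#' @export
load_long_csv <- function(path,
                          column_map = c(subject = "subject_id", time = "time",
                                         response = "response"),
                          covariates = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  for (role in c("subject", "time", "response"))
    if (!role %in% names(column_map))
      stop("`column_map` must name a `", role, "` column", call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ds <- longitudinal_dataset(raw, subject = column_map[["subject"]],
                             time = column_map[["time"]],
                             response = column_map[["response"]],
                             covariates = covariates)
  if (anyNA(ds$response)) {
    i <- which(is.na(ds$response))[1]
    stop(sprintf("parse error: missing response at row %d (after sorting)", i),
         call. = FALSE)
  }
  ds
}

#' Write a longitudinal dataset to CSV
#'
#' Inverse of [load_long_csv()]; values round-trip to full double precision.
#'
#' @param ds a `qrsaem_data` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a longitudinal dataset
#'
#' Report-style diagnostics: number of subjects, total observations, the
#' per-subject visit-count range and median, and any invariant violations
#' (nonfinite or negative times, nonfinite responses, a therapy indicator
#' that reverts from 1 to 0 within a subject).
#'
#' @param ds a `qrsaem_data` object.
#' @param strict if `TRUE`, violations raise an error instead of being
#'   reported.
#' @return a list of class `qrsaem_validation` with elements `n_subjects`,
#'   `n_obs`, `ni_range`, `ni_median`, `violations` (character vector).
#' @export
validate_dataset <- function(ds, strict = FALSE) {
  stopifnot(inherits(ds, "qrsaem_data"))
  viol <- character()
  if (nrow(ds) == 0) {
    rep <- structure(list(n_subjects = 0L, n_obs = 0L, ni_range = c(NA, NA),
                          ni_median = NA_real_, empty = TRUE,
                          violations = viol),
                     class = "qrsaem_validation")
    return(rep)
  }
  ni <- table(ds$subject_id)
  if (any(!is.finite(ds$time)) || any(ds$time < 0, na.rm = TRUE))
    viol <- c(viol, "time must be finite and nonnegative")
  if (any(!is.finite(ds$response)))
    viol <- c(viol, "response must be finite")
  if ("art" %in% names(ds)) {
    rev_subj <- vapply(split(ds$art, ds$subject_id),
                       function(a) any(diff(a) < 0), logical(1))
    if (any(rev_subj))
      viol <- c(viol, paste0("ART indicator decreases within subject(s): ",
                             paste(names(rev_subj)[rev_subj], collapse = ", ")))
  }
  if (strict && length(viol))
    stop("dataset validation failed: ", paste(viol, collapse = "; "), call. = FALSE)
  structure(list(n_subjects = length(ni), n_obs = nrow(ds),
                 ni_range = range(as.integer(ni)),
                 ni_median = stats::median(as.integer(ni)),
                 empty = FALSE, violations = viol),
            class = "qrsaem_validation")
}

#' @export
print.qrsaem_validation <- function(x, ...) {
  cat("Longitudinal dataset validation\n")
  cat(sprintf("  subjects: %d   observations: %d\n", x$n_subjects, x$n_obs))
  if (!x$empty)
    cat(sprintf("  visits per subject: %d-%d (median %.1f)\n",
                x$ni_range[1], x$ni_range[2], x$ni_median))
  if (length(x$violations))
    cat("  violations:\n", paste0("   - ", x$violations, collapse = "\n"), "\n")
  else cat("  no violations\n")
  invisible(x)
}

#' Specify a quantile linear mixed model
#'
#' Describes the \eqn{\tau}-th conditional-quantile model
#' \deqn{Q_\tau(y_{ij} | x_{ij}, b_i) = x_{ij}'\beta_\tau + z_{ij}'b_i}
#' by its quantile level and ordered fixed / random term lists.  The term
#' vocabulary is `"intercept"`, `"time"`, `"sqrt_time"`, plus any covariate
#' column name of the dataset.  Random terms are restricted to the intercept
#' and the two time slopes.  An empty `random` list degenerates to ordinary
#' fixed-effects quantile regression.
#'
#' @param tau quantile level in (0, 1).
#' @param fixed ordered character vector of fixed-effect terms (nonempty).
#' @param random ordered character vector of random-effect terms, a subset of
#'   `c("intercept", "time", "sqrt_time")`; may be empty.
#' @return an object of class `qrsaem_spec`.
#' @export
model_spec <- function(tau = 0.5,
                       fixed = c("intercept", "time", "sqrt_time",
                                 "bmi", "lvl", "art", "age"),
                       random = c("intercept", "time", "sqrt_time")) {
  .check_tau(tau)
  if (!length(fixed)) stop("`fixed` must be nonempty", call. = FALSE)
  bad <- setdiff(random, c("intercept", "time", "sqrt_time"))
  if (length(bad))
    stop("random terms restricted to intercept/time/sqrt_time; got ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(tau = tau, fixed = fixed, random = random),
            class = "qrsaem_spec")
}

.term_column <- function(term, ds) {
  switch(term,
         intercept = rep(1, nrow(ds)),
         time = ds$time,
         sqrt_time = {
           if (any(ds$time < 0)) stop("negative time with sqrt_time term", call. = FALSE)
           sqrt(ds$time)
         },
         {
           if (!term %in% names(ds))
             stop("unknown model term: ", term, call. = FALSE)
           ds[[term]]
         })
}

#' Build per-subject design matrices
#'
#' Realizes the fixed design \eqn{X} (N x p) and random design \eqn{Z}
#' (N x r) of a model specification against a dataset, in the specification's
#' term order, together with the subject grouping used by the estimation
#' engine.
#'
#' @param ds a `qrsaem_data` object.
#' @param spec a `qrsaem_spec` object.
#' @return a list of class `qrsaem_designs` with elements `X`, `Z`, `y`,
#'   `subject` (character), `subj_start`/`subj_len` (0-based row offsets and
#'   lengths per subject), `n`, `N`, `p`, `r`, `fixed`, `random`, `tau`.
#' @export
build_designs <- function(ds, spec) {
  stopifnot(inherits(ds, "qrsaem_data"), inherits(spec, "qrsaem_spec"))
  X <- do.call(cbind, lapply(spec$fixed, .term_column, ds = ds))
  colnames(X) <- spec$fixed
  r <- length(spec$random)
  Z <- if (r > 0) {
    z <- do.call(cbind, lapply(spec$random, .term_column, ds = ds))
    colnames(z) <- spec$random
    z
  } else matrix(0, nrow(ds), 0)
  ids <- unique(ds$subject_id)
  len <- as.integer(table(factor(ds$subject_id, levels = ids)))
  start <- c(0L, cumsum(len)[-length(len)])
  structure(list(X = X, Z = Z, y = ds$response, subject = ids,
                 subj_start = start, subj_len = len,
                 n = length(ids), N = nrow(ds), p = ncol(X), r = r,
                 fixed = spec$fixed, random = spec$random, tau = spec$tau),
            class = "qrsaem_designs")
}
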