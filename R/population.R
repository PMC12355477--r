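## Synthetic baseline cohorts.
##
## The model is populated from summary-level baseline statistics (mean/sd and
## plausibility bounds for continuous characteristics; category shares for
## the rest). Continuous traits are drawn from truncated normals by inverse
## CDF; an optional Gaussian copula induces dependence between continuous
## markers while preserving the truncated-normal marginals.

COHORT_CONTINUOUS <- c("age", METABOLIC_MARKERS)

qtrunc_norm <- function(u, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, length(u)))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + u * (phi - plo), mean, sd)
}

## Mean of the truncated normal (closed form, used by show methods and docs;
## tests use an independent quadrature oracle instead).
truncnorm_mean <- function(mean, sd, lower, upper) {
  if (sd == 0) return(mean)
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

#' Build a correlated sampler for continuous baseline characteristics
#'
#' Returns a sampling rule (a function of `n`) producing uniforms with a
#' Gaussian-copula dependence structure over the named continuous
#' characteristics. With an identity matrix (or `NULL`) the rule reduces to
#' independent sampling.
#'
#' @param baseline the `baseline` component of an `sz_params` object.
#' @param correlation optional correlation matrix; its dimnames must name
#'   continuous characteristics. Must be symmetric positive semi-definite.
#' @return a function `f(n)` returning an `n x k` matrix of uniforms with
#'   columns named after all continuous characteristics.
#' @export
correlate_metabolics <- function(baseline, correlation = NULL) {
  vars <- names(baseline$continuous)
  if (is.null(correlation)) {
    return(function(n) {
      u <- matrix(runif(n * length(vars)), nrow = n)
      colnames(u) <- vars
      u
    })
  }
  if (is.null(dimnames(correlation)) ||
      !all(rownames(correlation) %in% vars))
    stop_config("correlation matrix dimnames must name continuous characteristics")
  if (!isSymmetric(unname(correlation)))
    stop_config("correlation matrix must be symmetric")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop_config("correlation matrix is not positive semi-definite")
  cv <- rownames(correlation)
  ch <- chol(correlation + diag(1e-12, nrow(correlation)))
  function(n) {
    u <- matrix(runif(n * length(vars)), nrow = n)
    colnames(u) <- vars
    z <- matrix(rnorm(n * length(cv)), nrow = n) %*% ch
    u[, cv] <- pnorm(z)
    u
  }
}

#' Generate a synthetic baseline cohort
#'
#' Draws `n` patient profiles from the configured baseline summary:
#' truncated normals for age and the six metabolic markers (BMI, total
#' cholesterol, HDL-C, triglyceride, fasting glucose, systolic blood
#' pressure), categorical draws for sex, smoking, alcohol and adherence
#' level, and Bernoulli draws for prior CHD, prior stroke, prior diabetes
#' and antihypertensive treatment.
#'
#' @param baseline the `baseline` component of an `sz_params` object.
#' @param n number of patients.
#' @param seed optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @param correlation optional correlation matrix passed to
#'   [correlate_metabolics()].
#' @return a data frame (class `sz_cohort`) with one row per patient.
#' @export
generate_cohort <- function(baseline, n, seed = NULL, correlation = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  for (nm in names(baseline$continuous)) {
    ch <- baseline$continuous[[nm]]
    if (ch$lower >= ch$upper)
      stop_config("baseline/continuous/", nm, ": degenerate bounds")
  }
  sampler <- correlate_metabolics(baseline, correlation)
  u <- sampler(n)
  out <- data.frame(id = seq_len(n))
  for (nm in names(baseline$continuous)) {
    ch <- baseline$continuous[[nm]]
    out[[nm]] <- qtrunc_norm(u[, nm], ch$mean, ch$sd, ch$lower, ch$upper)
  }
  for (nm in names(baseline$categorical)) {
    pr <- baseline$categorical[[nm]]
    idx <- findInterval(runif(n), cumsum(pr), left.open = TRUE) + 1L
    out[[nm]] <- names(pr)[idx]
  }
  for (nm in names(baseline$binary))
    out[[nm]] <- runif(n) < baseline$binary[[nm]]
  class(out) <- c("sz_cohort", "data.frame")
  out
}

#' Write / read a cohort as CSV
#'
#' One row per patient, columns as in [generate_cohort()]; logical history
#' flags are stored as TRUE/FALSE.
#'
#' @param cohort an `sz_cohort` data frame.
#' @param path CSV path.
#' @return `path` (write) or the cohort (read), invisibly for write.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (nm in intersect(c("prior_chd", "prior_stroke", "prior_diabetes",
                         "antihypertensive"), names(df)))
    df[[nm]] <- as.logical(df[[nm]])
  class(df) <- c("sz_cohort", "data.frame")
  df
}
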