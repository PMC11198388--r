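#' Marginal distribution of one covariate
#'
#' Declares how a single cohort covariate is simulated. Continuous covariates
#' are parameterized by their median and a spread derived from the
#' interquartile range (`(q3 - q1) / 1.349`, the IQR-to-sigma factor of the
#' normal distribution) on the modelled scale; binary covariates by their
#' prevalence; categorical covariates by level probabilities.
#'
#' @param name Covariate name (must be a valid column name).
#' @param kind One of `"normal"`, `"lognormal"`, `"bernoulli"`,
#'   `"categorical"`.
#' @param location Median for continuous kinds (natural scale, also for
#'   lognormal), prevalence in \[0, 1\] for bernoulli.
#' @param scale Non-negative spread: standard deviation for normal, log-scale
#'   standard deviation for lognormal.
#' @param levels,probs Level labels and probabilities for categorical;
#'   `probs` must sum to 1 (tolerance 1e-12).
#' @param domain Domain tag, one of `"clinical"`, `"echo"`, `"lab"`.
#' @return Object of class `marginal_spec`.
#' @seealso [normal_marginal()], [lognormal_marginal()] for IQR-based
#'   constructors.
#' @export
marginal_spec <- function(name, kind, location = NULL, scale = NULL,
                          levels = NULL, probs = NULL,
                          domain = c("clinical", "echo", "lab")) {
  domain <- match.arg(domain)
  kind <- match.arg(kind, c("normal", "lognormal", "bernoulli", "categorical"))
  if (kind %in% c("normal", "lognormal")) {
    stopifnot(is.numeric(location), is.numeric(scale))
    if (scale < 0) stop("`scale` must be >= 0")
    if (kind == "lognormal" && location <= 0) {
      stop("lognormal `location` (median) must be positive")
    }
  } else if (kind == "bernoulli") {
    stopifnot(is.numeric(location))
    if (location < 0 || location > 1) {
      stop("bernoulli prevalence must be in [0, 1]")
    }
  } else {
    stopifnot(length(levels) >= 2, length(levels) == length(probs))
    if (any(probs < 0) || abs(sum(probs) - 1) > 1e-12) {
      stop("categorical `probs` must be non-negative and sum to 1")
    }
  }
  structure(
    list(name = name, kind = kind, location = location, scale = scale,
         levels = levels, probs = probs, domain = domain),
    class = "marginal_spec"
  )
}

#' IQR-to-sigma conversion used for continuous marginals
#'
#' @param q1,q3 First and third quartile on the modelled scale.
#' @return `(q3 - q1) / 1.349`.
#' @export
iqr_scale <- function(q1, q3) {
  if (q3 < q1) stop("need q3 >= q1")
  (q3 - q1) / 1.349
}

#' @rdname marginal_spec
#' @param median,q1,q3 Printed median and quartiles on the natural scale.
#' @export
normal_marginal <- function(name, median, q1, q3, domain) {
  marginal_spec(name, "normal", location = median, scale = iqr_scale(q1, q3),
                domain = domain)
}

#' @rdname marginal_spec
#' @export
lognormal_marginal <- function(name, median, q1, q3, domain) {
  marginal_spec(name, "lognormal", location = median,
                scale = iqr_scale(log(q1), log(q3)), domain = domain)
}

sample_marginal <- function(spec, n) {
  switch(spec$kind,
    normal = stats::rnorm(n, spec$location, spec$scale),
    lognormal = stats::rlnorm(n, log(spec$location), spec$scale),
    bernoulli = stats::rbinom(n, 1L, spec$location),
    categorical = factor(
      sample(spec$levels, n, replace = TRUE, prob = spec$probs),
      levels = spec$levels
    ),
    stop("unknown marginal kind: ", spec$kind)
  )
}

#' Sample a covariate table from a list of marginals
#'
#' Covariates are drawn independently, column by column in the order of
#' `marginals`, so identical `(marginals, n, seed)` give bitwise-identical
#' tables.
#'
#' @param marginals List of [marginal_spec()] objects.
#' @param n Number of rows (>= 0).
#' @param seed Optional integer seed.
#' @return `data.frame` with one column per marginal; domain tags attached as
#'   the `"domains"` attribute (named character vector).
#' @export
sample_covariates <- function(marginals, n, seed = NULL) {
  stopifnot(is.list(marginals), n >= 0)
  bad <- !vapply(marginals, inherits, logical(1), "marginal_spec")
  if (any(bad)) stop("`marginals` must all be marginal_spec objects")
  if (!is.null(seed)) set.seed(seed)
  cols <- lapply(marginals, sample_marginal, n = n)
  names(cols) <- vapply(marginals, `[[`, character(1), "name")
  out <- as.data.frame(cols, optional = TRUE)
  if (n == 0) {
    # zero-row frame still carries the declared, typed columns
    out <- as.data.frame(lapply(marginals, function(m) {
      if (m$kind == "categorical") factor(character(0), levels = m$levels)
      else if (m$kind == "bernoulli") integer(0) else numeric(0)
    }), optional = TRUE)
    names(out) <- names(cols)
  }
  attr(out, "domains") <- stats::setNames(
    vapply(marginals, `[[`, character(1), "domain"), names(cols)
  )
  out
}

#' Default covariate marginals for a severe-sMR heart-failure cohort
#'
#' Baseline marginals matching the published cohort summaries: medians and
#' IQRs for continuous variables, prevalences for comorbidities. Right-skewed
#' laboratory markers (NT-proBNP, BUN, creatinine, bilirubin and the liver
#' enzymes) are modelled lognormal; other continuous variables normal.
#'
#' @return List of [marginal_spec()] objects.
#' @export
default_marginals <- function() {
  list(
    # clinical
    normal_marginal("age", 71, 61, 78, "clinical"),
    marginal_spec("male", "bernoulli", location = 0.60, domain = "clinical"),
    normal_marginal("bmi", 26, 24, 29, "clinical"),
    marginal_spec("hypertension", "bernoulli", location = 0.51, domain = "clinical"),
    marginal_spec("hyperlipidemia", "bernoulli", location = 0.28, domain = "clinical"),
    marginal_spec("diabetes", "bernoulli", location = 0.21, domain = "clinical"),
    marginal_spec("cad", "bernoulli", location = 0.49, domain = "clinical"),
    marginal_spec("afib", "bernoulli", location = 0.37, domain = "clinical"),
    marginal_spec("copd", "bernoulli", location = 0.13, domain = "clinical"),
    marginal_spec("cerebrovascular_disease", "bernoulli", location = 0.19, domain = "clinical"),
    marginal_spec("pad", "bernoulli", location = 0.23, domain = "clinical"),
    # echocardiographic
    normal_marginal("lvedd", 53, 47, 60, "echo"),
    normal_marginal("la_diameter", 65, 60, 71, "echo"),
    normal_marginal("rvedd", 36, 32, 40, "echo"),
    normal_marginal("ra_diameter", 61, 56, 68, "echo"),
    marginal_spec("rv_dysfunction", "bernoulli", location = 0.44, domain = "echo"),
    normal_marginal("pap", 53.6, 46, 64.8, "echo"),
    marginal_spec("tr_severity", "categorical",
                  levels = c("mild", "moderate", "severe"),
                  probs = c(331, 488, 491) / 1310, domain = "echo"),
    # laboratory
    normal_marginal("hemoglobin", 12.3, 11, 14, "lab"),
    normal_marginal("platelets", 216, 174, 273, "lab"),
    normal_marginal("wbc", 7.7, 6.2, 9.4, "lab"),
    lognormal_marginal("creatinine", 1.1, 0.9, 1.5, "lab"),
    lognormal_marginal("bun", 21.3, 15.5, 31.3, "lab"),
    normal_marginal("albumin", 37.9, 33.5, 41.6, "lab"),
    lognormal_marginal("bilirubin", 0.7, 0.5, 1.1, "lab"),
    lognormal_marginal("ast", 27, 21, 38, "lab"),
    lognormal_marginal("alt", 24, 17, 41, "lab"),
    lognormal_marginal("ggt", 58, 33, 115, "lab"),
    normal_marginal("cholesterol", 151, 120, 183, "lab"),
    lognormal_marginal("ntprobnp", 3699.5, 1703.2, 8223.5, "lab")
  )
}
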