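# Inferential layer: linear models with categorical factors and covariates,
# a single-random-intercept mixed model fitted by profiled REML, and
# Pearson's chi-square for count tables.

#' Model specification
#'
#' Declares a response, fixed categorical factors with reference levels
#' (the hierarchy reference is "dominant" and the treatment reference
#' "control" in the study's contrasts), continuous covariates, an optional
#' random intercept grouping, and optional interaction terms.
#'
#' @param response response column name.
#' @param factors named list `list(factor_name = reference_level)`.
#' @param covariates character vector of continuous covariate columns.
#' @param random_intercept optional grouping column for a random intercept.
#' @param interactions character vector of interaction terms, e.g.
#'   `"phase:change"` (the component factors must appear in `factors`).
#' @return a `model_spec` object.
#' @export
model_spec <- function(response, factors = list(), covariates = character(),
                       random_intercept = NULL, interactions = character()) {
  stopifnot(is.character(response), length(response) == 1)
  out <- list(response = response, factors = factors,
              covariates = covariates, random_intercept = random_intercept,
              interactions = interactions)
  class(out) <- "model_spec"
  out
}

# build a model frame with releveled factors and the fixed-effects formula
prepare_design <- function(data, spec) {
  need <- c(spec$response, names(spec$factors), spec$covariates,
            spec$random_intercept)
  assert_has_cols(data, need, "model data")
  keep <- complete.cases(data[, need, drop = FALSE])
  if (!all(keep)) {
    message("dropping ", sum(!keep), " row(s) with missing values")
    data <- data[keep, , drop = FALSE]
  }
  for (f in names(spec$factors)) {
    ref <- spec$factors[[f]]
    lv <- unique(as.character(data[[f]]))
    if (!ref %in% lv) {
      stop_config("reference level '", ref, "' absent from factor ", f)
    }
    data[[f]] <- relevel(factor(data[[f]]), ref = ref)
  }
  rhs <- c(names(spec$factors), spec$covariates, spec$interactions)
  if (!length(rhs)) rhs <- "1"
  fml <- as.formula(paste(spec$response, "~", paste(rhs, collapse = " + ")))
  list(data = data, formula = fml)
}

check_full_rank <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop_config("design is rank-deficient; aliased columns: ",
                paste(aliased, collapse = ", "))
  }
  invisible(qr_x)
}

fit_result <- function(coefficients, n, method, sigma, extra = list()) {
  out <- c(list(coefficients = coefficients, n = n, method = method,
                sigma = sigma), extra)
  class(out) <- "herdrank_fit"
  out
}

#' @export
print.herdrank_fit <- function(x, ...) {
  cat(x$method, "fit, n =", x$n, "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Fit an ordinary least squares model from a model spec
#'
#' Treatment (dummy) coding against the declared reference levels; fitting
#' by QR decomposition; per-coefficient t-tests on residual degrees of
#' freedom.
#'
#' @param data a data.frame.
#' @param spec a [model_spec()] (without random intercept).
#' @return a `herdrank_fit`: coefficient table (term, estimate, se, t, df,
#'   p), n, sigma.
#' @export
fit_linear_model <- function(data, spec) {
  d <- prepare_design(data, spec)
  X <- model.matrix(d$formula, d$data)
  check_full_rank(X)
  fit <- lm(d$formula, data = d$data)
  s <- summary(fit)
  cf <- s$coefficients
  coefs <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                      t = cf[, 3], df = fit$df.residual, p = cf[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  fit_result(coefs, n = nrow(d$data), method = "OLS", sigma = s$sigma,
             extra = list(formula = d$formula, lm = fit))
}

# REML criterion for variance ratio lambda = sigma_b^2 / sigma_e^2,
# for y = X beta + Z b + e with one random intercept
reml_profile <- function(log_lambda, y, X, Z) {
  lambda <- exp(log_lambda)
  n <- length(y); p <- ncol(X)
  V <- diag(n) + lambda * tcrossprod(Z)
  ch <- chol(V)
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(X, Vi_y))
  r <- y - X %*% beta
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  q <- drop(crossprod(r, Vi_r))
  logdetV <- 2 * sum(log(diag(ch)))
  crit <- logdetV + determinant(XtViX, logarithm = TRUE)$modulus +
    (n - p) * log(q)
  list(crit = as.numeric(crit), beta = beta, XtViX = XtViX,
       sigma2 = q / (n - p))
}

#' Fit a single random-intercept mixed model by profiled REML
#'
#' The model is `y = X beta + Z b + e` with `b ~ N(0, sigma_b^2)` per group
#' and `e ~ N(0, sigma_e^2)`. REML is profiled down to a one-dimensional
#' optimization over the log variance ratio `lambda = sigma_b^2/sigma_e^2`.
#' Fixed-effect t-tests use residual degrees of freedom (`n - p`), a
#' documented simplification of Satterthwaite's approximation that is
#' immaterial for sign and significance at this study's sample sizes.
#'
#' @param data a data.frame.
#' @param spec a [model_spec()] with `random_intercept` set.
#' @return a `herdrank_fit` with coefficient table and variance components
#'   `sigma_b` and `sigma` (residual).
#' @export
fit_random_intercept_model <- function(data, spec) {
  if (is.null(spec$random_intercept)) {
    stop_config("spec has no random_intercept; use fit_linear_model()")
  }
  d <- prepare_design(data, spec)
  X <- model.matrix(d$formula, d$data)
  check_full_rank(X)
  y <- d$data[[spec$response]]
  g <- factor(d$data[[spec$random_intercept]])
  if (!any(table(g) >= 2)) {
    stop_config("random intercept needs groups with >= 2 observations")
  }
  Z <- model.matrix(~ g - 1)
  opt <- optimize(function(ll) reml_profile(ll, y, X, Z)$crit,
                  interval = c(-12, 12), tol = 1e-9)
  if (!is.finite(opt$objective)) {
    stop_config("REML optimization failed; criterion at optimum: ",
                opt$objective, " (log-lambda ", opt$minimum, ")")
  }
  best <- reml_profile(opt$minimum, y, X, Z)
  sigma2 <- best$sigma2
  lambda <- exp(opt$minimum)
  se <- sqrt(diag(solve(best$XtViX)) * sigma2)
  df <- length(y) - ncol(X)
  tval <- drop(best$beta) / se
  coefs <- data.frame(term = colnames(X), estimate = drop(best$beta),
                      se = se, t = tval, df = df,
                      p = 2 * pt(-abs(tval), df),
                      row.names = NULL, stringsAsFactors = FALSE)
  fit_result(coefs, n = length(y), method = "REML random intercept",
             sigma = sqrt(sigma2),
             extra = list(sigma_b = sqrt(lambda * sigma2),
                          lambda = lambda, formula = d$formula))
}

#' Pearson's chi-square test for count data
#'
#' For a matrix, tests independence of the margins with
#' `df = (r-1)(c-1)`; for a vector with `expected` proportions, tests
#' goodness of fit with `df = k-1`. No continuity correction.
#'
#' @param observed non-negative count matrix or vector.
#' @param expected optional proportions (vector case), summing to 1.
#' @return list with statistic, df, p, expected counts.
#' @export
chi_square_counts <- function(observed, expected = NULL) {
  if (any(observed < 0)) stop_config("counts must be non-negative")
  if (is.matrix(observed) && is.null(expected)) {
    E <- outer(rowSums(observed), colSums(observed)) / sum(observed)
    df <- (nrow(observed) - 1) * (ncol(observed) - 1)
  } else {
    observed <- as.vector(observed)
    if (is.null(expected)) expected <- rep(1 / length(observed),
                                           length(observed))
    if (abs(sum(expected) - 1) > 1e-8) {
      stop_config("expected proportions must sum to 1")
    }
    E <- sum(observed) * expected
    df <- length(observed) - 1
  }
  if (any(E == 0 & observed > 0)) {
    stop_config("expected count 0 with observed > 0; merge categories")
  }
  ok <- E > 0
  stat <- sum((observed[ok] - E[ok])^2 / E[ok])
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE),
       expected = E)
}
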