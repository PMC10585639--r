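# Power analysis: analytic noncentral-F power for a p-covariate multiple
# regression, and simulation (parametric bootstrap) power for the fitted
# random-intercept models.

#' Analytic power of a multiple regression F-test
#'
#' Power of the omnibus F-test of a linear regression with `p_covariates`
#' predictors at sample size `n`, given the population proportion of
#' variance explained `r_squared`. The effect size is Cohen's
#' `f^2 = R^2 / (1 - R^2)`; the test statistic under the alternative is
#' noncentral `F(p, n - p - 1, lambda)` with noncentrality
#' `lambda = f^2 * n` (convention configurable to `f^2 * (n - p - 1)`),
#' and power is the probability of exceeding the central-F critical value.
#' At `lambda = 0` the power equals `alpha` exactly.
#'
#' @param n Number of independent sampling units (subjects).
#' @param p_covariates Number of predictors (default 3: ethnicity, age,
#'   sex).
#' @param r_squared Population `R^2` in `(0, 1)`.
#' @param alpha Significance level.
#' @param ncp_convention `"n"` (`lambda = f^2 n`, default) or
#'   `"residual"` (`lambda = f^2 (n - p - 1)`).
#' @return List of class `"power_result"`: `power`, `method = "analytic"`,
#'   `f2`, `lambda`, `df1`, `df2`, `alpha`.
#' @export
analytic_power <- function(n, p_covariates = 3L, r_squared, alpha = 0.05,
                           ncp_convention = c("n", "residual")) {
  ncp_convention <- match.arg(ncp_convention)
  stopifnot(n > p_covariates + 1, r_squared >= 0, r_squared < 1,
            alpha > 0, alpha < 1)
  f2 <- r_squared / (1 - r_squared)
  df1 <- p_covariates
  df2 <- n - p_covariates - 1
  lambda <- f2 * switch(ncp_convention, n = n, residual = df2)
  fcrit <- stats::qf(1 - alpha, df1, df2)
  power <- stats::pf(fcrit, df1, df2, ncp = lambda, lower.tail = FALSE)
  structure(list(power = power, method = "analytic", f2 = f2,
                 lambda = lambda, df1 = df1, df2 = df2, alpha = alpha),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("<power_result> %s power = %.3f", x$method, x$power))
  if (x$method == "analytic") {
    cat(sprintf(" (f^2 = %.3f, lambda = %.2f, F(%d, %d), alpha = %g)\n",
                x$f2, x$lambda, x$df1, x$df2, x$alpha))
  } else {
    cat(sprintf(" (n_sims = %d, MCSE = %.4f)\n", x$n_sims, x$mcse))
  }
  invisible(x)
}

# Simulation power on an explicit design: simulate
# y = X beta + b[subject] + e from the given variance components, refit by
# REML, and count rejections of H0: beta[target] = 0 at level alpha.
.simulate_power <- function(X, subject, beta, sigma_b2, sigma_e2, target,
                            n_sims, alpha, seed) {
  prep <- .lmm_prepare(X, subject)
  jcol <- match(target, colnames(X))
  if (is.na(jcol)) stop("unknown target coefficient '", target, "'")
  mu <- drop(X %*% beta)
  sidx <- as.integer(subject)
  n_sub <- nlevels(subject)
  set.seed(as.integer(seed))
  rej <- vapply(seq_len(n_sims), function(s) {
    b <- stats::rnorm(n_sub, 0, sqrt(sigma_b2))
    y <- mu + b[sidx] + stats::rnorm(length(mu), 0, sqrt(sigma_e2))
    f <- tryCatch(.reml_fit(prep, y), error = function(err) NULL)
    if (is.null(f)) return(NA)
    se <- sqrt(f$vcov[jcol, jcol])
    2 * stats::pnorm(-abs(f$beta[jcol] / se)) < alpha
  }, logical(1L))
  ok <- rej[!is.na(rej)]
  p_hat <- mean(ok)
  list(power = p_hat, n_sims = length(ok), n_excluded = sum(is.na(rej)),
       mcse = sqrt(p_hat * (1 - p_hat) / length(ok)))
}

#' Post hoc simulation power for a fitted sector model
#'
#' Parametric-bootstrap power at the observed design: cohorts are
#' resimulated from the fitted fixed effects and variance components on
#' the same subjects, covariates and missing-eye pattern, refitted, and
#' the power for the target coefficient is the proportion of simulations
#' with an unadjusted p-value below `alpha`.
#'
#' @param fit A converged [fit_sector()] result.
#' @param cohort The cohort the fit came from.
#' @param target Coefficient of interest: one of `"ethnicity"`, `"age"`,
#'   `"sex"` (or a full design-column name).
#' @param n_sims Number of simulated cohorts.
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @return List of class `"power_result"`: `power`, `method =
#'   "simulation"`, `n_sims`, `n_excluded`, `mcse`.
#' @export
posthoc_power <- function(fit, cohort, target = "ethnicity",
                          n_sims = 200L, alpha = 0.05, seed = 1L) {
  stopifnot(inherits(fit, "sector_fit"))
  if (!isTRUE(fit$converged)) stop("posthoc_power: fit did not converge")
  target <- switch(target,
                   ethnicity = "ethnicityGhanaian",
                   age = "age_decades",
                   sex = "sexmale",
                   target)
  des <- .lmm_design(cohort, fit$sector, fit$covariates)
  beta <- fit$coefficients$estimate
  sim <- .simulate_power(des$X, des$subject, beta, fit$sigma_b2,
                         fit$sigma_e2, target, n_sims, alpha, seed)
  structure(c(sim, list(method = "simulation", target = target,
                        alpha = alpha)),
            class = "power_result")
}
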