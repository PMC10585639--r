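# Random-intercept REML core.
#
# Model: y = X beta + Z b + e, b ~ N(0, sigma_b^2 I) one intercept per
# subject, e ~ N(0, sigma_e^2 I). With theta = sigma_b^2 / sigma_e^2 the
# marginal covariance is sigma_e^2 * V(theta), V block diagonal with
# V_i = I + theta J on a subject with n_i eyes, so
#   V_i^{-1} = I - theta/(1 + n_i theta) J,   log|V_i| = log(1 + n_i theta).
# At fixed theta, beta and sigma_e^2 have closed GLS forms; the REML
# criterion is profiled to a 1-D bounded search over log(theta).
#
# All y-dependent pieces reduce to per-subject sums, so a design can be
# prepared once and refitted against thousands of response vectors (the
# sensitivity and power simulations lean on this).

THETA_INTERVAL <- c(1e-8, 1e4)

.lmm_design <- function(cohort, response, covariates = c("ethnicity", "age", "sex")) {
  stopifnot(inherits(cohort, "cohort"))
  if (!response %in% RESPONSES) {
    stop("unknown response '", response, "'")
  }
  covariates <- match.arg(covariates, c("ethnicity", "age", "sex"),
                          several.ok = TRUE)
  keep <- !is.na(cohort[[response]])
  df <- as.data.frame(cohort)[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop("no non-missing values for response '", response, "'")
  y <- df[[response]]
  X <- matrix(1, nrow(df), 1L, dimnames = list(NULL, "(Intercept)"))
  if ("ethnicity" %in% covariates) {
    X <- cbind(X, ethnicityGhanaian = as.numeric(df$ethnicity == "Ghanaian"))
  }
  if ("age" %in% covariates) {
    X <- cbind(X, age_decades = (df$age - 60) / 10)
  }
  if ("sex" %in% covariates) {
    X <- cbind(X, sexmale = as.numeric(df$sex == "male"))
  }
  if (qr(X)$rank < ncol(X)) {
    stop("singular design: covariates are collinear in this cohort")
  }
  subject <- factor(df$subject_id, levels = unique(df$subject_id))
  list(y = y, X = X, subject = subject, response = response)
}

.lmm_prepare <- function(X, subject) {
  ni <- as.vector(table(subject))
  list(
    X = X, subject = subject,
    XtX = crossprod(X),
    S = rowsum(X, subject),   # per-subject column sums, factor-level order
    ni = ni, n = nrow(X), p = ncol(X)
  )
}

# Profile REML for one response vector against a prepared design.
.reml_fit <- function(prep, y, theta_interval = THETA_INTERVAL) {
  Xty <- crossprod(prep$X, y)[, 1L]
  ti <- rowsum(y, prep$subject)[, 1L]
  yty <- sum(y * y)
  nmp <- prep$n - prep$p

  eval_at <- function(theta) {
    ci <- theta / (1 + prep$ni * theta)
    A <- prep$XtX - crossprod(prep$S * sqrt(ci))
    bvec <- Xty - crossprod(prep$S, ci * ti)[, 1L]
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    beta <- backsolve(ch, forwardsolve(t(ch), bvec))
    rss <- (yty - sum(ci * ti^2)) - sum(beta * bvec)
    if (!is.finite(rss) || rss <= 0) return(NULL)
    s2 <- rss / nmp
    crit <- nmp * log(s2) + sum(log1p(prep$ni * theta)) + 2 * sum(log(diag(ch)))
    list(crit = crit, beta = beta, s2 = s2, ch = ch)
  }
  crit_fn <- function(lt) {
    r <- eval_at(exp(lt))
    if (is.null(r)) return(.Machine$double.xmax)
    r$crit
  }
  lo <- log(theta_interval[1L]); hi <- log(theta_interval[2L])
  opt <- stats::optimize(crit_fn, interval = c(lo, hi), tol = 1e-10)
  # guard against an interior local optimum beating an endpoint
  cand <- c(opt$minimum, lo, hi)
  vals <- vapply(cand, crit_fn, numeric(1L))
  lt_hat <- cand[which.min(vals)]
  theta <- exp(lt_hat)
  at <- eval_at(theta)
  if (is.null(at)) stop("REML fit failed: criterion not evaluable at optimum")
  vcov <- at$s2 * chol2inv(at$ch)
  dimnames(vcov) <- list(colnames(prep$X), colnames(prep$X))
  list(
    beta = setNames(at$beta, colnames(prep$X)),
    vcov = vcov,
    sigma_e2 = at$s2,
    sigma_b2 = theta * at$s2,
    theta = theta,
    reml_criterion = at$crit,
    converged = TRUE,
    at_boundary = theta <= theta_interval[1L] * 1.5
  )
}

#' Fit a per-sector random-intercept mixed model
#'
#' Fits the thickness of one ETDRS sector (or the central choroid) on
#' ethnicity, age and sex with a random intercept per subject, so that the
#' dependence between a subject's two eyes is accounted for. Estimation is
#' restricted maximum likelihood, profiled to a bounded 1-D search over
#' `theta = sigma_b^2 / sigma_e^2` on the log scale (closed-form GLS for
#' the coefficients and residual variance at fixed `theta`); the
#' `sigma_b^2 = 0` boundary is permitted. Inference is Wald: normal
#' 95% intervals (`estimate +/- 1.96 SE`) and two-sided z p-values, with a
#' Bonferroni-adjusted p-value `min(1, m * p)` for family size `m`.
#'
#' Reference levels are European ethnicity and female sex; age enters as
#' `(age - 60) / 10`, so slopes read in micrometres per decade with an
#' interpretable intercept.
#'
#' @param cohort A [cohort()].
#' @param response One of [etdrs_sectors()] or `"choroid"`. Rows with a
#'   missing response (choroid only) are dropped; subjects contributing a
#'   single eye are retained.
#' @param covariates Subset of `c("ethnicity", "age", "sex")`.
#' @param family_size Bonferroni family size `m` applied to the adjusted
#'   p-values (default 1, i.e. no adjustment; the 9-sector family is
#'   applied by [fit_all_sectors()]).
#' @param theta_interval Search interval for `theta`.
#' @return An object of class `"sector_fit"`: a list with `sector`,
#'   `coefficients` (data frame with `term`, `estimate`, `se`, `z`,
#'   `ci_lo`, `ci_hi`, `p_raw`, `p_bonferroni`), `vcov`, `sigma_b2`,
#'   `sigma_e2`, `theta`, `icc`, `n_eyes`, `n_subjects`, `converged`.
#' @export
fit_sector <- function(cohort, response,
                       covariates = c("ethnicity", "age", "sex"),
                       family_size = 1L,
                       theta_interval = THETA_INTERVAL) {
  des <- .lmm_design(cohort, response, covariates)
  grp <- table(des$subject[!duplicated(des$subject)])
  prep <- .lmm_prepare(des$X, des$subject)
  fit <- .reml_fit(prep, des$y, theta_interval)

  se <- sqrt(diag(fit$vcov))
  z <- fit$beta / se
  zc <- stats::qnorm(0.975)
  p <- 2 * stats::pnorm(-abs(z))
  coefs <- data.frame(
    term = names(fit$beta),
    estimate = unname(fit$beta),
    se = unname(se),
    z = unname(z),
    ci_lo = unname(fit$beta - zc * se),
    ci_hi = unname(fit$beta + zc * se),
    p_raw = unname(p),
    p_bonferroni = unname(bonferroni(p, family_size)),
    stringsAsFactors = FALSE
  )
  structure(list(
    sector = response,
    coefficients = coefs,
    vcov = fit$vcov,
    sigma_b2 = fit$sigma_b2,
    sigma_e2 = fit$sigma_e2,
    theta = fit$theta,
    icc = fit$sigma_b2 / (fit$sigma_b2 + fit$sigma_e2),
    reml_criterion = fit$reml_criterion,
    n_eyes = prep$n,
    n_subjects = nlevels(des$subject),
    converged = fit$converged,
    at_boundary = fit$at_boundary,
    covariates = covariates,
    family_size = as.integer(family_size)
  ), class = "sector_fit")
}

#' @export
print.sector_fit <- function(x, ...) {
  cat(sprintf("<sector_fit> response '%s': %d eyes, %d subjects\n",
              x$sector, x$n_eyes, x$n_subjects))
  cat(sprintf("variance components: sigma_b^2 = %.2f, sigma_e^2 = %.2f (ICC %.2f)\n",
              x$sigma_b2, x$sigma_e2, x$icc))
  cf <- x$coefficients
  cf$estimate <- round(cf$estimate, 2)
  cf$se <- round(cf$se, 2)
  cf$z <- round(cf$z, 2)
  cf$ci_lo <- round(cf$ci_lo, 2)
  cf$ci_hi <- round(cf$ci_hi, 2)
  cf$p_raw <- round(cf$p_raw, 3)
  cf$p_bonferroni <- round(cf$p_bonferroni, 3)
  print(cf, row.names = FALSE)
  invisible(x)
}

#' Fit all sector models with a Bonferroni family
#'
#' Runs [fit_sector()] independently for each requested response and
#' returns a tidy coefficient table. The Bonferroni family defaults to the
#' number of retinal sectors tested (9); the choroid, when analysed, is
#' conventionally treated as its own single-test family
#' (`fit_sector(cohort, "choroid")`).
#'
#' @param cohort A [cohort()].
#' @param responses Character vector of responses (default all 9 sectors).
#' @param covariates Covariates passed to [fit_sector()].
#' @param family_size Bonferroni `m` (default `length(responses)`).
#' @return Data frame with one row per response x term: `response`, `term`,
#'   `estimate`, `se`, `ci_lo`, `ci_hi`, `p_raw`, `p_adj`, `sigma_b2`,
#'   `sigma_e2`, `icc`, `n_eyes`, `n_subjects`, `converged`.
#' @export
fit_all_sectors <- function(cohort, responses = etdrs_sectors(),
                            covariates = c("ethnicity", "age", "sex"),
                            family_size = length(responses)) {
  rows <- lapply(responses, function(r) {
    f <- fit_sector(cohort, r, covariates, family_size = family_size)
    cf <- f$coefficients
    data.frame(
      response = r, term = cf$term, estimate = cf$estimate, se = cf$se,
      ci_lo = cf$ci_lo, ci_hi = cf$ci_hi, p_raw = cf$p_raw,
      p_adj = cf$p_bonferroni, sigma_b2 = f$sigma_b2, sigma_e2 = f$sigma_e2,
      icc = f$icc, n_eyes = f$n_eyes, n_subjects = f$n_subjects,
      converged = f$converged, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bonferroni correction
#'
#' `min(1, m * p)`, elementwise, order preserved. Never decreases a
#' p-value and is monotone in `p`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param m Family size, `>= 1`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1, all(p >= 0 & p <= 1, na.rm = TRUE))
  pmin(1, m * p)
}
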