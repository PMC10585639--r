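# Monte Carlo sensitivity of the ethnicity association to an unmeasured
# confounder, modelled as multiplicative measurement error: each targeted
# eye's response y is replaced by y * (1 + u) with u drawn symmetrically
# around zero and |u| <= e, for an error magnitude e on a fixed grid of
# fractions of the original measurement. At each grid level the cohort is
# repeatedly perturbed and refitted, and the proportion of simulations in
# which the ethnicity coefficient stays significant is recorded; the
# estimated error tolerance e* for a criterion c (e.g. 95% or 99%) is the
# largest grid magnitude at which the isotonically smoothed proportion has
# stayed >= c everywhere below it.

#' Sensitivity-analysis configuration
#'
#' @param error_grid Ordered error magnitudes in `[0, 1]` (fractions of the
#'   original measurement). Default `seq(0, 1, by = 0.05)`.
#' @param n_sims_per_level Simulations per grid level.
#' @param alpha Significance level applied to the unadjusted ethnicity
#'   p-value (default 0.05).
#' @param criteria Proportion criteria defining the error thresholds
#'   (default `c(0.95, 0.99)`).
#' @param target_group `"Ghanaian"` (default; only Ghanaian eyes are
#'   perturbed) or `"all"`.
#' @param response Response analysed (default `"choroid"`).
#' @param error_law `"uniform"` (`u ~ U(-e, e)`) or `"normal"`
#'   (`u ~ N(0, e^2/3)`, variance-matched to the uniform law).
#' @param seed Integer seed; results are bit-reproducible given it.
#' @param batch_size Simulations per convergence-trace batch.
#' @param mcse_tol Optional Monte Carlo SE tolerance; when set, levels are
#'   extended in batches (up to `n_max`) until the binomial MCSE of the
#'   proportion falls below it.
#' @param n_max Cap on simulations per level under adaptive extension.
#' @return List of class `"sensitivity_config"`.
#' @export
sensitivity_config <- function(error_grid = seq(0, 1, by = 0.05),
                               n_sims_per_level = 200L,
                               alpha = 0.05,
                               criteria = c(0.95, 0.99),
                               target_group = c("Ghanaian", "all"),
                               response = "choroid",
                               error_law = c("uniform", "normal"),
                               seed = 1L,
                               batch_size = 50L,
                               mcse_tol = NULL,
                               n_max = 10000L) {
  target_group <- match.arg(target_group)
  error_law <- match.arg(error_law)
  stopifnot(
    all(error_grid >= 0 & error_grid <= 1),
    !is.unsorted(error_grid, strictly = TRUE),
    n_sims_per_level >= 1, alpha > 0, alpha < 1,
    all(criteria > 0 & criteria < 1),
    response %in% RESPONSES,
    batch_size >= 1
  )
  structure(list(
    error_grid = error_grid, n_sims_per_level = as.integer(n_sims_per_level),
    alpha = alpha, criteria = sort(criteria), target_group = target_group,
    response = response, error_law = error_law, seed = as.integer(seed),
    batch_size = as.integer(batch_size), mcse_tol = mcse_tol,
    n_max = as.integer(n_max)
  ), class = "sensitivity_config")
}

.draw_error <- function(n, e, law) {
  if (e == 0) return(numeric(n))
  switch(law,
         uniform = stats::runif(n, -e, e),
         normal = stats::rnorm(n, 0, e / sqrt(3)))
}

#' Inject multiplicative measurement error into a cohort
#'
#' Replaces the response value `y` of each targeted eye by `y * (1 + u)`,
#' `u` drawn independently per eye, symmetric about zero with magnitude
#' bounded by `e` (so the error is mean-zero and at most `e * 100%` of the
#' original measurement). Covariates and untargeted records are unchanged.
#' Uses the current RNG state; seed beforehand for reproducibility.
#'
#' @param cohort A [cohort()].
#' @param e Error magnitude in `[0, 1]`.
#' @param response Response column to perturb.
#' @param target_group `"Ghanaian"` or `"all"`.
#' @param error_law `"uniform"` or `"normal"` (see [sensitivity_config()]).
#' @return A perturbed [cohort()].
#' @export
perturb_cohort <- function(cohort, e, response = "choroid",
                           target_group = c("Ghanaian", "all"),
                           error_law = c("uniform", "normal")) {
  target_group <- match.arg(target_group)
  error_law <- match.arg(error_law)
  stopifnot(inherits(cohort, "cohort"), e >= 0, e <= 1,
            response %in% RESPONSES)
  y <- cohort[[response]]
  idx <- which(!is.na(y) &
                 (target_group == "all" | cohort$ethnicity == "Ghanaian"))
  u <- .draw_error(length(idx), e, error_law)
  y[idx] <- y[idx] * (1 + u)
  out <- as.data.frame(cohort)
  out[[response]] <- y
  cohort(out, provenance = attr(cohort, "provenance"))
}

#' Run the Monte Carlo confounder-sensitivity analysis
#'
#' For each error magnitude on the grid, repeatedly perturbs the cohort
#' ([perturb_cohort()]), refits the random-intercept model of the response
#' on ethnicity, age and sex, and records whether the unadjusted ethnicity
#' p-value stays below `alpha`. Reports the per-level significance
#' proportion with its binomial Monte Carlo standard error, a batch trace
#' for convergence assessment, and the error thresholds `e*` for each
#' criterion, computed on the isotonically smoothed (non-increasing in
#' `e`) proportion curve.
#'
#' At `e = 0` the perturbation is the identity, so the proportion is
#' degenerate (exactly 0 or 1). Fit failures are counted, excluded from
#' the proportion, and flagged with a warning status when they exceed 1%
#' of simulations.
#'
#' @param cohort A [cohort()] fit-able by [fit_sector()].
#' @param config A [sensitivity_config()].
#' @return List of class `"sensitivity_result"` with `levels` (data frame
#'   `e`, `n_sims`, `n_fail`, `prop`, `prop_smooth`, `mcse`), `thresholds`
#'   (named by criterion; `NA` when the criterion already fails at the
#'   smallest grid magnitude), `trace` (per-level batch proportions),
#'   `status` (`"ok"` or `"warning"`), and the `config`.
#' @export
run_sensitivity <- function(cohort, config = sensitivity_config()) {
  stopifnot(inherits(config, "sensitivity_config"))
  des <- .lmm_design(cohort, config$response)
  prep <- .lmm_prepare(des$X, des$subject)
  jcol <- match("ethnicityGhanaian", colnames(des$X))
  if (is.na(jcol)) stop("run_sensitivity: design lacks an ethnicity term")
  y0 <- des$y
  rows <- as.data.frame(cohort)[!is.na(cohort[[config$response]]), , drop = FALSE]
  idx <- which(config$target_group == "all" | rows$ethnicity == "Ghanaian")

  set.seed(config$seed)
  lev <- vector("list", length(config$error_grid))
  trace <- vector("list", length(config$error_grid))
  for (li in seq_along(config$error_grid)) {
    e <- config$error_grid[li]
    sig <- logical(0)
    repeat {
      n_new <- if (length(sig) == 0L) config$n_sims_per_level else config$batch_size
      new <- vapply(seq_len(n_new), function(s) {
        u <- .draw_error(length(idx), e, config$error_law)
        y <- y0
        y[idx] <- y0[idx] * (1 + u)
        f <- tryCatch(.reml_fit(prep, y), error = function(err) NULL)
        if (is.null(f)) return(NA)
        se <- sqrt(f$vcov[jcol, jcol])
        p <- 2 * stats::pnorm(-abs(f$beta[jcol] / se))
        p < config$alpha
      }, logical(1L))
      sig <- c(sig, new)
      ok <- sig[!is.na(sig)]
      phat <- mean(ok)
      mcse <- sqrt(phat * (1 - phat) / length(ok))
      if (is.null(config$mcse_tol) || mcse <= config$mcse_tol ||
          length(sig) >= config$n_max) break
    }
    ok <- sig[!is.na(sig)]
    phat <- mean(ok)
    lev[[li]] <- data.frame(
      e = e, n_sims = length(ok), n_fail = sum(is.na(sig)), prop = phat,
      mcse = sqrt(phat * (1 - phat) / length(ok))
    )
    nb <- length(ok) %/% config$batch_size
    trace[[li]] <- if (nb >= 1L) {
      vapply(seq_len(nb), function(b) {
        mean(ok[((b - 1L) * config$batch_size + 1L):(b * config$batch_size)])
      }, numeric(1L))
    } else phat
  }
  levels <- do.call(rbind, lev)

  # isotonic (non-increasing in e) smoothing, then threshold extraction
  levels$prop_smooth <- -stats::isoreg(levels$e, -levels$prop)$yf
  thresholds <- vapply(config$criteria, function(cr) {
    ok <- levels$prop_smooth >= cr
    first_bad <- which(!ok)[1L]
    if (is.na(first_bad)) max(levels$e)
    else if (first_bad == 1L) NA_real_
    else levels$e[first_bad - 1L]
  }, numeric(1L))
  names(thresholds) <- sprintf("e_star_%g", 100 * config$criteria)

  fail_rate <- sum(levels$n_fail) / sum(levels$n_sims + levels$n_fail)
  structure(list(
    levels = levels[c("e", "n_sims", "n_fail", "prop", "prop_smooth", "mcse")],
    thresholds = thresholds,
    trace = trace,
    status = if (fail_rate > 0.01) "warning" else "ok",
    fail_rate = fail_rate,
    config = config
  ), class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> response '%s', %d grid levels, status %s\n",
              x$config$response, nrow(x$levels), x$status))
  print(transform(x$levels, prop = round(prop, 3),
                  prop_smooth = round(prop_smooth, 3),
                  mcse = round(mcse, 4)), row.names = FALSE)
  cat("thresholds:",
      paste(sprintf("%s = %s", names(x$thresholds),
                    ifelse(is.na(x$thresholds), "none", x$thresholds)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Monte Carlo convergence check for a batch trace
#'
#' Given per-batch significance proportions, computes the running pooled
#' proportion and its binomial Monte Carlo standard error, declares
#' convergence when the final MCSE is below `mcse_tol`, and extrapolates
#' the number of simulations needed from the binomial variance
#' (`n = p(1-p) / tol^2`).
#'
#' @param batch_props Numeric vector of per-batch proportions (>= 2
#'   batches).
#' @param batch_size Simulations per batch.
#' @param mcse_tol Target Monte Carlo SE.
#' @return List with `converged`, `mcse` (running trace), `p_hat`,
#'   `n_recommended`.
#' @export
check_convergence <- function(batch_props, batch_size, mcse_tol) {
  stopifnot(length(batch_props) >= 2L, batch_size >= 1, mcse_tol > 0,
            all(batch_props >= 0 & batch_props <= 1))
  running_p <- cumsum(batch_props) / seq_along(batch_props)
  n_run <- batch_size * seq_along(batch_props)
  mcse <- sqrt(running_p * (1 - running_p) / n_run)
  p_hat <- running_p[length(running_p)]
  list(
    converged = mcse[length(mcse)] < mcse_tol,
    mcse = mcse,
    p_hat = p_hat,
    n_recommended = ceiling(p_hat * (1 - p_hat) / mcse_tol^2)
  )
}
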