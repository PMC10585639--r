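test_that("REML fixed effects match the explicit block-covariance GLS oracle", {
  for (seed in c(11L, 23L, 37L)) {
    co <- random_small_cohort(8L, seed)
    f <- fit_sector(co, "c0")
    oracle <- gls_oracle(co, "c0", f$theta)
    expect_lt(max(abs(f$coefficients$estimate - oracle)), 1e-6)
  }
})

test_that("with one eye per subject the fit collapses to ordinary least squares", {
  cfg <- mod_config(seed = 3L, eye_missing_prob = 0)
  co <- generate_cohort(cfg)$cohort
  one_eye <- cohort(as.data.frame(co)[co$eye == "OD", ])
  f <- fit_sector(one_eye, "p_inf")
  df <- as.data.frame(one_eye)
  ols <- stats::lm(p_inf ~ I(ethnicity == "Ghanaian") + I((age - 60) / 10) +
                     I(sex == "male"), data = df)
  expect_lt(max(abs(f$coefficients$estimate - unname(stats::coef(ols)))), 1e-8)
})

test_that("the REML fit agrees with lme4 on a default cohort", {
  skip_if_not_installed("lme4")
  co <- generate_cohort(default_config(17L))$cohort
  for (resp in c("c0", "choroid")) {
    f <- fit_sector(co, resp)
    df <- as.data.frame(co)
    df$gh <- as.numeric(df$ethnicity == "Ghanaian")
    df$dec <- (df$age - 60) / 10
    df$male <- as.numeric(df$sex == "male")
    m <- lme4::lmer(stats::reformulate(c("gh", "dec", "male", "(1 | subject_id)"),
                                       resp),
                    data = df, REML = TRUE)
    expect_lt(max(abs(f$coefficients$estimate - unname(lme4::fixef(m)))), 1e-5)
    vc <- as.data.frame(lme4::VarCorr(m))
    expect_equal(f$sigma_b2, vc$vcov[1L], tolerance = 1e-4)
    expect_equal(f$sigma_e2, vc$vcov[2L], tolerance = 1e-4)
    expect_lt(max(abs(f$coefficients$se -
                        sqrt(diag(as.matrix(stats::vcov(m)))))), 1e-4)
  }
})

test_that("singular designs are reported as errors", {
  co <- as.data.frame(generate_cohort(default_config(2L))$cohort)
  co <- co[co$ethnicity == "European", ]
  expect_error(fit_sector(cohort(co), "c0"), "singular")
})

test_that("the intraclass correlation is recovered across replicates", {
  cfg <- mod_config(n_ghanaian = 250L, n_european = 250L)
  rho_hat <- vapply(1:40, function(i) {
    cfg$seed <- 5000L + i
    co <- generate_cohort(cfg)$cohort
    fit_sector(co, "c0")$icc
  }, numeric(1L))
  expect_lt(abs(mean(rho_hat) - 0.8), 0.05)
})

test_that("ethnicity effects are recovered without material bias in all responses", {
  cfg <- mod_config(n_ghanaian = 250L, n_european = 250L)
  responses <- c(etdrs_sectors(), "choroid")
  est <- matrix(NA_real_, 25L, length(responses),
                dimnames = list(NULL, responses))
  for (i in 1:25) {
    cfg$seed <- 7700L + i
    co <- generate_cohort(cfg)$cohort
    fits <- fit_all_sectors(co, responses)
    eth <- fits[fits$term == "ethnicityGhanaian", ]
    est[i, eth$response] <- eth$estimate
  }
  mean_est <- colMeans(est)
  expect_true(all(mean_est < 0))
  expect_true(all(abs(mean_est - cfg$beta_eth[responses]) <
                    0.10 * abs(cfg$beta_eth[responses])))
})

test_that("bonferroni is the capped multiple and never decreases a p-value", {
  expect_equal(bonferroni(0.01, 9), 0.09)
  expect_equal(bonferroni(0.2, 9), 1.0)
  p <- c(0.001, 0.03, 0.5, 1)
  expect_equal(bonferroni(p, 9), pmin(1, 9 * p))
  expect_true(all(bonferroni(p, 5) >= p))
  # monotone: order of adjusted values follows order of raw values
  expect_true(!is.unsorted(bonferroni(sort(p), 3)))
  expect_error(bonferroni(1.2, 9))
})

test_that("inter-eye correlation matches the covariance formula and handles r = 1", {
  co <- toy_cohort(6L)
  # toy cohort has OS = OD + 2 exactly -> r = 1, degenerate CI
  r1 <- intereye_correlation(co, "c0")
  expect_equal(r1$r, 1)
  expect_equal(r1$ci95, c(1, 1))

  co2 <- generate_cohort(mod_config(seed = 8L, eye_missing_prob = 0))$cohort
  res <- intereye_correlation(co2, "p_tem")
  df <- as.data.frame(co2)
  od <- df[df$eye == "OD", "p_tem"]
  os <- df[df$eye == "OS", "p_tem"]
  r_direct <- sum((od - mean(od)) * (os - mean(os))) /
    sqrt(sum((od - mean(od))^2) * sum((os - mean(os))^2))
  expect_equal(res$r, r_direct, tolerance = 1e-10)
  ct <- stats::cor.test(od, os)
  expect_equal(res$ci95, as.numeric(ct$conf.int), tolerance = 1e-8)
  expect_error(intereye_correlation(toy_cohort(1L), "c0"), ">= 4")
})

test_that("Bland-Altman bias and limits of agreement follow the hand formula", {
  co <- toy_cohort(5L)  # OS = OD + 2 exactly
  ba <- bland_altman(co, "f_sup")
  expect_equal(ba$bias, -2)
  expect_equal(ba$loa_low, -2)
  expect_equal(ba$loa_high, -2)

  co2 <- generate_cohort(mod_config(seed = 14L, eye_missing_prob = 0))$cohort
  ba2 <- bland_altman(co2, "c0")
  df <- as.data.frame(co2)
  d <- df[df$eye == "OD", "c0"] - df[df$eye == "OS", "c0"]
  expect_equal(ba2$bias, mean(d), tolerance = 1e-12)
  expect_equal(ba2$loa_high, mean(d) + 1.96 * stats::sd(d), tolerance = 1e-12)
  expect_equal(ba2$loa_low, 2 * ba2$bias - ba2$loa_high, tolerance = 1e-12)
})

test_that("the Yates chi-square matches the continuity-corrected formula", {
  yates_oracle <- function(tab) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum(pmax(0, abs(tab - E) - 0.5)^2 / E)
  }
  set.seed(4)
  for (i in 1:6) {
    tab <- matrix(stats::rpois(4, 20) + 1L, 2L, 2L)
    expect_equal(sex_chi_square(tab)$statistic, yates_oracle(tab),
                 tolerance = 1e-12)
  }
  prop <- matrix(c(10, 10, 10, 10), 2L)
  expect_equal(sex_chi_square(prop)$statistic, 0)
  expect_error(sex_chi_square(matrix(c(0, 0, 5, 5), 2L)), "zero margin")
})

test_that("the age rank-sum statistic matches pair counting and the exact permutation p", {
  build <- function(eur_ages, gha_ages) {
    rows <- list()
    mk <- function(id, eth, age) {
      rec <- data.frame(subject_id = id, ethnicity = eth, age = age,
                        sex = "female", eye = "OD", stringsAsFactors = FALSE)
      for (s in etdrs_sectors()) rec[[s]] <- 300
      rec$choroid <- 250
      rec
    }
    for (i in seq_along(eur_ages)) rows[[length(rows) + 1L]] <-
      mk(sprintf("E%d", i), "European", eur_ages[i])
    for (i in seq_along(gha_ages)) rows[[length(rows) + 1L]] <-
      mk(sprintf("G%d", i), "Ghanaian", gha_ages[i])
    cohort(do.call(rbind, rows))
  }
  u_count <- function(x, y) {
    sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  # identical groups: W at the midrank centre, p near 1
  co <- build(c(50, 55, 60, 65), c(50, 55, 60, 65))
  res <- age_rank_sum(co)
  expect_equal(res$statistic, 4 * 4 / 2)
  expect_gt(res$p_value, 0.9)
  # complete separation: minimal statistic for the first group
  res2 <- age_rank_sum(build(c(41, 42), c(80, 81)))
  expect_equal(res2$statistic, 0)

  set.seed(6)
  for (i in 1:4) {
    eur <- round(stats::runif(4, 40, 80))
    gha <- round(stats::runif(4, 40, 80))
    res <- age_rank_sum(build(eur, gha))
    expect_equal(res$statistic, u_count(eur, gha))
    # exact permutation distribution of U, n <= 8
    all_ages <- c(eur, gha)
    combos <- utils::combn(8L, 4L)
    u_perm <- apply(combos, 2L, function(idx) {
      u_count(all_ages[idx], all_ages[-idx])
    })
    obs <- u_count(eur, gha)
    p_exact <- mean(abs(u_perm - 8) >= abs(obs - 8) - 1e-12)
    expect_lt(abs(res$p_value - p_exact), 0.1)
  }
})

test_that("the descriptives report bundles all summaries coherently", {
  co <- generate_cohort(default_config(10L))$cohort
  rep <- descriptives_report(co)
  expect_equal(nrow(rep$intereye), 9L)
  expect_true(all(rep$intereye$r >= -1 & rep$intereye$r <= 1))
  # limits of agreement symmetric about the bias
  expect_equal(rep$intereye$loa_high - rep$intereye$bias,
               rep$intereye$bias - rep$intereye$loa_low, tolerance = 1e-10)
  expect_true(rep$sex_test$statistic >= 0)
  expect_true(rep$age_test$p_value >= 0 && rep$age_test$p_value <= 1)
})
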