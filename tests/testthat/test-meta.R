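make_studies <- function(means, sds, ns, sector = "c0",
                         mean_age = seq(25, by = 10, length.out = length(means))) {
  data.frame(
    label = sprintf("study%02d", seq_along(means)),
    population = "African American", mean_age = mean_age, sector = sector,
    mean = means, sd = sds, n = ns, ci_lo = NA_real_, ci_hi = NA_real_,
    se = NA_real_, eye = "OD", device = "Cirrus HD-OCT", healthy = TRUE,
    stringsAsFactors = FALSE
  )
}

test_that("DerSimonian-Laird pooling matches the hand formula oracle", {
  st <- make_studies(c(250, 260, 280), c(10, 10, 10), c(25, 25, 25))
  p <- pool_studies(st, "c0")
  # independent hand evaluation
  y <- c(250, 260, 280); v <- rep(100 / 25, 3L); w <- 1 / v
  ybar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar)^2)
  tau2 <- max(0, (Q - 2) / (sum(w) - sum(w^2) / sum(w)))
  wstar <- 1 / (v + tau2)
  pooled <- sum(wstar * y) / sum(wstar)
  expect_equal(p$Q, Q, tolerance = 1e-10)
  expect_equal(p$tau2, tau2, tolerance = 1e-10)
  expect_equal(p$pooled_mean, pooled, tolerance = 1e-10)
  expect_equal(p$I2, max(0, (Q - 2) / Q) * 100, tolerance = 1e-10)
  expect_equal(p$ci95, pooled + c(-1, 1) * stats::qnorm(0.975) / sqrt(sum(wstar)),
               tolerance = 1e-10)
})

test_that("pooling agrees with metafor's DL estimator", {
  skip_if_not_installed("metafor")
  set.seed(15)
  st <- make_studies(stats::rnorm(6, 260, 15), stats::runif(6, 8, 25),
                     sample(30:150, 6L))
  p <- pool_studies(st, "c0")
  m <- metafor::rma(yi = st$mean, vi = st$sd^2 / st$n, method = "DL")
  expect_equal(p$pooled_mean, as.numeric(m$beta), tolerance = 1e-8)
  expect_equal(p$tau2, m$tau2, tolerance = 1e-8)
  expect_equal(p$Q, m$QE, tolerance = 1e-8)
  expect_equal(p$I2, m$I2, tolerance = 1e-6)
  expect_equal(p$se, m$se, tolerance = 1e-8)
})

test_that("degenerate pooling cases behave as closed forms require", {
  one <- pool_studies(make_studies(255, 12, 40), "c0")
  expect_equal(one$k, 1L)
  expect_equal(one$pooled_mean, 255)
  expect_equal(one$Q, 0)
  expect_equal(one$tau2, 0)
  expect_equal(one$I2, 0)

  same <- pool_studies(make_studies(rep(260, 4), rep(10, 4), rep(30, 4)), "c0")
  expect_equal(same$tau2, 0)
  expect_equal(same$I2, 0)
  expect_equal(same$pooled_mean, 260)

  expect_error(pool_studies(make_studies(250, 10, 20), "p_sup"), "no records")
})

test_that("pooling invariants hold: order invariance, I2-Q link, CI width", {
  set.seed(30)
  st <- make_studies(stats::rnorm(5, 255, 12), stats::runif(5, 10, 20),
                     sample(25:90, 5L))
  p1 <- pool_studies(st, "c0")
  p2 <- pool_studies(st[sample(nrow(st)), ], "c0")
  expect_equal(p1$pooled_mean, p2$pooled_mean, tolerance = 1e-12)
  expect_equal(p1$tau2, p2$tau2, tolerance = 1e-12)
  expect_true(p1$I2 >= 0 && p1$I2 <= 100)
  expect_identical(p1$I2 == 0, p1$Q <= p1$df)

  # tau2 = 0 (homogeneous): pooled CI no wider than the widest study CI
  hom <- make_studies(c(258, 259, 260), c(12, 14, 13), c(40, 35, 50))
  ph <- pool_studies(hom, "c0")
  expect_equal(ph$tau2, 0)
  widest <- max(2 * stats::qnorm(0.975) * hom$sd / sqrt(hom$n))
  expect_lte(diff(ph$ci95), widest)
})

test_that("eligibility screening applies the rules in order with reasons", {
  st <- make_studies(c(250, 255, 260), c(10, NA, 10), c(25, 40, 30))
  st$mean_age[3L] <- NA          # -> no age
  st$ci_lo[2L] <- 255 - 1.96 * 10 / sqrt(40)
  st$ci_hi[2L] <- 255 + 1.96 * 10 / sqrt(40)
  extra <- make_studies(270, 10, 35)
  extra$healthy <- FALSE
  noeye <- make_studies(240, NA, 20)   # no sd, no ci, no se -> no dispersion
  res <- filter_eligible(rbind(st, extra, noeye))

  expect_equal(sort(res$excluded$reason),
               sort(c("no age", "not healthy-only", "no dispersion")))
  expect_equal(nrow(res$eligible), 2L)
  # CI-derived SD inverts the forward computation sd -> ci
  ci_row <- res$eligible[res$eligible$sd_from == "ci", ]
  expect_equal(ci_row$sd, 10 * 1.96 / (3.92 / 2), tolerance = 1e-6)
})

test_that("SE-derived dispersion is back-converted to an SD", {
  st <- make_studies(250, NA, 64)
  st$se <- 2.5
  res <- filter_eligible(st)
  expect_equal(res$eligible$sd, 2.5 * 8)
  expect_equal(res$eligible$sd_from, "se")
})

test_that("eye selection is reproducible, identity on single-eye rows, and unbiased", {
  single <- make_studies(250, 10, 25)
  expect_identical(select_eye(single, seed = 3L)$mean, single$mean)

  both <- rbind(make_studies(250, 10, 25), make_studies(255, 10, 25))
  both$eye <- c("OD", "OS")
  both$label <- "studyX"
  s1 <- select_eye(both, seed = 7L)
  s2 <- select_eye(both, seed = 7L)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 1L)

  # 10^4 independent study pairs: each eye picked ~50%
  n <- 10000L
  big <- data.frame(
    label = rep(sprintf("s%05d", seq_len(n)), each = 2L),
    population = "x", mean_age = 30, sector = "c0",
    mean = rep(c(1, 2), n), sd = 1, n = 10, ci_lo = NA_real_,
    ci_hi = NA_real_, se = NA_real_, eye = rep(c("OD", "OS"), n),
    device = "d", healthy = TRUE, stringsAsFactors = FALSE
  )
  sel <- select_eye(big, seed = 99L)
  frac_od <- mean(sel$eye == "OD")
  expect_lt(abs(frac_od - 0.5), 0.015)
})

test_that("age stratification uses half-open decade bins", {
  st <- make_studies(rep(250, 5), rep(10, 5), rep(30, 5),
                     mean_age = c(21, 28.9, 47.7, 49, 30))
  binned <- stratify_by_age(st)
  expect_equal(binned$age_group,
               c("[20,30)", "[20,30)", "[40,50)", "[40,50)", "[30,40)"))
  pools <- pool_by_age(binned, "c0")
  expect_setequal(names(pools), c("[20,30)", "[30,40)", "[40,50)"))
  expect_equal(pools[["[20,30)"]]$k, 2L)
})

test_that("group comparison adds variances and the forest table has k + 1 rows", {
  st <- make_studies(c(250, 252, 251), c(10, 10, 10), c(40, 40, 40))
  p <- pool_studies(st, "c0")
  same <- compare_groups(p, list(mean = p$pooled_mean, se = 0))
  expect_equal(same$difference, 0)

  ref <- list(mean = 260, ci95 = c(260 - 1.96 * 3, 260 + 1.96 * 3))
  cmp <- compare_groups(p, ref)
  se_d <- sqrt(p$se^2 + 3^2)
  expect_equal(cmp$difference, p$pooled_mean - 260, tolerance = 1e-10)
  expect_equal(cmp$ci_hi - cmp$difference, 1.96 * se_d, tolerance = 1e-3)
  expect_error(compare_groups(p, list(sector = "p_sup", mean = 1, se = 1)),
               "mismatch")

  ft <- forest_table(p)
  expect_equal(nrow(ft), p$k + 1L)
  expect_true(ft$pooled[nrow(ft)])
})

test_that("the bundled synthetic study table flows through the whole meta pipeline", {
  path <- system.file("extdata", "studies_synthetic.csv", package = "octnorms")
  st <- read_studies(path)
  res <- filter_eligible(st)
  expect_true("no age" %in% res$excluded$reason)
  sel <- select_eye(res$eligible, seed = 1L)
  pools <- pool_by_age(sel, "c0")
  expect_true(length(pools) >= 2L)
  for (p in pools) expect_true(is.finite(p$pooled_mean) && p$pooled_mean > 0)
})
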