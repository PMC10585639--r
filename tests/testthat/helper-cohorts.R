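# Shared fixture builders: everything is generated in code, seeded.

toy_grid <- function(value = 300) {
  stats::setNames(rep(value, 9L), etdrs_sectors())
}

# A small hand-built cohort: n_sub subjects alternating group and sex,
# both eyes, deterministic thickness values.
toy_cohort <- function(n_sub = 4L, choroid = TRUE) {
  rows <- list()
  for (i in seq_len(n_sub)) {
    base <- 250 + 5 * i
    for (eye in c("OD", "OS")) {
      rec <- data.frame(
        subject_id = sprintf("S%02d", i),
        ethnicity = if (i %% 2L == 0L) "Ghanaian" else "European",
        age = 50 + i,
        sex = if (i %% 3L == 0L) "male" else "female",
        eye = eye,
        stringsAsFactors = FALSE
      )
      for (s in etdrs_sectors()) rec[[s]] <- base + (eye == "OS") * 2
      rec$choroid <- if (choroid) base - 30 else NA_real_
      rows[[length(rows) + 1L]] <- rec
    }
  }
  cohort(do.call(rbind, rows), provenance = "toy")
}

# Config helper: default config with scalar overrides broadcast across
# all responses.
mod_config <- function(seed = 1L, n_ghanaian = NULL, n_european = NULL,
                       beta_eth = NULL, beta_age = NULL, beta_sex = NULL,
                       sigma_b = NULL, sigma_e = NULL,
                       eye_missing_prob = NULL) {
  cfg <- default_config(seed)
  if (!is.null(n_ghanaian)) cfg$n_ghanaian <- as.integer(n_ghanaian)
  if (!is.null(n_european)) cfg$n_european <- as.integer(n_european)
  for (fld in c("beta_eth", "beta_age", "beta_sex", "sigma_b", "sigma_e")) {
    v <- get(fld)
    if (!is.null(v)) cfg[[fld]][] <- v
  }
  if (!is.null(eye_missing_prob)) cfg$eye_missing_prob[] <- eye_missing_prob
  validate_config(cfg)
}

# Random small cohort for oracle checks: n_sub subjects, random 1-2 eyes.
random_small_cohort <- function(n_sub, seed) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_sub)) {
    eyes <- if (stats::runif(1) < 0.3) "OD" else c("OD", "OS")
    b <- stats::rnorm(1, 0, 12)
    eth <- sample(c("Ghanaian", "European"), 1L)
    age <- round(stats::runif(1, 40, 85), 1)
    sex <- sample(c("female", "male"), 1L)
    for (eye in eyes) {
      rec <- data.frame(
        subject_id = sprintf("R%02d", i),
        ethnicity = eth, age = age, sex = sex,
        eye = eye, stringsAsFactors = FALSE
      )
      for (s in etdrs_sectors()) {
        rec[[s]] <- 280 + b + stats::rnorm(1, 0, 8)
      }
      rec$choroid <- 250 + b + stats::rnorm(1, 0, 8)
      rows[[length(rows) + 1L]] <- rec
    }
  }
  df <- do.call(rbind, rows)
  # guarantee both ethnicities so the design is nonsingular
  df$ethnicity[df$subject_id == "R01"] <- "European"
  df$ethnicity[df$subject_id == sprintf("R%02d", n_sub)] <- "Ghanaian"
  cohort(df, provenance = sprintf("random_small seed %d", seed))
}

# Explicit dense-GLS oracle: assemble V = I + theta * Z Z' per subject and
# solve (X' V^-1 X) beta = X' V^-1 y directly.
gls_oracle <- function(cohort, response, theta) {
  des <- octnorms:::.lmm_design(cohort, response)
  Z <- stats::model.matrix(~ 0 + des$subject)
  V <- diag(length(des$y)) + theta * tcrossprod(Z)
  Vi <- solve(V)
  A <- t(des$X) %*% Vi %*% des$X
  drop(solve(A, t(des$X) %*% Vi %*% des$y))
}
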