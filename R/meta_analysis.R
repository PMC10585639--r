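# Random-effects meta-analysis of per-sector mean thickness across
# published studies: eligibility screening, random single-eye selection,
# DerSimonian-Laird pooling with Cochran's Q and I^2, age-group
# stratification, and comparison against a reference cohort.
#
# Study tables are long data frames, one row per study x sector, with
# columns: label, population, mean_age, sector, mean, sd, n, ci_lo, ci_hi,
# se, eye, device, healthy. Dispersion may arrive as an SD, a 95% CI or an
# SE; CIs/SEs are back-converted to SDs assuming normality
# (sd = sqrt(n) * (ci_hi - ci_lo) / 3.92, sd = se * sqrt(n)).

STUDY_COLUMNS <- c("label", "population", "mean_age", "sector", "mean",
                   "sd", "n", "ci_lo", "ci_hi", "se", "eye", "device",
                   "healthy")

#' Read a study-summary table for meta-analysis
#'
#' @param path CSV with the columns listed above; empty fields are `NA`.
#' @return Data frame of study records.
#' @export
read_studies <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(STUDY_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("read_studies: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df[STUDY_COLUMNS]
}

#' Screen study records for meta-analysis eligibility
#'
#' Applies the inclusion rules in order and attaches the first failed rule
#' to each exclusion: a record must (1) report a mean in a known ETDRS
#' sector, (2) carry dispersion convertible to an SD (SD, 95% CI or SE),
#' (3) state the sample size, (4) state the imaging device, (5) state the
#' participants' mean (or median) age, and (6) concern healthy subjects
#' only. CI- or SE-derived SDs are back-computed under normality and the
#' conversion route recorded in `sd_from`.
#'
#' @param records Long study data frame (see [read_studies()]).
#' @return List with `eligible` (records with `sd` filled and `sd_from`
#'   added) and `excluded` (records with a `reason` column).
#' @export
filter_eligible <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  reason <- rep(NA_character_, nrow(records))
  sd_out <- records$sd
  sd_from <- rep(NA_character_, nrow(records))

  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (is.na(r$sector) || !(r$sector %in% RESPONSES) || is.na(r$mean)) {
      reason[i] <- "no sector mean"
    } else if (!is.na(r$sd) && r$sd > 0) {
      sd_from[i] <- "sd"
    } else if (!is.na(r$ci_lo) && !is.na(r$ci_hi) && r$ci_hi > r$ci_lo &&
               !is.na(r$n)) {
      sd_out[i] <- sqrt(r$n) * (r$ci_hi - r$ci_lo) / 3.92
      sd_from[i] <- "ci"
    } else if (!is.na(r$se) && r$se > 0 && !is.na(r$n)) {
      sd_out[i] <- r$se * sqrt(r$n)
      sd_from[i] <- "se"
    } else {
      reason[i] <- "no dispersion"
    }
    if (is.na(reason[i])) {
      if (is.na(r$n) || r$n < 1) reason[i] <- "no sample size"
      else if (is.na(r$device) || !nzchar(r$device)) reason[i] <- "no device"
      else if (is.na(r$mean_age)) reason[i] <- "no age"
      else if (is.na(r$healthy) || !as.logical(r$healthy)) {
        reason[i] <- "not healthy-only"
      }
    }
  }
  keep <- is.na(reason)
  eligible <- records[keep, , drop = FALSE]
  eligible$sd <- sd_out[keep]
  eligible$sd_from <- sd_from[keep]
  excluded <- records[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  rownames(eligible) <- rownames(excluded) <- NULL
  list(eligible = eligible, excluded = excluded)
}

#' Randomly select one eye per study and sector
#'
#' Where a study reports both eyes separately (an `OD` and an `OS` row for
#' the same study and sector), one is selected uniformly at random;
#' single-eye, bilateral-average (`both`) and `unspecified` rows pass
#' through unchanged. Seeded and reproducible.
#'
#' @param records Long study data frame.
#' @param seed Integer seed.
#' @return The records with one row per study x sector.
#' @export
select_eye <- function(records, seed = 1L) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  set.seed(as.integer(seed))
  key <- paste(records$label, records$sector, sep = "\r")
  keep <- rep(TRUE, nrow(records))
  for (rows in split(seq_len(nrow(records)), factor(key, unique(key)))) {
    eyes <- records$eye[rows]
    if (length(rows) == 2L && setequal(eyes, c("OD", "OS"))) {
      chosen <- sample(c("OD", "OS"), 1L)
      keep[rows[eyes != chosen]] <- FALSE
    }
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' DerSimonian-Laird random-effects pooling for one sector
#'
#' Pools per-study mean thicknesses with inverse-variance weights
#' `w_i = n_i / sd_i^2`, computing Cochran's heterogeneity statistic
#' `Q = sum w_i (y_i - ybar)^2` about the fixed-effect mean, the
#' DerSimonian-Laird moment estimate
#' `tau^2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`,
#' `I^2 = max(0, (Q - df) / Q) * 100`, and the random-effects pooled mean
#' with weights `1 / (v_i + tau^2)` and a normal 95% CI.
#'
#' @param records Eligible long study records (SD filled; see
#'   [filter_eligible()]).
#' @param sector Sector to pool.
#' @return List of class `"pooled_estimate"`: `sector`, `k`, `pooled_mean`,
#'   `ci95`, `se`, `tau2`, `Q`, `df`, `I2` (percent), `p_Q`, `studies`
#'   (data frame with per-study `y`, `v`, random-effects `weight`).
#' @export
pool_studies <- function(records, sector) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  rows <- records[!is.na(records$sector) & records$sector == sector, ,
                  drop = FALSE]
  k <- nrow(rows)
  if (k == 0L) stop("pool_studies: no records for sector '", sector, "'")
  if (any(is.na(rows$sd) | rows$sd <= 0 | is.na(rows$n) | rows$n < 1)) {
    stop("pool_studies: records must carry sd > 0 and n >= 1; run filter_eligible() first")
  }
  y <- rows$mean
  v <- rows$sd^2 / rows$n
  w <- 1 / v
  ybar <- sum(w * y) / sum(w)
  Q <- if (k == 1L) 0 else sum(w * (y - ybar)^2)
  df <- k - 1L
  tau2 <- if (k == 1L) 0 else max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  wstar <- 1 / (v + tau2)
  pooled <- sum(wstar * y) / sum(wstar)
  se <- 1 / sqrt(sum(wstar))
  zc <- stats::qnorm(0.975)
  structure(list(
    sector = sector, k = k, pooled_mean = pooled,
    ci95 = c(pooled - zc * se, pooled + zc * se), se = se,
    tau2 = tau2, Q = Q, df = df, I2 = I2,
    p_Q = if (df > 0) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_,
    studies = data.frame(label = rows$label, y = y, v = v,
                         weight = wstar / sum(wstar),
                         stringsAsFactors = FALSE)
  ), class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "<pooled_estimate> sector '%s': %d studies, pooled %.2f um [%.2f; %.2f]\n",
    x$sector, x$k, x$pooled_mean, x$ci95[1L], x$ci95[2L]))
  cat(sprintf("Q = %.2f (df %d, p = %.3f), tau^2 = %.2f, I^2 = %.1f%%\n",
              x$Q, x$df, x$p_Q, x$tau2, x$I2))
  invisible(x)
}

#' Stratify study records into decade age bins
#'
#' Half-open decade bins `[20, 30)`, `[30, 40)`, ... on the study mean
#' age, so verbal groupings like "between 20 and 30 years" are reproduced
#' exactly and a boundary age (30.0) falls into the upper bin.
#'
#' @param records Long study data frame with `mean_age`.
#' @return The records with an `age_group` character column (`"[lo,hi)"`).
#' @export
stratify_by_age <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  lo <- 10 * floor(records$mean_age / 10)
  records$age_group <- ifelse(is.na(lo), NA_character_,
                              sprintf("[%d,%d)", lo, lo + 10L))
  records
}

#' Pool a sector within each age group
#'
#' @param records Eligible long study records.
#' @param sector Sector to pool.
#' @return Named list of [pool_studies()] results, one per age bin
#'   containing the sector.
#' @export
pool_by_age <- function(records, sector) {
  records <- stratify_by_age(records)
  records <- records[!is.na(records$sector) & records$sector == sector, ,
                     drop = FALSE]
  bins <- sort(unique(records$age_group))
  setNames(lapply(bins, function(b) {
    pool_studies(records[records$age_group == b, , drop = FALSE], sector)
  }), bins)
}

#' Compare a pooled estimate with a reference group
#'
#' Difference (pooled minus reference) with a 95% CI from independent
#' normal variance addition. The reference is given as a mean plus either
#' a 95% CI or an SE.
#'
#' @param pooled A [pool_studies()] result.
#' @param reference List with `mean` and either `ci95` (length 2) or `se`;
#'   an optional `sector` is checked against the pooled sector.
#' @return Data frame row: `sector`, `difference`, `ci_lo`, `ci_hi`, `se`.
#' @export
compare_groups <- function(pooled, reference) {
  stopifnot(inherits(pooled, "pooled_estimate"))
  if (!is.null(reference$sector) && reference$sector != pooled$sector) {
    stop("compare_groups: sector mismatch: '", pooled$sector, "' vs '",
         reference$sector, "'")
  }
  se_ref <- if (!is.null(reference$se)) reference$se
  else (reference$ci95[2L] - reference$ci95[1L]) / (2 * stats::qnorm(0.975))
  d <- pooled$pooled_mean - reference$mean
  se_d <- sqrt(pooled$se^2 + se_ref^2)
  zc <- stats::qnorm(0.975)
  data.frame(sector = pooled$sector, difference = d,
             ci_lo = d - zc * se_d, ci_hi = d + zc * se_d, se = se_d,
             stringsAsFactors = FALSE)
}

#' Forest-plot table for a pooled sector
#'
#' One row per study plus a final pooled row, ready for plotting or
#' export.
#'
#' @param pooled A [pool_studies()] result.
#' @return Data frame with `label`, `mean`, `ci_lo`, `ci_hi`, `weight`,
#'   `pooled` (logical); `nrow = k + 1`.
#' @export
forest_table <- function(pooled) {
  stopifnot(inherits(pooled, "pooled_estimate"))
  zc <- stats::qnorm(0.975)
  st <- pooled$studies
  rbind(
    data.frame(label = st$label, mean = st$y,
               ci_lo = st$y - zc * sqrt(st$v), ci_hi = st$y + zc * sqrt(st$v),
               weight = st$weight, pooled = FALSE, stringsAsFactors = FALSE),
    data.frame(label = "Pooled", mean = pooled$pooled_mean,
               ci_lo = pooled$ci95[1L], ci_hi = pooled$ci95[2L],
               weight = 1, pooled = TRUE, stringsAsFactors = FALSE)
  )
}
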