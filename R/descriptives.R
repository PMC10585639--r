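# Descriptive statistics: inter-eye agreement and the demographic
# comparisons that accompany a two-group cohort table.

.eye_pairs <- function(cohort, sector) {
  stopifnot(inherits(cohort, "cohort"))
  if (!sector %in% RESPONSES) stop("unknown sector '", sector, "'")
  df <- as.data.frame(cohort)[!is.na(cohort[[sector]]), , drop = FALSE]
  od <- df[df$eye == "OD", c("subject_id", sector)]
  os <- df[df$eye == "OS", c("subject_id", sector)]
  m <- merge(od, os, by = "subject_id", suffixes = c("_od", "_os"))
  m[order(match(m$subject_id, df$subject_id)), , drop = FALSE]
}

#' Inter-eye Pearson correlation with Fisher-z confidence interval
#'
#' Pearson correlation between right- and left-eye measurements of the
#' subjects contributing both eyes, with a 95% CI from the Fisher z
#' transform (`atanh(r) +/- 1.96 / sqrt(n - 3)`, back-transformed).
#'
#' @param cohort A [cohort()].
#' @param sector A response name (sector or `"choroid"`).
#' @return List with `r`, `ci95` (length-2), `n_pairs`.
#' @export
intereye_correlation <- function(cohort, sector) {
  m <- .eye_pairs(cohort, sector)
  n <- nrow(m)
  if (n < 4L) stop("intereye_correlation: need >= 4 both-eye subjects, have ", n)
  r <- stats::cor(m[[2L]], m[[3L]])
  if (abs(r) >= 1 - 1e-15) {
    ci <- c(r, r)
  } else {
    z <- atanh(r)
    hw <- stats::qnorm(0.975) / sqrt(n - 3)
    ci <- tanh(c(z - hw, z + hw))
  }
  list(r = r, ci95 = ci, n_pairs = n)
}

#' Bland-Altman inter-eye agreement
#'
#' Bias (mean right-minus-left difference) and 95% limits of agreement
#' (`bias +/- 1.96 SD` of the differences) for one response.
#'
#' @inheritParams intereye_correlation
#' @return List with `bias`, `loa_low`, `loa_high`, `sd_diff`, `n_pairs`.
#' @export
bland_altman <- function(cohort, sector) {
  m <- .eye_pairs(cohort, sector)
  n <- nrow(m)
  if (n < 2L) stop("bland_altman: need >= 2 both-eye subjects, have ", n)
  d <- m[[2L]] - m[[3L]]
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, n_pairs = n)
}

.subject_table <- function(cohort) {
  df <- as.data.frame(cohort)
  df[!duplicated(df$subject_id), c("subject_id", "ethnicity", "age", "sex")]
}

#' Sex-by-ethnicity chi-square test
#'
#' Pearson chi-square with Yates continuity correction (df = 1) on the
#' 2x2 subject-level table of sex by ethnicity.
#'
#' @param x A [cohort()], or a 2x2 integer matrix of counts (rows =
#'   groups, columns = sexes).
#' @return List with `statistic`, `p_value`, `table`.
#' @export
sex_chi_square <- function(x) {
  if (inherits(x, "cohort")) {
    s <- .subject_table(x)
    tab <- table(factor(s$ethnicity, ETHNICITY_LEVELS),
                 factor(s$sex, SEX_LEVELS))
  } else {
    tab <- as.table(as.matrix(x))
    if (!all(dim(tab) == c(2L, 2L))) stop("sex_chi_square: need a 2x2 table")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("sex_chi_square: zero margin in the 2x2 table")
  }
  ct <- stats::chisq.test(tab, correct = TRUE)
  list(statistic = unname(ct$statistic), p_value = ct$p.value, table = tab)
}

#' Wilcoxon rank-sum comparison of age between groups
#'
#' Two-sample Wilcoxon rank-sum test on subject ages, European group
#' first, using midranks for ties and the normal approximation with
#' continuity correction. The statistic is the Mann-Whitney form of the
#' first group, as R's [stats::wilcox.test()] reports it.
#'
#' @param cohort A [cohort()].
#' @return List with `statistic` (W), `p_value`, `n` (per-group counts).
#' @export
age_rank_sum <- function(cohort) {
  s <- .subject_table(cohort)
  eur <- s$age[s$ethnicity == "European"]
  gha <- s$age[s$ethnicity == "Ghanaian"]
  if (length(eur) < 2L || length(gha) < 2L) {
    stop("age_rank_sum: need >= 2 subjects per group")
  }
  wt <- suppressWarnings(
    stats::wilcox.test(eur, gha, exact = FALSE, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n = c(European = length(eur), Ghanaian = length(gha)))
}

#' Cohort descriptives report
#'
#' Bundles the per-response inter-eye correlation (with Fisher-z CI),
#' Bland-Altman bias and limits of agreement, the sex-by-group Yates
#' chi-square and the age rank-sum test into one report.
#'
#' @param cohort A [cohort()].
#' @param sectors Responses to summarise (default the 9 retinal sectors).
#' @return List of class `"descriptives_report"` with `intereye` (data
#'   frame), `sex_test`, `age_test`.
#' @export
descriptives_report <- function(cohort, sectors = etdrs_sectors()) {
  rows <- lapply(sectors, function(s) {
    r <- intereye_correlation(cohort, s)
    ba <- bland_altman(cohort, s)
    data.frame(sector = s, r = r$r, r_ci_lo = r$ci95[1L], r_ci_hi = r$ci95[2L],
               bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
               n_pairs = r$n_pairs, stringsAsFactors = FALSE)
  })
  structure(list(
    intereye = do.call(rbind, rows),
    sex_test = sex_chi_square(cohort),
    age_test = age_rank_sum(cohort)
  ), class = "descriptives_report")
}
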