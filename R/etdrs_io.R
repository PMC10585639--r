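# Canonical sector enumeration: central fovea, then the parafoveal (1-3 mm,
# "p_") and perifoveal (3-6 mm, "f_") rings, each split into superior, nasal,
# inferior and temporal quadrants. Nasal/temporal are anatomical.
ETDRS_SECTORS <- c(
  "c0",
  "p_sup", "p_nas", "p_inf", "p_tem",
  "f_sup", "f_nas", "f_inf", "f_tem"
)

COHORT_COLUMNS <- c(
  "subject_id", "ethnicity", "age", "sex", "eye",
  ETDRS_SECTORS, "choroid"
)

ETHNICITY_LEVELS <- c("European", "Ghanaian")
SEX_LEVELS <- c("female", "male")
EYE_LEVELS <- c("OD", "OS")

#' ETDRS sector names
#'
#' Canonical names of the 9 ETDRS macular grid sectors used throughout the
#' package: `c0` (central 1 mm fovea), `p_*` (parafoveal ring, 1-3 mm) and
#' `f_*` (perifoveal ring, 3-6 mm), with suffixes `sup`/`nas`/`inf`/`tem`
#' for the superior, nasal, inferior and temporal quadrants.
#'
#' @return Character vector of length 9.
#' @export
#' @examples
#' etdrs_sectors()
etdrs_sectors <- function() ETDRS_SECTORS

#' Construct a validated cohort of per-eye thickness records
#'
#' A cohort is a data frame with one row per imaged eye, holding subject
#' covariates (ethnicity, age in years, sex), eye laterality (`OD` right /
#' `OS` left), the 9 ETDRS sector thicknesses and (optionally) central
#' choroidal thickness, all in micrometres. Construction enforces the data
#' model invariants:
#'
#' * all retinal sector values finite and positive (a row must be complete);
#' * choroid optional (`NA`), but finite and positive where present;
#' * age within 18-110 years;
#' * at most one record per (subject, eye);
#' * covariates constant across a subject's two eyes.
#'
#' @param records Data frame with columns
#'   `subject_id, ethnicity, age, sex, eye, c0, p_sup, p_nas, p_inf, p_tem,
#'   f_sup, f_nas, f_inf, f_tem, choroid`.
#' @param provenance Free-text origin of the data (file path or generator
#'   seed); stored as an attribute.
#' @return The validated data frame with class `"cohort"`. Row order is
#'   preserved.
#' @export
cohort <- function(records, provenance = "in-memory") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(COHORT_COLUMNS, names(records))
  if (length(missing_cols) > 0L) {
    stop("cohort: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  records <- records[COHORT_COLUMNS]
  records$subject_id <- as.character(records$subject_id)

  if (nrow(records) > 0L) {
    .check_enum(records$ethnicity, ETHNICITY_LEVELS, "ethnicity")
    .check_enum(records$sex, SEX_LEVELS, "sex")
    .check_enum(records$eye, EYE_LEVELS, "eye")

    if (!is.numeric(records$age) || anyNA(records$age) ||
        any(records$age < 18 | records$age > 110)) {
      stop("cohort: age must be numeric within [18, 110]")
    }
    for (s in ETDRS_SECTORS) {
      v <- records[[s]]
      if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)) || any(v <= 0)) {
        stop("cohort: sector '", s, "' must be finite and > 0 in every row")
      }
    }
    ch <- records$choroid
    if (!is.numeric(ch)) stop("cohort: choroid must be numeric (NA allowed)")
    bad_ch <- !is.na(ch) & (!is.finite(ch) | ch <= 0)
    if (any(bad_ch)) stop("cohort: choroid must be finite and > 0 where present")

    key <- paste(records$subject_id, records$eye, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- records[duplicated(key), , drop = FALSE][1L, ]
      stop("cohort: integrity error: duplicate record for subject '",
           dup$subject_id, "', eye ", dup$eye)
    }
    cov <- unique(records[c("subject_id", "ethnicity", "age", "sex")])
    if (anyDuplicated(cov$subject_id)) {
      bad <- cov$subject_id[duplicated(cov$subject_id)][1L]
      stop("cohort: integrity error: inconsistent covariates for subject '",
           bad, "'")
    }
  }
  rownames(records) <- NULL
  structure(records, provenance = provenance,
            class = c("cohort", "data.frame"))
}

.check_enum <- function(x, levels, name) {
  if (!all(x %in% levels)) {
    stop("cohort: ", name, " must be one of: ", paste(levels, collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.cohort <- function(x, ...) {
  subj <- x[!duplicated(x$subject_id), ]
  grp <- table(subj$ethnicity)
  cat(sprintf("<cohort> %d eye records, %d subjects (%s)\n",
              nrow(x), nrow(subj),
              paste(sprintf("%d %s", as.integer(grp), names(grp)),
                    collapse = " + ")))
  cat("provenance:", attr(x, "provenance"), "\n")
  print(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("...", nrow(x) - 4L, "more rows\n")
  invisible(x)
}

#' Read a cohort from CSV
#'
#' Reads a per-eye thickness table in the canonical CSV dialect (comma
#' separated, `.` decimal mark, LF line endings, UTF-8; header exactly the
#' canonical column order; missing choroid encoded as an empty field) and
#' validates all cohort invariants.
#'
#' @param path Path to a CSV file.
#' @return A [cohort()] with `provenance` set to `path`.
#' @seealso [write_cohort()] for the inverse; the two are a bit-exact
#'   round trip on canonical files.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("read_cohort: '", path, "': missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  numeric_cols <- c("age", ETDRS_SECTORS, "choroid")
  for (col in numeric_cols) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & nzchar(raw))
    if (length(bad) > 0L) {
      stop(sprintf(
        "read_cohort: parse error in '%s': row %d, column '%s': '%s' is not a number",
        path, bad[1L], col, raw[bad[1L]]))
    }
    if (col != "choroid") {
      empty <- which(!nzchar(raw))
      if (length(empty) > 0L) {
        stop(sprintf(
          "read_cohort: parse error in '%s': row %d, column '%s' is empty",
          path, empty[1L], col))
      }
    }
    df[[col]] <- val
  }
  cohort(df, provenance = path)
}

#' Write a cohort to CSV
#'
#' Writes the canonical, deterministic CSV form: canonical column order,
#' all thickness and age values with exactly 2 decimal places, missing
#' choroid as an empty field, LF line endings, no quoting. Writing then
#' re-reading yields an equal cohort, and `write(read(f))` is byte-identical
#' to a canonical `f`.
#'
#' @param x A [cohort()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  fmt <- function(v) {
    out <- formatC(v, format = "f", digits = 2)
    out[is.na(v)] <- ""
    out
  }
  cols <- list(
    x$subject_id, x$ethnicity, fmt(x$age), x$sex, x$eye
  )
  for (s in ETDRS_SECTORS) cols[[length(cols) + 1L]] <- fmt(x[[s]])
  cols[[length(cols) + 1L]] <- fmt(x$choroid)
  lines <- c(paste(COHORT_COLUMNS, collapse = ","),
             if (nrow(x) > 0L) do.call(paste, c(cols, sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Resolve an ETDRS grid to the canonical anatomical orientation
#'
#' ETDRS quadrants are reported anatomically (nasal/temporal), so a right
#' (OD) and a left (OS) eye map mirror each other horizontally on screen.
#' Device software normally exports anatomical labels already, in which case
#' this function is the identity. For screen-oriented exports
#' (`input = "screen"`), the nasal and temporal quadrants of an OS grid are
#' swapped in both rings; applying the transform twice restores the input.
#'
#' @param grid Named numeric vector with the 9 sector names of
#'   [etdrs_sectors()].
#' @param eye `"OD"` or `"OS"`.
#' @param input `"anatomical"` (default; identity) or `"screen"`.
#' @return The grid in canonical anatomical orientation, ordered as
#'   [etdrs_sectors()].
#' @export
orient_grid <- function(grid, eye, input = c("anatomical", "screen")) {
  input <- match.arg(input)
  eye <- match.arg(eye, EYE_LEVELS)
  if (!setequal(names(grid), ETDRS_SECTORS)) {
    stop("orient_grid: grid must have exactly the 9 ETDRS sector names")
  }
  g <- grid[ETDRS_SECTORS]
  if (input == "screen" && eye == "OS") {
    swap <- c(p_nas = "p_tem", p_tem = "p_nas", f_nas = "f_tem", f_tem = "f_nas")
    g[names(swap)] <- grid[swap]
  }
  g
}
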