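#' Read and write cohort tables
#'
#' The canonical cohort CSV dialect has columns `id, age, sex, bmi,
#' prior_fracture, parental_hip_fracture, current_smoking,
#' glucocorticoids, rheumatoid_arthritis, secondary_osteoporosis,
#' alcohol_3plus, fn_tscore, followup_years, hip_fracture_observed`; flags
#' are 0/1 and a missing value is an empty field. Extra columns are
#' preserved; column order is immaterial. Reading validates the flags and
#' errors with the offending row numbers; writing is lossless (round
#' trips are exact to CSV numeric precision).
#'
#' @param path CSV path.
#' @param cohort Cohort `data.frame`.
#' @return `read_cohort()` returns the cohort `data.frame`;
#'   `write_cohort()` returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 na.strings = c("", "NA"))
  miss <- setdiff(COHORT_COLUMNS, names(df))
  if (length(miss))
    stop("cohort file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (f in c(FLAG_COLUMNS, "hip_fracture_observed")) {
    v <- df[[f]]
    bad <- which(!is.na(v) & !v %in% c(0, 1))
    if (length(bad))
      stop("column '", f, "' has non-0/1 values in row(s) ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
    df[[f]] <- as.integer(v)
  }
  df$age <- as.numeric(df$age)
  df$bmi <- as.numeric(df$bmi)
  df$fn_tscore <- as.numeric(df$fn_tscore)
  df$followup_years <- as.numeric(df$followup_years)
  df
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  extra <- setdiff(names(cohort), COHORT_COLUMNS)
  df <- cohort[c(COHORT_COLUMNS, extra)]
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v)
    ifelse(is.na(v), "", sprintf("%.17g", v)))
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
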