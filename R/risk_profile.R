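#' Construct a fracture risk profile
#'
#' One person's input vector for the probability engine: age, sex, BMI, the
#' seven dichotomous clinical risk factors, and an optional femoral-neck
#' T-score. Ages outside the operational range 40--90 are clamped to it with
#' a warning (the engine, like FRAX calculators, is defined on that range).
#'
#' @param age Age in years.
#' @param sex `"female"` or `"male"`.
#' @param bmi Body mass index, kg/m2 (> 0).
#' @param prior_fracture,parental_hip_fracture,current_smoking,glucocorticoids,rheumatoid_arthritis,secondary_osteoporosis,alcohol_3plus
#'   Dichotomous risk-factor flags, 0/1 (or logical).
#' @param fn_tscore Femoral-neck BMD T-score in SD units, or `NA` for an
#'   assessment "without BMD". When present must lie in \[-6, 4\].
#' @return An object of class `risk_profile` (a named list).
#' @examples
#' risk_profile(age = 65, bmi = 23, prior_fracture = 1)
#' @export
risk_profile <- function(age, sex = "female", bmi = 23,
                         prior_fracture = 0, parental_hip_fracture = 0,
                         current_smoking = 0, glucocorticoids = 0,
                         rheumatoid_arthritis = 0,
                         secondary_osteoporosis = 0, alcohol_3plus = 0,
                         fn_tscore = NA_real_) {
  flags <- c(prior_fracture = prior_fracture,
             parental_hip_fracture = parental_hip_fracture,
             current_smoking = current_smoking,
             glucocorticoids = glucocorticoids,
             rheumatoid_arthritis = rheumatoid_arthritis,
             secondary_osteoporosis = secondary_osteoporosis,
             alcohol_3plus = alcohol_3plus)
  flags <- vapply(flags, as.numeric, numeric(1))
  if (any(!flags %in% c(0, 1)))
    stop("risk-factor flags must be strictly 0/1", call. = FALSE)
  if (!is.finite(age)) stop("age must be finite", call. = FALSE)
  if (age < 40 || age > 90) {
    warning("age ", age, " clamped to the operational range [40, 90]",
            call. = FALSE)
    age <- min(max(age, 40), 90)
  }
  if (!is.finite(bmi) || bmi <= 0) stop("bmi must be > 0", call. = FALSE)
  sex <- match.arg(sex, c("female", "male"))
  if (!is.na(fn_tscore) &&
      (!is.finite(fn_tscore) || fn_tscore < -6 || fn_tscore > 4))
    stop("fn_tscore must be finite and within [-6, 4]", call. = FALSE)
  structure(c(list(age = age, sex = sex, bmi = bmi), as.list(flags),
              list(fn_tscore = fn_tscore)),
            class = "risk_profile")
}

#' @export
print.risk_profile <- function(x, ...) {
  on <- FLAG_COLUMNS[unlist(x[FLAG_COLUMNS]) == 1]
  cat(sprintf("<risk_profile> %s, age %.1f, BMI %.1f, T-score %s\n",
              x$sex, x$age, x$bmi,
              if (is.na(x$fn_tscore)) "absent" else sprintf("%.2f", x$fn_tscore)))
  cat("  risk factors:",
      if (length(on)) paste(on, collapse = ", ") else "none", "\n")
  invisible(x)
}

# Coerce a risk_profile or cohort data.frame into a plain data.frame of
# engine inputs (one row per person). Ages outside the operational range
# [40, 90] are clamped with a warning, as in risk_profile().
.as_profile_frame <- function(x) {
  if (inherits(x, "risk_profile")) {
    as.data.frame(unclass(x), stringsAsFactors = FALSE)
  } else if (is.data.frame(x)) {
    need <- c("age", "bmi", FLAG_COLUMNS)
    miss <- setdiff(need, names(x))
    if (length(miss))
      stop("cohort is missing columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (is.null(x$fn_tscore)) x$fn_tscore <- NA_real_
    out_of_range <- !is.na(x$age) & (x$age < 40 | x$age > 90)
    if (any(out_of_range)) {
      warning(sum(out_of_range), " age(s) clamped to the operational ",
              "range [40, 90]", call. = FALSE)
      x$age <- pmin(pmax(x$age, 40), 90)
    }
    x
  } else {
    stop("expected a risk_profile or a cohort data.frame", call. = FALSE)
  }
}
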