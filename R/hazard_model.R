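#' Construct a fracture/death hazard model
#'
#' A `hazard_model` bundles the age-indexed annual hazards of first major
#' osteoporotic fracture (MOF), first hip fracture and death for one
#' population (ethnicity), together with multiplicative clinical-risk-factor
#' effects and a femoral-neck BMD gradient. It is the transparent,
#' configurable engine behind all 10-year probabilities in this package; it
#' is not a reproduction of any proprietary FRAX coefficient set.
#'
#' Each baseline hazard is either a Gompertz law `h(a) = alpha * exp(beta *
#' a)` (`list(gompertz = c(alpha, beta))`) or an age-indexed table
#' (`list(age = ..., hazard = ...)`, linearly interpolated between nodes).
#' Hazards must be finite and non-negative on the full age grid 40--100
#' years (a 90-year-old still needs hazards out to age 100 for a 10-year
#' horizon).
#'
#' Individual risk scales the fracture hazards by
#' `exp(sum(flag * log_rr) + bmi_per_unit * (bmi - bmi_reference) +
#' bmd_log_rr_per_sd * (tscore_mean(age) - fn_tscore))`;
#' the death hazard is shared across risk profiles (no excess mortality from
#' the risk factors). The BMD term is centred on the age-specific population
#' mean T-score, so a woman at the reference T-score has the same risk with
#' and without BMD by construction.
#'
#' @param ethnicity Population label, e.g. `"chinese"`.
#' @param mof,hip,death Baseline hazard specifications (see Details).
#' @param log_rr Named list of log relative risks, one per dichotomous
#'   clinical risk factor, plus `bmi_per_unit` (log RR per BMI unit above
#'   `bmi_reference`; typically negative).
#' @param bmi_reference BMI (kg/m2) at which the BMI term vanishes.
#' @param bmd_log_rr_per_sd Log risk gradient per 1 SD *lower* femoral-neck
#'   T-score (positive: lower bone density, higher risk).
#' @param tscore_reference List with `mean_age60` (population mean T-score
#'   at age 60), `slope_per_year` (change in mean per year of age) and `sd`.
#' @return An object of class `hazard_model`.
#' @seealso [ten_year_probability()], [read_hazard_model()],
#'   [default_hazard_models()]
#' @export
hazard_model <- function(ethnicity, mof, hip, death, log_rr,
                         bmi_reference = 25,
                         bmd_log_rr_per_sd = 0.47,
                         tscore_reference = list(mean_age60 = -1.84,
                                                 slope_per_year = -0.03,
                                                 sd = 0.87)) {
  model <- structure(
    list(ethnicity = ethnicity,
         mof = .as_hazard_fun(mof, "mof"),
         hip = .as_hazard_fun(hip, "hip"),
         death = .as_hazard_fun(death, "death"),
         log_rr = log_rr,
         bmi_reference = bmi_reference,
         bmd_log_rr_per_sd = bmd_log_rr_per_sd,
         tscore_reference = tscore_reference),
    class = "hazard_model")
  validate_hazard_model(model)
  model
}

# Normalise a hazard spec into list(kind, params) with an evaluator.
.as_hazard_fun <- function(spec, label) {
  if (!is.null(spec$gompertz)) {
    g <- as.numeric(spec$gompertz)
    if (length(g) != 2L || any(!is.finite(g)) || g[1] < 0)
      stop("invalid gompertz spec for '", label, "' hazard", call. = FALSE)
    list(kind = "gompertz", alpha = g[1], beta = g[2])
  } else if (!is.null(spec$age)) {
    age <- as.numeric(spec$age); hz <- as.numeric(spec$hazard)
    if (length(age) != length(hz) || is.unsorted(age, strictly = TRUE))
      stop("hazard table for '", label, "' needs strictly increasing ages",
           call. = FALSE)
    if (min(age) > 40 || max(age) < 100)
      stop("hazard table for '", label, "' must cover ages 40-100",
           call. = FALSE)
    list(kind = "table", age = age, hazard = hz)
  } else {
    stop("hazard spec for '", label,
         "' must have a 'gompertz' or 'age'/'hazard' entry", call. = FALSE)
  }
}

validate_hazard_model <- function(model) {
  grid <- 40:100
  for (nm in c("mof", "hip", "death")) {
    h <- baseline_hazard(model, nm, grid)
    if (any(!is.finite(h)) || any(h < 0))
      stop("baseline '", nm, "' hazard must be finite and >= 0 on ages 40-100",
           call. = FALSE)
  }
  lr <- model$log_rr
  if (is.null(lr$prior_fracture) || lr$prior_fracture <= 0)
    stop("prior_fracture relative risk must exceed 1 ",
         "(required so the intervention threshold sits above the lower ",
         "assessment threshold)", call. = FALSE)
  if (any(!is.finite(unlist(lr))))
    stop("all log relative risks must be finite", call. = FALSE)
  invisible(model)
}

#' Baseline annual hazard at given ages
#'
#' @param model A [hazard_model()].
#' @param outcome One of `"mof"`, `"hip"`, `"death"`.
#' @param age Vector of ages in years; must lie within the model grid
#'   (40--100).
#' @param extend Internal: hold the hazard at its age-100 value beyond the
#'   grid (used by the integrators when a long follow-up runs past 100)
#'   instead of raising a range error.
#' @return Vector of annual hazards (per person-year).
#' @export
baseline_hazard <- function(model, outcome = c("mof", "hip", "death"), age,
                            extend = FALSE) {
  outcome <- match.arg(outcome)
  if (extend) age <- pmin(age, 100)
  bad <- age[age < 40 - 1e-9 | age > 100 + 1e-9]
  if (length(bad))
    stop("age ", round(bad[1], 2), " outside the hazard grid [40, 100]",
         call. = FALSE)
  h <- model[[outcome]]
  if (h$kind == "gompertz") {
    h$alpha * exp(h$beta * age)
  } else {
    approx(h$age, h$hazard, xout = age, rule = 2)$y
  }
}

#' Population mean femoral-neck T-score at a given age
#'
#' Linear-in-age reference used to centre the BMD effect.
#' @inheritParams baseline_hazard
#' @param age Ages in years.
#' @return Mean T-scores (SD units).
#' @export
tscore_mean_at <- function(model, age) {
  r <- model$tscore_reference
  r$mean_age60 + r$slope_per_year * (age - 60)
}

#' @export
print.hazard_model <- function(x, ...) {
  cat("<hazard_model>", x$ethnicity, "\n")
  for (nm in c("mof", "hip", "death")) {
    h <- x[[nm]]
    if (h$kind == "gompertz")
      cat(sprintf("  %-5s Gompertz alpha=%.4g beta=%.4g\n", nm, h$alpha, h$beta))
    else
      cat(sprintf("  %-5s table on %d ages [%g, %g]\n", nm,
                  length(h$age), min(h$age), max(h$age)))
  }
  rr <- exp(unlist(x$log_rr))
  cat("  relative risks:",
      paste(sprintf("%s=%.2f", names(rr), rr), collapse = ", "), "\n")
  cat(sprintf("  BMD gradient: RR %.2f per SD lower T-score\n",
              exp(x$bmd_log_rr_per_sd)))
  invisible(x)
}

#' Read or write a hazard model as YAML
#'
#' The YAML layout carries `ethnicity`, `gompertz:` (or `table:`) blocks for
#' `mof`/`hip`/`death`, a `log_rr:` mapping (including `bmi_per_unit`),
#' `bmi_reference`, `bmd_log_rr_per_sd` and `tscore_reference`.
#'
#' @param path File path.
#' @return `read_hazard_model()` returns a [hazard_model()];
#'   `write_hazard_model()` returns `path` invisibly.
#' @export
read_hazard_model <- function(path) {
  y <- yaml::read_yaml(path)
  haz <- function(nm) {
    if (!is.null(y$gompertz[[nm]])) list(gompertz = y$gompertz[[nm]])
    else if (!is.null(y$table[[nm]])) y$table[[nm]]
    else stop("no '", nm, "' hazard in ", path, call. = FALSE)
  }
  hazard_model(ethnicity = y$ethnicity,
               mof = haz("mof"), hip = haz("hip"), death = haz("death"),
               log_rr = y$log_rr,
               bmi_reference = y$bmi_reference %||% 25,
               bmd_log_rr_per_sd = y$bmd_log_rr_per_sd,
               tscore_reference = y$tscore_reference)
}

#' @rdname read_hazard_model
#' @param model A [hazard_model()].
#' @export
write_hazard_model <- function(model, path) {
  block <- function(h) {
    if (h$kind == "gompertz") c(h$alpha, h$beta) else NULL
  }
  tbl <- function(h) {
    if (h$kind == "table") list(age = h$age, hazard = h$hazard) else NULL
  }
  y <- list(ethnicity = model$ethnicity,
            gompertz = Filter(Negate(is.null),
                              list(mof = block(model$mof),
                                   hip = block(model$hip),
                                   death = block(model$death))),
            table = Filter(Negate(is.null),
                           list(mof = tbl(model$mof), hip = tbl(model$hip),
                                death = tbl(model$death))),
            log_rr = model$log_rr,
            bmi_reference = model$bmi_reference,
            bmd_log_rr_per_sd = model$bmd_log_rr_per_sd,
            tscore_reference = model$tscore_reference)
  y <- Filter(function(el) length(el) > 0, y)
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

#' Default per-ethnicity hazard models
#'
#' Three population models (Chinese, Malay, Indian) with Gompertz baseline
#' hazards anchored so that a 62-year-old woman of average BMI with no
#' clinical risk factors has 10-year probabilities of the same order as a
#' Singaporean cohort mean (MOF around 6-7%, hip around 2%), and
#' literature-magnitude relative risks (prior fracture 1.8, glucocorticoids
#' 1.7, parental hip fracture 1.5, rheumatoid arthritis 1.4, alcohol 1.4,
#' secondary osteoporosis 1.3, smoking 1.25). These are explicitly *not*
#' FRAX coefficients; the non-Chinese baselines are documented placeholders
#' (0.9x and 0.8x the Chinese level).
#'
#' @return Named list of [hazard_model()] objects.
#' @export
default_hazard_models <- function() {
  log_rr <- list(prior_fracture = log(1.8),
                 parental_hip_fracture = log(1.5),
                 current_smoking = log(1.25),
                 glucocorticoids = log(1.7),
                 rheumatoid_arthritis = log(1.4),
                 secondary_osteoporosis = log(1.3),
                 alcohol_3plus = log(1.4),
                 bmi_per_unit = -0.03)
  tref <- list(mean_age60 = -1.839, slope_per_year = -0.03, sd = 0.87)
  mk <- function(ethnicity, scale) {
    hazard_model(ethnicity = ethnicity,
                 mof = list(gompertz = c(scale * 2.316e-05, 0.085)),
                 hip = list(gompertz = c(scale * 2.062e-06, 0.105)),
                 death = list(gompertz = c(2.5e-05, 0.092)),
                 log_rr = log_rr,
                 bmi_reference = 25,
                 bmd_log_rr_per_sd = log(1.6),
                 tscore_reference = tref)
  }
  list(chinese = mk("chinese", 1), malay = mk("malay", 0.9),
       indian = mk("indian", 0.8))
}
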