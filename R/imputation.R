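# Fixed covariate sets for the simulated (imputed) variables. These are the
# conditional models used to carry risk-factor structure from a fully
# observed reference cohort into a cohort that lacks the variable.
IMPUTATION_COVARIATES <- list(
  parental_hip_fracture = c("age", "prior_fracture"),
  glucocorticoids = c("age", "sex", "bmi"),
  rheumatoid_arthritis = c("sex", "bmi", "prior_fracture"),
  fn_tscore = c("age", "bmi", "prior_fracture", "current_smoking")
)

# Design matrix (with intercept) for a covariate set; sex enters as an
# indicator for male. Errors name the first offending record and covariate.
.imputation_design <- function(cohort, covariates, factor) {
  X <- matrix(1, nrow(cohort), 1, dimnames = list(NULL, "(Intercept)"))
  for (cv in covariates) {
    if (is.null(cohort[[cv]]))
      stop("covariate '", cv, "' required to impute '", factor,
           "' is absent from the cohort", call. = FALSE)
    v <- if (cv == "sex") as.numeric(cohort$sex == "male") else
      as.numeric(cohort[[cv]])
    if (anyNA(v))
      stop("covariate '", cv, "' is missing in record ",
           which(is.na(v))[1], " (needed to impute '", factor, "')",
           call. = FALSE)
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- if (cv == "sex") "sex_male" else cv
  }
  X
}

#' Fit the missing-variable imputation model on a reference cohort
#'
#' Fits, on a fully observed reference cohort, the factor-specific
#' conditional regressions used to simulate variables that a target cohort
#' lacks: maximum-likelihood logistic regressions for parental hip fracture
#' (on age and prior fracture), glucocorticoid use (on age, sex and BMI)
#' and rheumatoid arthritis (on sex, BMI and prior fracture), and an
#' ordinary least-squares regression for the femoral-neck T-score (on age,
#' BMI, prior fracture and smoking) whose root-mean-square residual is
#' retained as the stochastic spread.
#'
#' A factor that is constant in the reference (all 0 or all 1) cannot
#' support a regression; it falls back to an intercept-only prevalence
#' model with a warning.
#'
#' @param reference Fully observed cohort `data.frame` (>= 200 records)
#'   with all risk factors and `fn_tscore` present.
#' @return An object of class `imputation_model`.
#' @seealso [impute_dichotomous()], [impute_tscore()], [impute_missing()]
#' @export
fit_imputation_model <- function(reference) {
  if (nrow(reference) < 200)
    stop("reference cohort must have at least 200 records", call. = FALSE)
  for (cl in c("age", "sex", "bmi", FLAG_COLUMNS, "fn_tscore"))
    if (is.null(reference[[cl]]) || anyNA(reference[[cl]]))
      stop("reference cohort must be fully observed; '", cl,
           "' is absent or has missing values", call. = FALSE)
  factors <- list()
  for (f in setdiff(names(IMPUTATION_COVARIATES), "fn_tscore")) {
    covs <- IMPUTATION_COVARIATES[[f]]
    y <- reference[[f]]
    if (all(y == 0) || all(y == 1)) {
      warning("'", f, "' is constant in the reference; ",
              "falling back to an intercept-only prevalence model",
              call. = FALSE)
      p <- (sum(y) + 0.5) / (length(y) + 1)  # Haldane continuity
      factors[[f]] <- list(type = "logistic", covariates = character(0),
                           coef = c("(Intercept)" = qlogis(p)))
    } else {
      X <- .imputation_design(reference, covs, f)
      fit <- glm.fit(X, y, family = binomial())
      factors[[f]] <- list(type = "logistic", covariates = covs,
                           coef = coef_named(fit, X))
    }
  }
  Xt <- .imputation_design(reference, IMPUTATION_COVARIATES$fn_tscore,
                           "fn_tscore")
  tfit <- lm.fit(Xt, reference$fn_tscore)
  factors$fn_tscore <- list(
    type = "linear", covariates = IMPUTATION_COVARIATES$fn_tscore,
    coef = coef_named(tfit, Xt),
    residual_sd = sqrt(mean(tfit$residuals^2)))
  structure(list(factors = factors, n_reference = nrow(reference)),
            class = "imputation_model")
}

coef_named <- function(fit, X) setNames(fit$coefficients, colnames(X))

#' @export
print.imputation_model <- function(x, ...) {
  cat("<imputation_model> fitted on", x$n_reference, "reference records\n")
  for (f in names(x$factors)) {
    m <- x$factors[[f]]
    cat(sprintf("  %s (%s ~ %s)\n", f, m$type,
                if (length(m$covariates))
                  paste(m$covariates, collapse = " + ") else "1"))
    cat("    coef:", paste(sprintf("%s=%.4g", names(m$coef), m$coef),
                           collapse = ", "), "\n")
    if (!is.null(m$residual_sd))
      cat(sprintf("    residual SD: %.4g\n", m$residual_sd))
  }
  invisible(x)
}

#' @export
coef.imputation_model <- function(object, ...) {
  lapply(object$factors, `[[`, "coef")
}

#' Predicted probability or conditional mean for one imputed factor
#'
#' @param object An [imputation_model][fit_imputation_model()].
#' @param newdata Cohort `data.frame` carrying the factor's covariates.
#' @param factor Factor name (one of the model's factors).
#' @param ... Unused.
#' @return For a logistic factor, predicted probabilities in (0, 1); for
#'   `fn_tscore`, conditional means in SD units.
#' @export
predict.imputation_model <- function(object, newdata, factor, ...) {
  m <- object$factors[[factor]]
  if (is.null(m))
    stop("'", factor, "' is not part of this imputation model",
         call. = FALSE)
  X <- .imputation_design(newdata, m$covariates, factor)
  eta <- drop(X %*% m$coef)
  if (m$type == "logistic") plogis(eta) else eta
}

# One RNG stream per factor: base seed plus a stable hash of the factor
# name, so adding or reordering factors does not perturb other draws.
.factor_seed <- function(base_seed, factor) {
  h <- sum(utf8ToInt(factor) * seq_along(utf8ToInt(factor)))
  as.integer((as.numeric(base_seed) + h) %% 2147483647)
}

#' Stochastically impute a dichotomous risk factor
#'
#' For each record (in record order) the fitted logistic model gives a
#' predicted probability p; an independent uniform random number u is drawn
#' from a stream seeded by `seed` and the factor name, and the record is
#' assigned a positive value iff u <= p. The whole column is (re)assigned;
#' the result is deterministic given the seed.
#'
#' @param cohort Target cohort `data.frame` carrying the factor's
#'   covariates.
#' @param model An [imputation_model][fit_imputation_model()].
#' @param factor Name of the dichotomous factor to fill.
#' @param seed Base integer seed.
#' @return The cohort with the factor column filled (0/1).
#' @export
impute_dichotomous <- function(cohort, model, factor, seed = 1) {
  m <- model$factors[[factor]]
  if (is.null(m) || m$type != "logistic")
    stop("'", factor, "' is not a dichotomous factor of this model",
         call. = FALSE)
  p <- predict(model, cohort, factor)
  set.seed(.factor_seed(seed, factor))
  u <- runif(nrow(cohort))
  cohort[[factor]] <- as.integer(u <= p)
  cohort
}

#' Stochastically impute the femoral-neck T-score
#'
#' Predicted conditional mean from the fitted linear model plus, by
#' default, a Gaussian residual with the model's residual SD (without the
#' residual the imputed T-score distribution would be far narrower than
#' a measured one).
#'
#' @inheritParams impute_dichotomous
#' @param noise Add the Gaussian residual? (default `TRUE`).
#' @return The cohort with `fn_tscore` filled (SD units).
#' @export
impute_tscore <- function(cohort, model, seed = 1, noise = TRUE) {
  m <- model$factors$fn_tscore
  if (is.null(m)) stop("model has no fn_tscore component", call. = FALSE)
  mu <- predict(model, cohort, "fn_tscore")
  if (noise) {
    set.seed(.factor_seed(seed, "fn_tscore"))
    mu <- mu + rnorm(nrow(cohort), 0, m$residual_sd)
  }
  cohort$fn_tscore <- mu
  cohort
}

#' Impute every missing simulated variable in a cohort
#'
#' Applies [impute_dichotomous()] to each dichotomous factor column that is
#' absent or contains missing values, then [impute_tscore()] likewise, all
#' from one base seed (each factor has its own derived stream).
#'
#' @inheritParams impute_tscore
#' @return The cohort with all model factors filled.
#' @export
impute_missing <- function(cohort, model, seed = 1, noise = TRUE) {
  for (f in setdiff(names(model$factors), "fn_tscore")) {
    if (is.null(cohort[[f]]) || anyNA(cohort[[f]]))
      cohort <- impute_dichotomous(cohort, model, f, seed)
  }
  if (is.null(cohort$fn_tscore) || anyNA(cohort$fn_tscore))
    cohort <- impute_tscore(cohort, model, seed, noise)
  cohort
}

#' Compare imputed prevalences with an age-adjusted reference
#'
#' Direct age standardisation on 5-year bins, with the *target* cohort's
#' age distribution as the standard: the reference prevalence in each bin
#' is weighted by the target's share of that bin. Bins with no reference
#' records are dropped with a warning (weights renormalised).
#'
#' @param imputed Target cohort after imputation.
#' @param reference Reference cohort.
#' @param factors Factor columns to compare (default: the dichotomous
#'   factors both cohorts carry).
#' @return `data.frame` with columns `factor`, `imputed_pct`,
#'   `reference_adj_pct`, `diff_pp` (percentage points).
#' @export
prevalence_report <- function(imputed, reference,
                              factors = intersect(FLAG_COLUMNS,
                                                  intersect(names(imputed),
                                                            names(reference)))) {
  breaks <- seq(40, 105, 5)
  tbin <- cut(imputed$age, breaks, right = FALSE)
  rbin <- cut(reference$age, breaks, right = FALSE)
  w <- table(tbin) / length(tbin)
  present <- names(w)[w > 0]
  empty <- present[!present %in% names(table(rbin))[table(rbin) > 0]]
  if (length(empty)) {
    warning("reference has no records in age bin(s) ",
            paste(empty, collapse = ", "), "; bin(s) dropped",
            call. = FALSE)
    present <- setdiff(present, empty)
  }
  w <- w[present] / sum(w[present])
  out <- lapply(factors, function(f) {
    pt <- 100 * mean(imputed[[f]])
    pr_bin <- tapply(reference[[f]], rbin, mean)[present]
    pr <- sum(w * pr_bin) * 100
    data.frame(factor = f, imputed_pct = pt, reference_adj_pct = pr,
               diff_pp = pt - pr)
  })
  do.call(rbind, out)
}
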