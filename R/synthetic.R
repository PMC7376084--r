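# Structural slopes shared by the target- and reference-cohort generators.
# Logit scale for the dichotomous factors, SD units for the T-score.
# Intercepts are solved at generation time so each cohort hits its
# specified marginal prevalences exactly in expectation; the T-score
# intercept is anchored at the spec's nominal covariate means.
STRUCTURAL_SLOPES <- list(
  prior_fracture = c(age = 0.05),
  parental_hip_fracture = c(age = -0.02, prior_fracture = 0.4),
  glucocorticoids = c(age = 0.02, sex_male = -0.3, bmi = -0.02),
  rheumatoid_arthritis = c(sex_male = -0.5, bmi = -0.03,
                           prior_fracture = 0.5),
  fn_tscore = c(age = -0.035, bmi = 0.06, prior_fracture = -0.3,
                current_smoking = -0.15)
)

# Variance of the T-score linear predictor under the default covariate
# structure; the Gaussian residual is sized so the marginal T-score SD
# equals the spec value. Calibrated once against the default spec.
TSCORE_EXPLAINED_VAR <- 0.1329

#' Specification of a synthetic target cohort
#'
#' Defaults emulate a Singaporean women's cohort aged 50+: age 61.7 (SD
#' 7.8, truncated at 50), BMI 23.2 (SD 3.6, truncated at 14), factor
#' prevalences (prior fracture 6.6%, smoking 5.4%, secondary osteoporosis
#' 14.4%, alcohol 3+ units 0.058%, parental hip fracture 6.6%,
#' glucocorticoids 0.4%, rheumatoid arthritis 1.9%) and femoral-neck
#' T-score mean -1.89 (SD 0.87). Truncated-normal parent parameters are
#' solved so the *realised* mean and SD match the stated values. The
#' `blank` columns are removed from the emitted cohort (kept in the truth
#' attribute), emulating variables a survey cohort never measured.
#'
#' @param n Number of women.
#' @param age_mean,age_sd,age_min Age distribution (years).
#' @param bmi_mean,bmi_sd,bmi_min BMI distribution (kg/m2).
#' @param prevalence Named vector of factor prevalences in \[0, 1\].
#' @param tscore_mean,tscore_sd Marginal T-score distribution (SD units).
#' @param blank Columns to blank in the emitted cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 29323,
                        age_mean = 61.7, age_sd = 7.8, age_min = 50,
                        bmi_mean = 23.2, bmi_sd = 3.6, bmi_min = 14,
                        prevalence = c(prior_fracture = 0.066,
                                       current_smoking = 0.054,
                                       secondary_osteoporosis = 0.144,
                                       alcohol_3plus = 0.00058,
                                       parental_hip_fracture = 0.066,
                                       glucocorticoids = 0.004,
                                       rheumatoid_arthritis = 0.019),
                        tscore_mean = -1.89, tscore_sd = 0.87,
                        blank = c("parental_hip_fracture",
                                  "glucocorticoids",
                                  "rheumatoid_arthritis", "fn_tscore")) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (age_sd <= 0 || bmi_sd <= 0 || tscore_sd <= 0)
    stop("all SDs must be positive", call. = FALSE)
  if (any(prevalence < 0 | prevalence > 1))
    stop("prevalences must lie in [0, 1]", call. = FALSE)
  miss <- setdiff(FLAG_COLUMNS, names(prevalence))
  if (length(miss))
    stop("prevalence missing for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  structure(list(n = n, age_mean = age_mean, age_sd = age_sd,
                 age_min = age_min, bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 bmi_min = bmi_min, prevalence = prevalence,
                 tscore_mean = tscore_mean, tscore_sd = tscore_sd,
                 blank = blank),
            class = "cohort_spec")
}

# Parent (mu, sigma) of a lower-truncated normal whose truncated mean/SD
# equal the targets.
.trunc_normal_params <- function(mean, sd, lower) {
  moments <- function(mu, sigma) {
    a <- (lower - mu) / sigma
    lam <- stats::dnorm(a) / (1 - stats::pnorm(a))
    m <- mu + sigma * lam
    v <- sigma^2 * (1 + a * lam - lam^2)
    c(m, sqrt(v))
  }
  obj <- function(par) {
    ms <- moments(par[1], exp(par[2]))
    (ms[1] - mean)^2 + (ms[2] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj,
                      control = list(reltol = 1e-14, maxit = 2000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

.rtruncnorm <- function(n, mu, sigma, lower) {
  plo <- stats::pnorm(lower, mu, sigma)
  stats::qnorm(runif(n, plo, 1), mu, sigma)
}

# Solve the intercept of logit(p) = c0 + eta so that mean(p) over the
# realised covariates equals the target prevalence.
.solve_intercept <- function(eta, target) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  uniroot(function(c0) mean(plogis(c0 + eta)) - target,
          interval = c(-40, 20), tol = 1e-12)$root
}

# Shared structural core: given drawn age/sex/bmi, fill in the factor and
# T-score columns from the structural equations. Returns the cohort plus
# the generating coefficients (solved intercepts included).
.fill_structural <- function(df, spec, seed) {
  slopes <- STRUCTURAL_SLOPES
  gen <- list()
  sex_male <- as.numeric(df$sex == "male")
  draw <- function(name, p) {
    set.seed(.factor_seed(seed, name))
    as.integer(runif(nrow(df)) <= p)
  }
  # prior fracture: logistic in age
  eta <- slopes$prior_fracture[["age"]] * df$age
  c0 <- .solve_intercept(eta, spec$prevalence[["prior_fracture"]])
  p <- plogis(c0 + eta)
  df$prior_fracture <- draw("prior_fracture", p)
  gen$prior_fracture <- c("(Intercept)" = c0, slopes$prior_fracture)
  # smoking, secondary osteoporosis, alcohol: Bernoulli at prevalence
  for (f in c("current_smoking", "secondary_osteoporosis", "alcohol_3plus")) {
    df[[f]] <- draw(f, spec$prevalence[[f]])
    gen[[f]] <- c("(Intercept)" = qlogis(min(max(
      spec$prevalence[[f]], 1e-12), 1 - 1e-12)))
  }
  covs <- list(age = df$age, bmi = df$bmi, sex_male = sex_male)
  for (f in c("parental_hip_fracture", "glucocorticoids",
              "rheumatoid_arthritis")) {
    sl <- slopes[[f]]
    eta <- rep(0, nrow(df))
    for (cv in names(sl))
      eta <- eta + sl[[cv]] * (covs[[cv]] %||% df[[cv]])
    c0 <- .solve_intercept(eta, spec$prevalence[[f]])
    df[[f]] <- draw(f, plogis(c0 + eta))
    gen[[f]] <- c("(Intercept)" = c0, sl)
  }
  # T-score: linear in age/BMI/prior fracture/smoking + Gaussian residual.
  sl <- slopes$fn_tscore
  c0 <- spec$tscore_mean -
    (sl[["age"]] * spec$age_mean + sl[["bmi"]] * spec$bmi_mean +
       sl[["prior_fracture"]] * spec$prevalence[["prior_fracture"]] +
       sl[["current_smoking"]] * spec$prevalence[["current_smoking"]])
  mu <- c0 + sl[["age"]] * df$age + sl[["bmi"]] * df$bmi +
    sl[["prior_fracture"]] * df$prior_fracture +
    sl[["current_smoking"]] * df$current_smoking
  resid_sd <- sqrt(max(spec$tscore_sd^2 - TSCORE_EXPLAINED_VAR, 1e-4))
  set.seed(.factor_seed(seed, "fn_tscore"))
  df$fn_tscore <- mu + rnorm(nrow(df), 0, resid_sd)
  gen$fn_tscore <- c("(Intercept)" = c0, sl)
  attr(df, "generator") <- list(coefficients = gen, resid_sd = resid_sd)
  df
}

#' Generate a synthetic target cohort
#'
#' Draws a seeded, reproducible cohort of women from a [cohort_spec()]:
#' truncated-normal age and BMI, prior fracture mildly age-dependent
#' (logistic in age), the remaining factors Bernoulli at their prevalences
#' (conditionally independent given age, sex and BMI), and a femoral-neck
#' T-score linear in age, BMI, prior fracture and smoking plus Gaussian
#' noise. The columns in `spec$blank` are then blanked (`NA`), emulating a
#' survey cohort that never measured them; the complete data are kept in
#' the `truth` attribute, and the generating coefficients in the
#' `generator` attribute of the truth.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; every column has its own derived stream, so
#'   the draws for one variable do not perturb another's.
#' @return Cohort `data.frame` in the canonical dialect, with attributes
#'   `truth` (the unblanked cohort) and `generator`.
#' @export
generate_target_cohort <- function(spec = cohort_spec(), seed = 1) {
  n <- spec$n
  ap <- .trunc_normal_params(spec$age_mean, spec$age_sd, spec$age_min)
  bp <- .trunc_normal_params(spec$bmi_mean, spec$bmi_sd, spec$bmi_min)
  set.seed(.factor_seed(seed, "age"))
  age <- .rtruncnorm(n, ap$mu, ap$sigma, spec$age_min)
  set.seed(.factor_seed(seed, "bmi"))
  bmi <- .rtruncnorm(n, bp$mu, bp$sigma, spec$bmi_min)
  df <- data.frame(id = seq_len(n), age = age, sex = "female", bmi = bmi,
                   stringsAsFactors = FALSE)
  df <- .fill_structural(df, spec, seed)
  df$followup_years <- NA_real_
  df$hip_fracture_observed <- NA_integer_
  truth <- df[COHORT_COLUMNS]
  attr(truth, "generator") <- attr(df, "generator")
  out <- truth
  for (cl in spec$blank) out[[cl]] <- out[[cl]][NA]
  attr(out, "truth") <- truth
  attr(out, "generator") <- attr(df, "generator")
  out
}

#' Generate a fully observed reference cohort (ages 65+)
#'
#' An age-stratified reference in the mould of an elderly community cohort:
#' one third of records in each of the strata 65--69, 70--74 and 75+
#' (uniform ages within strata, 75+ spread to 90), both sexes, with every
#' risk factor and the femoral-neck T-score observed. Uses the same
#' structural slopes as [generate_target_cohort()], so fitting the
#' imputation regressions on this cohort and imputing a target cohort is a
#' well-posed recovery exercise.
#'
#' @param n Number of records (>= 30; smaller references make the
#'   regressions unstable).
#' @param seed Integer seed.
#' @param spec A [cohort_spec()] supplying the BMI distribution, the
#'   prevalence anchors and the T-score anchors.
#' @param sex_female_prop Proportion of women (default 0.5, a combined
#'   men-and-women reference).
#' @return Fully observed cohort `data.frame` with a `generator`
#'   attribute.
#' @export
generate_reference_cohort <- function(n, seed = 1, spec = cohort_spec(),
                                      sex_female_prop = 0.5) {
  if (n < 30)
    stop("reference cohort needs at least 30 records", call. = FALSE)
  sizes <- diff(round(seq(0, n, length.out = 4)))
  set.seed(.factor_seed(seed, "ref_age"))
  age <- c(runif(sizes[1], 65, 70), runif(sizes[2], 70, 75),
           runif(sizes[3], 75, 90))
  set.seed(.factor_seed(seed, "ref_sex"))
  sex <- ifelse(runif(n) <= sex_female_prop, "female", "male")
  bp <- .trunc_normal_params(spec$bmi_mean, spec$bmi_sd, spec$bmi_min)
  set.seed(.factor_seed(seed, "ref_bmi"))
  bmi <- .rtruncnorm(n, bp$mu, bp$sigma, spec$bmi_min)
  df <- data.frame(id = seq_len(n), age = age, sex = sex, bmi = bmi,
                   stringsAsFactors = FALSE)
  df <- .fill_structural(df, spec, seed)
  df$followup_years <- NA_real_
  df$hip_fracture_observed <- NA_integer_
  gen <- attr(df, "generator")
  df <- df[COHORT_COLUMNS]
  attr(df, "generator") <- gen
  df
}

#' Follow-up specification
#'
#' Follow-up durations are drawn from Uniform(2*mean - max, max), which
#' has the stated mean and maximum (defaults: mean 9.1 y, max 11.5 y, so
#' Uniform(6.7, 11.5)). The drawn duration is the administrative censoring
#' time; person-years are counted to it.
#'
#' @param mean_years,max_years Mean and maximum follow-up (years).
#' @return An object of class `followup_spec`.
#' @export
followup_spec <- function(mean_years = 9.1, max_years = 11.5) {
  lo <- 2 * mean_years - max_years
  if (mean_years <= 0 || mean_years > max_years || lo < 0)
    stop("need 0 < mean <= max and 2*mean - max >= 0", call. = FALSE)
  structure(list(mean_years = mean_years, max_years = max_years, lo = lo),
            class = "followup_spec")
}

#' Simulate follow-up outcomes under a hazard model
#'
#' For each woman, draws an administrative censoring time from the
#' follow-up distribution, a first-hip-fracture time by inverse transform
#' on her individual cumulative hip hazard, and a death time likewise from
#' the shared death hazard. A hip fracture is observed iff it precedes
#' both death and censoring. Requires complete risk profiles (use the
#' truth attribute of a generated cohort, not the blanked one).
#'
#' @param cohort Fully observed cohort `data.frame`.
#' @param model A [hazard_model()].
#' @param spec A [followup_spec()].
#' @param seed Integer seed (independent streams for censoring, fracture
#'   and death).
#' @param use_bmd Scale the fracture hazard by the BMD term? Default
#'   `FALSE`, matching the without-BMD scoring route so that simulated
#'   events are self-consistent with [expected_fracture_count()].
#' @param step Integration step (years).
#' @return The cohort with `followup_years` and `hip_fracture_observed`
#'   filled.
#' @export
simulate_followup <- function(cohort, model, spec = followup_spec(),
                              seed = 1, use_bmd = FALSE, step = 0.05) {
  df <- .as_profile_frame(cohort)
  n <- nrow(df)
  set.seed(.factor_seed(seed, "followup"))
  fu <- runif(n, spec$lo, spec$max_years)
  mult <- .risk_multiplier(df, model, use_bmd = use_bmd)
  horizon <- spec$max_years
  sample_times <- function(outcome, m, stream) {
    g <- .cumhaz_nodes(df$age, m, model, outcome, horizon, step)
    set.seed(.factor_seed(seed, stream))
    E <- rexp(n)
    L <- length(g$tgrid)
    k <- rowSums(g$H < E)           # last node with H < E
    t <- rep(Inf, n)
    hit <- k < L
    if (any(hit)) {
      idx <- cbind(which(hit), k[hit])
      h <- g$hstep[idx]
      t[hit] <- g$tgrid[k[hit]] + (E[hit] - g$H[idx]) / h
    }
    t
  }
  t_frac <- sample_times("hip", mult, "hip_event")
  t_death <- sample_times("death", 1, "death")
  cohort$followup_years <- fu
  cohort$hip_fracture_observed <- as.integer(t_frac < pmin(t_death, fu))
  cohort
}
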