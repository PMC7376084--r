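# Flat (age-constant) hazard model: closed forms are exact for it.
const_hazard_model <- function(h_mof = 0.02, h_hip = 0.01, h_death = 0.05,
                               rr_prior = 1.8, bmd_grad = 0.47,
                               log_rr_extra = list()) {
  flat <- function(h) list(age = c(40, 100), hazard = c(h, h))
  log_rr <- modifyList(
    list(prior_fracture = log(rr_prior), parental_hip_fracture = log(1.5),
         current_smoking = log(1.25), glucocorticoids = log(1.7),
         rheumatoid_arthritis = log(1.4), secondary_osteoporosis = log(1.3),
         alcohol_3plus = log(1.4), bmi_per_unit = 0),
    log_rr_extra)
  hazard_model("test", mof = flat(h_mof), hip = flat(h_hip),
               death = flat(h_death), log_rr = log_rr,
               bmi_reference = 25, bmd_log_rr_per_sd = bmd_grad,
               tscore_reference = list(mean_age60 = -1.84,
                                       slope_per_year = -0.03, sd = 0.87))
}

# Exact constant-hazard competing-risk 10-year probability (fraction).
competing_closed_form <- function(hf, hd, horizon = 10) {
  if (hf + hd == 0) return(0)
  hf / (hf + hd) * (1 - exp(-horizon * (hf + hd)))
}

# Cohort data.frame from risk_profile-style arguments (one row per call).
cohort_row <- function(id, age, bmi = 25, fn_tscore = NA_real_,
                       followup_years = NA_real_,
                       hip_fracture_observed = NA_integer_, sex = "female",
                       ...) {
  flags <- setNames(rep(0L, length(fraxpath:::FLAG_COLUMNS)),
                    fraxpath:::FLAG_COLUMNS)
  dots <- list(...)
  flags[names(dots)] <- unlist(dots)
  cbind(data.frame(id = id, age = age, sex = sex, bmi = bmi,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(flags)),
        data.frame(fn_tscore = fn_tscore, followup_years = followup_years,
                   hip_fracture_observed = hip_fracture_observed))
}

# Monte-Carlo discrete-event lifetime oracle: simulates n_sim lifetimes on
# 0.01-year steps with per-step event probabilities hazard*dt, fracture
# checked before death within a step. Independent of the package's
# continuous-time integrator.
mc_lifetime_oracle <- function(profile, model, outcome = "hip",
                               n_sim = 1e6, dt = 0.01, horizon = 10,
                               seed = 1) {
  steps <- round(horizon / dt)
  ages <- profile$age + (seq_len(steps) - 1) * dt
  hf <- individual_hazard(profile, model, outcome,
                          age_at_time = pmin(ages, 100))
  hd <- baseline_hazard(model, "death", pmin(ages, 100))
  surv_f <- cumprod(1 - hf * dt)
  surv_d <- cumprod(1 - hd * dt)
  set.seed(seed)
  u_f <- runif(n_sim)
  u_d <- runif(n_sim)
  # first step where the cumulative event probability passes u (steps+1 =>
  # no event within the horizon)
  k_f <- findInterval(u_f, 1 - c(surv_f, 0), left.open = TRUE) + 1
  k_d <- findInterval(u_d, 1 - c(surv_d, 0), left.open = TRUE) + 1
  p_hat <- mean(k_f <= steps & k_f <= k_d)
  list(p_hat = p_hat, se = sqrt(p_hat * (1 - p_hat) / n_sim))
}

random_test_profile <- function(seed) {
  set.seed(seed)
  risk_profile(age = runif(1, 50, 85), bmi = runif(1, 18, 32),
               prior_fracture = rbinom(1, 1, 0.3),
               parental_hip_fracture = rbinom(1, 1, 0.2),
               current_smoking = rbinom(1, 1, 0.2),
               glucocorticoids = rbinom(1, 1, 0.1),
               rheumatoid_arthritis = rbinom(1, 1, 0.1),
               secondary_osteoporosis = rbinom(1, 1, 0.2),
               alcohol_3plus = rbinom(1, 1, 0.05),
               fn_tscore = if (runif(1) < 0.5) runif(1, -3.5, 0)
                           else NA_real_)
}
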