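#' Individual annual hazard under a hazard model
#'
#' Baseline hazard at a given age scaled by the profile's multiplicative
#' risk: `exp(sum(flag * log_rr) + bmi_per_unit * (bmi - bmi_reference) +
#' bmd_log_rr_per_sd * (tscore_mean(age) - fn_tscore))`. The BMD term is
#' centred on the population mean T-score at the profile's *baseline* age,
#' so it is a constant multiplier over a projection horizon; it is omitted
#' when `fn_tscore` is absent.
#'
#' @param profile A [risk_profile()].
#' @param model A [hazard_model()].
#' @param outcome `"mof"` or `"hip"`.
#' @param age_at_time Age (years) at which to evaluate the hazard; must lie
#'   on the model grid \[40, 100\].
#' @return Annual hazard (per person-year), strictly positive when the
#'   baseline is.
#' @export
individual_hazard <- function(profile, model, outcome = c("mof", "hip"),
                              age_at_time = profile$age) {
  outcome <- match.arg(outcome)
  df <- .as_profile_frame(profile)
  mult <- .risk_multiplier(df, model, use_bmd = !is.na(df$fn_tscore))
  baseline_hazard(model, outcome, age_at_time) * mult
}

# Multiplicative risk factor for each row of a profile frame.
# use_bmd may be a scalar or per-row logical.
.risk_multiplier <- function(df, model, use_bmd = FALSE) {
  lr <- model$log_rr
  known <- c(FLAG_COLUMNS, "bmi_per_unit")
  unknown <- setdiff(names(lr), known)
  if (length(unknown))
    stop("unknown factor name(s) in model log_rr: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  eta <- rep(0, nrow(df))
  for (f in FLAG_COLUMNS) {
    v <- df[[f]]
    if (anyNA(v))
      stop("risk factor '", f, "' is missing for row(s) ",
           paste(utils::head(which(is.na(v)), 5), collapse = ", "),
           "; impute before computing probabilities", call. = FALSE)
    if (any(!v %in% c(0, 1)))
      stop("risk factor '", f, "' must be 0/1", call. = FALSE)
    eta <- eta + v * (lr[[f]] %||% 0)
  }
  eta <- eta + (lr$bmi_per_unit %||% 0) * (df$bmi - model$bmi_reference)
  use_bmd <- rep_len(use_bmd, nrow(df))
  if (any(use_bmd)) {
    t <- df$fn_tscore
    if (anyNA(t[use_bmd]))
      stop("fn_tscore is missing for row(s) ",
           paste(utils::head(which(use_bmd & is.na(t)), 5), collapse = ", "),
           call. = FALSE)
    centred <- tscore_mean_at(model, df$age) - t
    eta <- eta + ifelse(use_bmd, model$bmd_log_rr_per_sd * centred, 0)
  }
  exp(eta)
}

# Core competing-risk integrator. For each person i (baseline age age0[i],
# constant fracture-hazard multiplier mult[i]) computes
#   CIF_i(tau_i) = int_0^tau_i h_f(t) exp(-int_0^t [h_f + h_d]) dt
# on a fixed step grid by the piecewise-exponential (actuarial) scheme:
# hazards are averaged over each step and treated as constant within it,
# giving the exact conditional probability per step. Exact for constant
# hazards; O(step^2) for smooth ones; fully deterministic.
.cuminc <- function(age0, mult, model, outcome, horizon, step = 0.05) {
  n <- length(age0)
  horizon <- rep_len(horizon, n)
  if (any(horizon < 0)) stop("negative projection horizon", call. = FALSE)
  tmax <- max(horizon, 0)
  L <- ceiling(tmax / step - 1e-9)
  tgrid <- c(seq(0, by = step, length.out = L), tmax)
  tgrid[L + 1] <- max(tgrid[L + 1], tgrid[L])  # guard rounding
  ages <- outer(age0, tgrid, `+`)
  BF <- matrix(baseline_hazard(model, outcome, ages, extend = TRUE), n)
  BD <- matrix(baseline_hazard(model, "death", ages, extend = TRUE), n)
  if (any(!is.finite(BF)) || any(!is.finite(BD))) {
    bad <- which(!is.finite(BF) | !is.finite(BD), arr.ind = TRUE)[1, ]
    stop("non-finite hazard at age ", round(ages[bad[1], bad[2]], 2),
         call. = FALSE)
  }
  S <- rep(1, n)
  cif <- rep(0, n)
  for (k in seq_len(ncol(ages) - 1)) {
    dt_full <- tgrid[k + 1] - tgrid[k]
    if (dt_full <= 0) next
    hf <- mult * (BF[, k] + BF[, k + 1]) / 2
    hd <- (BD[, k] + BD[, k + 1]) / 2
    htot <- hf + hd
    # per-person exposure within this step, truncated at the horizon
    dt <- pmin(pmax(horizon - tgrid[k], 0), dt_full)
    r <- ifelse(htot > 0, hf / htot, 0)
    cif <- cif + S * r * (1 - exp(-htot * dt))
    S <- S * exp(-htot * dt_full)
  }
  cif
}

# Cumulative hazard of a single cause at the grid nodes (n x length(tgrid)),
# step-averaged, for inverse-transform event sampling. Returns list(tgrid, H).
.cumhaz_nodes <- function(age0, mult, model, outcome, horizon, step = 0.05) {
  n <- length(age0)
  L <- ceiling(horizon / step - 1e-9) + 1
  tgrid <- seq(0, by = step, length.out = L)
  tgrid[L] <- horizon
  ages <- outer(age0, tgrid, `+`)
  B <- matrix(baseline_hazard(model, outcome, ages, extend = TRUE), n)
  hstep <- mult * (B[, -L, drop = FALSE] + B[, -1, drop = FALSE]) / 2
  dts <- diff(tgrid)
  H <- cbind(0, t(apply(sweep(hstep, 2, dts, `*`), 1, cumsum)))
  list(tgrid = tgrid, H = H, hstep = hstep)
}

#' 10-year fracture probabilities for one profile
#'
#' Computes the 10-year probabilities of a first major osteoporotic
#' fracture and of a first hip fracture, with death as a competing risk:
#' the cumulative incidence
#' \deqn{P = \int_0^{10} h_f(t)\,e^{-\int_0^t [h_f(u)+h_d(u)]\,du}\,dt,}
#' evaluated by a deterministic fixed-step piecewise-exponential scheme.
#' Recomputation with identical inputs is bit-identical.
#'
#' @inheritParams individual_hazard
#' @param horizon Projection horizon in years (default 10).
#' @param step Integration step in years (default 0.05).
#' @return A `probability_pair`: list with `mof_pct`, `hip_pct` (percent,
#'   in \[0, 100\]) and `with_bmd` (whether the T-score entered the
#'   calculation).
#' @examples
#' m <- default_hazard_models()$chinese
#' ten_year_probability(risk_profile(age = 65, prior_fracture = 1), m)
#' @export
ten_year_probability <- function(profile, model, horizon = 10, step = 0.05) {
  df <- .as_profile_frame(profile)
  stopifnot(nrow(df) == 1L)
  with_bmd <- !is.na(df$fn_tscore)
  p <- cohort_probabilities(df, model, with_bmd = with_bmd,
                            horizon = horizon, step = step)
  structure(list(mof_pct = p$mof_pct, hip_pct = p$hip_pct,
                 with_bmd = with_bmd),
            class = "probability_pair")
}

#' @export
print.probability_pair <- function(x, ...) {
  cat(sprintf("10-year probability (%s BMD): MOF %.2f%%, hip %.2f%%\n",
              if (x$with_bmd) "with" else "without", x$mof_pct, x$hip_pct))
  invisible(x)
}

#' Fracture probabilities for a whole cohort
#'
#' Vectorised over the rows of a cohort table in the canonical dialect
#' (see [read_cohort()]).
#'
#' @param cohort Cohort `data.frame` with `age`, `bmi`, the seven flag
#'   columns and (if `with_bmd`) `fn_tscore`.
#' @param model A [hazard_model()].
#' @param with_bmd Logical: include the femoral-neck T-score term?
#' @param horizon,step As in [ten_year_probability()].
#' @return `data.frame` with columns `mof_pct` and `hip_pct`.
#' @export
cohort_probabilities <- function(cohort, model, with_bmd = FALSE,
                                 horizon = 10, step = 0.05) {
  df <- .as_profile_frame(cohort)
  if (nrow(df) == 0)
    return(data.frame(mof_pct = numeric(0), hip_pct = numeric(0)))
  mult <- .risk_multiplier(df, model, use_bmd = with_bmd)
  data.frame(
    mof_pct = 100 * .cuminc(df$age, mult, model, "mof", horizon, step),
    hip_pct = 100 * .cuminc(df$age, mult, model, "hip", horizon, step))
}

#' Expected number of first fractures over individual follow-up
#'
#' Sums each person's cumulative incidence truncated at her own follow-up
#' window, i.e. the number of first fractures the model predicts for the
#' cohort as observed.
#'
#' @param cohort Cohort `data.frame` including `followup_years` (> 0).
#' @param model A [hazard_model()].
#' @param outcome `"hip"` or `"mof"`.
#' @param step Integration step (years).
#' @return Expected count, between 0 and `nrow(cohort)`.
#' @export
expected_fracture_count <- function(cohort, model, outcome = c("hip", "mof"),
                                    step = 0.05) {
  outcome <- match.arg(outcome)
  if (nrow(cohort) == 0) {
    warning("empty cohort: expected count is 0", call. = FALSE)
    return(0)
  }
  df <- .as_profile_frame(cohort)
  fu <- cohort$followup_years
  if (is.null(fu) || anyNA(fu) || any(fu <= 0))
    stop("followup_years must be present and > 0 for every record",
         call. = FALSE)
  mult <- .risk_multiplier(df, model, use_bmd = FALSE)
  sum(.cuminc(df$age, mult, model, outcome, fu, step))
}
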