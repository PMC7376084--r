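#' Triage a cohort through the BMD-referral management algorithm
#'
#' Implements the case-finding algorithm: a woman with a prior fragility
#' fracture is eligible for treatment outright (no probability computed).
#' Otherwise her 10-year MOF probability without BMD is compared with the
#' age-specific assessment thresholds: strictly below the lower assessment
#' threshold she is discharged; strictly above the upper assessment
#' threshold she is treated without a BMD test; in between she is referred
#' for BMD, her probability is recomputed with the femoral-neck T-score,
#' and she is treated iff the recomputed probability is greater than or
#' equal to the intervention threshold. Both boundary values of the band
#' fall into the BMD referral; all comparisons use unrounded values.
#'
#' If a referred woman's T-score is missing it is imputed on the spot
#' (flagged in the record) when an imputation model is supplied; with
#' `require_bmd = TRUE` this is an error instead.
#'
#' If the cohort carries columns `mof_pct_no_bmd` (and, for referred
#' women, `mof_pct_with_bmd`), those supplied probabilities are used
#' verbatim and no engine is needed — e.g. to audit a published threshold
#' table against externally computed probabilities.
#'
#' @param cohort Cohort `data.frame` in the canonical dialect.
#' @param curve A [threshold_curve][build_threshold_curve()].
#' @param model A [hazard_model()] (may be `NULL` when probabilities are
#'   supplied in the cohort).
#' @param imputation Optional [imputation_model][fit_imputation_model()]
#'   for on-the-spot T-score imputation.
#' @param seed Seed for on-the-spot imputation.
#' @param require_bmd Error instead of imputing a missing T-score.
#' @param step Integration step for the engine (years).
#' @return `data.frame` of disposition records: `id`, `category` (one of
#'   `treat_prior_fracture`, `treat_above_uat`, `bmd_then_treat`,
#'   `bmd_then_no_treat`, `no_treat_below_lat`), `mof_pct_no_bmd`,
#'   `mof_pct_with_bmd` (`NA` outside the BMD branch), the thresholds at
#'   her age, and `tscore_imputed`.
#' @export
triage <- function(cohort, curve, model = NULL, imputation = NULL,
                   seed = 1, require_bmd = FALSE, step = 0.05) {
  if (anyDuplicated(cohort$id))
    stop("duplicate ids in cohort", call. = FALSE)
  n <- nrow(cohort)
  thr <- threshold_at(curve, cohort$age)
  supplied <- !is.null(cohort$mof_pct_no_bmd)
  category <- rep(NA_character_, n)
  category[cohort$prior_fracture == 1] <- "treat_prior_fracture"
  open <- is.na(category)
  p0 <- rep(NA_real_, n)
  if (supplied) {
    p0[open] <- cohort$mof_pct_no_bmd[open]
  } else if (any(open)) {
    if (is.null(model))
      stop("either a hazard model or supplied probability columns ",
           "are required", call. = FALSE)
    p0[open] <- cohort_probabilities(cohort[open, , drop = FALSE], model,
                                     with_bmd = FALSE, step = step)$mof_pct
  }
  category[open & p0 < thr$lat_pct] <- "no_treat_below_lat"
  category[open & p0 > thr$uat_pct] <- "treat_above_uat"
  band <- is.na(category)
  p1 <- rep(NA_real_, n)
  tscore_imputed <- rep(FALSE, n)
  if (any(band)) {
    if (supplied) {
      p1[band] <- cohort$mof_pct_with_bmd[band]
      if (anyNA(p1[band]))
        stop("mof_pct_with_bmd must be supplied for every woman in the ",
             "BMD referral band", call. = FALSE)
    } else {
      missing_t <- band & is.na(cohort$fn_tscore)
      if (any(missing_t)) {
        if (require_bmd || is.null(imputation))
          stop(sum(missing_t), " woman/women in the BMD referral band ",
               "have no femoral-neck T-score and imputation is disabled",
               call. = FALSE)
        filled <- impute_tscore(cohort[missing_t, , drop = FALSE],
                                imputation, seed)
        cohort$fn_tscore[missing_t] <- filled$fn_tscore
        tscore_imputed[missing_t] <- TRUE
      }
      p1[band] <- cohort_probabilities(cohort[band, , drop = FALSE], model,
                                       with_bmd = TRUE, step = step)$mof_pct
    }
    category[band & p1 >= thr$it_pct] <- "bmd_then_treat"
    category[band & p1 < thr$it_pct] <- "bmd_then_no_treat"
  }
  data.frame(id = cohort$id, category = category,
             mof_pct_no_bmd = ifelse(category == "treat_prior_fracture",
                                     NA_real_, p0),
             mof_pct_with_bmd = p1,
             it_pct = thr$it_pct, lat_pct = thr$lat_pct,
             uat_pct = thr$uat_pct,
             tscore_imputed = tscore_imputed,
             stringsAsFactors = FALSE)
}

#' Disposition audit of a triaged cohort
#'
#' Summarises the triage records into the overlapping guidance-style rows:
#' the entire cohort; women treated on a prior fragility fracture; women
#' otherwise eligible for treatment (high probability without BMD, or
#' above the intervention threshold after a BMD test); women sent for BMD
#' tests (whether or not subsequently treated); and women not treated
#' (below the lower threshold, or below the intervention threshold after
#' BMD). The five atomic categories are also reported. Each row carries
#' the count, percent of cohort, mean femoral-neck T-score and mean
#' MOF/hip probabilities without and with BMD.
#'
#' @param records Triage records from [triage()].
#' @param cohort The triaged cohort (T-scores as used at triage time are
#'   needed for the with-BMD means; impute first if absent).
#' @param model A [hazard_model()] for the probability means, or `NULL`
#'   to skip them.
#' @param step Integration step (years).
#' @return `data.frame` of class `disposition_summary`.
#' @export
disposition_summary <- function(records, cohort, model = NULL,
                                step = 0.05) {
  if (anyDuplicated(records$id)) stop("duplicate ids", call. = FALSE)
  if (!setequal(records$id, cohort$id))
    stop("records and cohort ids do not match", call. = FALSE)
  cohort <- cohort[match(records$id, cohort$id), ]
  n <- nrow(records)
  have_probs <- !is.null(model) && !anyNA(cohort$fn_tscore)
  if (have_probs) {
    p_no <- cohort_probabilities(cohort, model, with_bmd = FALSE,
                                 step = step)
    p_with <- cohort_probabilities(cohort, model, with_bmd = TRUE,
                                   step = step)
  }
  groups <- c(
    list(entire_cohort = rep(TRUE, n)),
    setNames(lapply(DISPOSITION_CATEGORIES,
                    function(cat) records$category == cat),
             DISPOSITION_CATEGORIES),
    list(
      otherwise_eligible = records$category %in%
        c("treat_above_uat", "bmd_then_treat"),
      bmd_tests = records$category %in%
        c("bmd_then_treat", "bmd_then_no_treat"),
      no_treatment = records$category %in%
        c("no_treat_below_lat", "bmd_then_no_treat")))
  rows <- lapply(names(groups), function(g) {
    sel <- groups[[g]]
    data.frame(
      group = g, n = sum(sel), pct = 100 * sum(sel) / n,
      mean_fn_tscore = if (!anyNA(cohort$fn_tscore) && any(sel))
        mean(cohort$fn_tscore[sel]) else NA_real_,
      mean_mof_no_bmd = if (have_probs && any(sel))
        mean(p_no$mof_pct[sel]) else NA_real_,
      mean_hip_no_bmd = if (have_probs && any(sel))
        mean(p_no$hip_pct[sel]) else NA_real_,
      mean_mof_with_bmd = if (have_probs && any(sel))
        mean(p_with$mof_pct[sel]) else NA_real_,
      mean_hip_with_bmd = if (have_probs && any(sel))
        mean(p_with$hip_pct[sel]) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("disposition_summary", "data.frame")
  out
}

#' @export
print.disposition_summary <- function(x, ...) {
  cat("Disposition of the cohort\n")
  df <- as.data.frame(x)
  df[-(1:2)] <- lapply(df[-(1:2)], function(v) round(v, 2))
  print(df, row.names = FALSE)
  invisible(x)
}
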