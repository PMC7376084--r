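#' Calibration of expected versus observed hip fractures
#'
#' Bins women by their baseline 10-year hip-fracture probability (percent,
#' computed without BMD) into left-closed, right-open intervals
#' `[k, k + width)` — a probability exactly on an edge falls in the higher
#' bin. Per bin, the expected count is the sum of individual cumulative
#' incidences truncated at each woman's follow-up, and the observed count
#' is the number of recorded first hip fractures; cumulative columns run
#' from the lowest bin upward. The expected total equals
#' [expected_fracture_count()].
#'
#' @param cohort Cohort `data.frame` with complete risk factors,
#'   `followup_years` (> 0) and `hip_fracture_observed` (0/1).
#' @param model A [hazard_model()].
#' @param bin_width Bin width in probability percentage points.
#' @param step Integration step (years).
#' @return `data.frame` with `bin_lo`, `bin_hi`, `n`, `expected`,
#'   `observed`, `cum_expected`, `cum_observed`.
#' @export
# Left-closed, right-open bin index: a probability exactly on an edge
# belongs to the higher bin.
.prob_bin <- function(p_pct, bin_width) floor(p_pct / bin_width)

calibration_table <- function(cohort, model, bin_width = 1, step = 0.05) {
  fu <- cohort$followup_years
  if (is.null(fu) || is.null(cohort$hip_fracture_observed))
    stop("cohort needs followup_years and hip_fracture_observed",
         call. = FALSE)
  if (anyNA(fu) || any(fu < 0))
    stop("negative or missing follow-up", call. = FALSE)
  df <- .as_profile_frame(cohort)
  mult <- .risk_multiplier(df, model, use_bmd = FALSE)
  p10 <- 100 * .cuminc(df$age, mult, model, "hip", 10, step)
  exp_i <- .cuminc(df$age, mult, model, "hip", fu, step)
  bin <- .prob_bin(p10, bin_width)
  bins <- seq(0, max(bin))
  agg <- function(v) vapply(bins, function(b) sum(v[bin == b]), numeric(1))
  out <- data.frame(bin_lo = bins * bin_width,
                    bin_hi = (bins + 1) * bin_width,
                    n = agg(rep(1, nrow(df))),
                    expected = agg(exp_i),
                    observed = agg(cohort$hip_fracture_observed))
  out$cum_expected <- cumsum(out$expected)
  out$cum_observed <- cumsum(out$observed)
  out
}
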