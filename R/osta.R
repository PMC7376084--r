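#' OSTA index
#'
#' Osteoporosis Self-Assessment Tool for Asians:
#' `0.2 * (weight_kg - age_years)`.
#'
#' @param weight_kg Body weight in kg.
#' @param age_years Age in years.
#' @return Numeric index (dimensionless).
#' @examples
#' osta_index(45, 75)  # -6
#' @export
osta_index <- function(weight_kg, age_years) 0.2 * (weight_kg - age_years)

#' Screening performance of OSTA against femoral-neck BMD
#'
#' Classifies each woman as screen-positive when her OSTA index falls
#' below the cutoff (default `-1`, the conventional low-risk boundary;
#' configurable) and as condition-positive when her femoral-neck T-score
#' is `<= -2.5` (densitometric osteoporosis), then reports the 2x2-table
#' sensitivity and specificity. Used as an external check that imputed
#' T-scores carry a realistic relation to body size and age.
#'
#' If the cohort has no `weight` column, weight is reconstructed from BMI
#' via a configured height distribution (`weight = bmi * height^2`,
#' `height ~ Normal(height_mean, height_sd)`, seeded) and a message is
#' logged.
#'
#' @param cohort Cohort `data.frame` with `age`, `fn_tscore`, and `weight`
#'   (kg) or `bmi`.
#' @param cutoff Screen-positive rule: index strictly below this value.
#' @param tscore_threshold Condition-positive rule on `fn_tscore`.
#' @param height_mean,height_sd Height model (metres) for weight
#'   reconstruction.
#' @param seed Seed for the height draw.
#' @return List with `sensitivity_pct`, `specificity_pct`, the 2x2
#'   `table`, and the `cutoff` used. Sensitivity is `NA` (with a message)
#'   when there are no condition-positives.
#' @export
osta_validate <- function(cohort, cutoff = -1, tscore_threshold = -2.5,
                          height_mean = 1.56, height_sd = 0.06, seed = 1) {
  if (anyNA(cohort$fn_tscore))
    stop("fn_tscore must be available (measured or imputed) for every ",
         "record", call. = FALSE)
  weight <- cohort$weight
  if (is.null(weight)) {
    message("no weight column: reconstructing weight from BMI with ",
            "height ~ Normal(", height_mean, ", ", height_sd, ")")
    set.seed(.factor_seed(seed, "osta_height"))
    height <- rnorm(nrow(cohort), height_mean, height_sd)
    weight <- cohort$bmi * height^2
  }
  screen_pos <- osta_index(weight, cohort$age) < cutoff
  cond_pos <- cohort$fn_tscore <= tscore_threshold
  tab <- table(screen = factor(screen_pos, c(TRUE, FALSE)),
               osteoporosis = factor(cond_pos, c(TRUE, FALSE)))
  sens <- if (sum(cond_pos) == 0) {
    message("no condition-positive records: sensitivity undefined")
    NA_real_
  } else 100 * sum(screen_pos & cond_pos) / sum(cond_pos)
  spec <- if (sum(!cond_pos) == 0) NA_real_ else
    100 * sum(!screen_pos & !cond_pos) / sum(!cond_pos)
  list(sensitivity_pct = sens, specificity_pct = spec, table = tab,
       cutoff = cutoff)
}
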