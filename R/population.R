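#' Ethnic population weights by 5-year age bin
#'
#' Proportions of each ethnic group within 5-year age bins tiling 40--90,
#' used to average per-ethnicity thresholds into a single national curve.
#' Proportions must sum to 1 within every bin.
#'
#' @param entries `data.frame` with columns `ethnicity`, `age_lo`, `age_hi`,
#'   `proportion`.
#' @return An object of class `population_weights`.
#' @export
population_weights <- function(entries) {
  need <- c("ethnicity", "age_lo", "age_hi", "proportion")
  if (!all(need %in% names(entries)))
    stop("weights need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bins <- unique(entries[c("age_lo", "age_hi")])
  bins <- bins[order(bins$age_lo), ]
  if (bins$age_lo[1] != 40 || bins$age_hi[nrow(bins)] != 90 ||
      any(bins$age_lo[-1] != bins$age_hi[-nrow(bins)]))
    stop("age bins must tile [40, 90] without gaps or overlap",
         call. = FALSE)
  sums <- tapply(entries$proportion, entries$age_lo, sum)
  if (any(abs(sums - 1) > 1e-9))
    stop("proportions must sum to 1 within every age bin", call. = FALSE)
  structure(entries, class = c("population_weights", "data.frame"))
}

# Weight of one ethnicity at one age (age 90 falls in the last bin).
.weight_at <- function(weights, ethnicity, age) {
  sel <- weights$ethnicity == ethnicity &
    weights$age_lo <= age &
    (age < weights$age_hi | (age == 90 & weights$age_hi == 90))
  if (!any(sel)) 0 else sum(weights$proportion[sel])
}

#' Ethnic- and age-dependent mean BMI reference
#'
#' Mean body mass index (kg/m2) by ethnicity and 5-year age bin; used to
#' build the average-woman profiles behind the intervention and assessment
#' thresholds. All values must lie in (14, 45).
#'
#' @param entries `data.frame` with columns `ethnicity`, `age_lo`, `age_hi`,
#'   `bmi`.
#' @return An object of class `bmi_reference`.
#' @export
bmi_reference <- function(entries) {
  need <- c("ethnicity", "age_lo", "age_hi", "bmi")
  if (!all(need %in% names(entries)))
    stop("BMI reference needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(entries$bmi <= 14 | entries$bmi >= 45))
    stop("reference BMI values must lie in (14, 45)", call. = FALSE)
  structure(entries, class = c("bmi_reference", "data.frame"))
}

.bmi_at <- function(bmi_ref, ethnicity, age) {
  sel <- bmi_ref$ethnicity == ethnicity &
    bmi_ref$age_lo <= age &
    (age < bmi_ref$age_hi | (age == 90 & bmi_ref$age_hi == 90))
  if (!any(sel))
    stop("no reference BMI for ", ethnicity, " at age ", age, call. = FALSE)
  bmi_ref$bmi[which(sel)[1]]
}

#' Default population weights and BMI reference
#'
#' Documented placeholders for a three-group population (Chinese, Malay,
#' Indian) with proportions roughly 0.76/0.13/0.11, the Chinese share
#' drifting slightly upward with age, and mean BMI declining mildly with
#' age from ethnic-specific mid-life levels (Chinese 23.5, Malay 26.5,
#' Indian 25.5 kg/m2 at 40--44). National census values can be substituted
#' through the same constructors.
#'
#' @return `default_population_weights()`: a [population_weights()];
#'   `default_bmi_reference()`: a [bmi_reference()].
#' @export
default_population_weights <- function() {
  lo <- seq(40, 85, 5)
  chinese <- round(seq(0.74, 0.80, length.out = length(lo)), 4)
  malay <- round(0.6 * (1 - chinese), 4)
  indian <- round(1 - chinese - malay, 4)
  population_weights(data.frame(
    ethnicity = rep(c("chinese", "malay", "indian"), each = length(lo)),
    age_lo = rep(lo, 3), age_hi = rep(lo + 5, 3),
    proportion = c(chinese, malay, indian)))
}

#' @rdname default_population_weights
#' @export
default_bmi_reference <- function() {
  lo <- seq(40, 85, 5)
  decline <- 0.15 * pmax(seq_along(lo) - 5, 0)  # mild decline from age 65
  bmi_reference(data.frame(
    ethnicity = rep(c("chinese", "malay", "indian"), each = length(lo)),
    age_lo = rep(lo, 3), age_hi = rep(lo + 5, 3),
    bmi = c(23.5 - decline, 26.5 - decline, 25.5 - decline)))
}
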