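#' Age-specific intervention threshold
#'
#' The intervention threshold (IT) at a given age is the 10-year major
#' osteoporotic fracture probability (without BMD) of a woman of average
#' BMI whose only clinical risk factor is a prior fragility fracture —
#' the risk-equivalence principle: women without a fracture but with an
#' equivalent probability are equally eligible for treatment. The
#' per-ethnicity probabilities are averaged with the population weights
#' for the age's 5-year bin.
#'
#' @param age Age in years, on the 5-year grid 40, 45, ..., 90 (off-grid
#'   ages are resolved by the [threshold_curve] lookup, not here).
#' @param models Named list of [hazard_model()] objects, one per ethnicity
#'   appearing in `weights`.
#' @param weights A [population_weights()].
#' @param bmi_ref A [bmi_reference()].
#' @return Threshold as a 10-year MOF probability in percent.
#' @export
intervention_threshold <- function(age, models = default_hazard_models(),
                                   weights = default_population_weights(),
                                   bmi_ref = default_bmi_reference()) {
  .weighted_threshold(age, models, weights, bmi_ref, prior_fracture = 1)
}

#' Age-specific lower assessment threshold
#'
#' The lower assessment threshold (LAT) is the 10-year MOF probability of a
#' woman of average BMI with *no* clinical risk factors: below it neither
#' treatment nor a BMD test is indicated.
#'
#' @inheritParams intervention_threshold
#' @return Threshold in percent.
#' @export
lower_assessment_threshold <- function(age, models = default_hazard_models(),
                                       weights = default_population_weights(),
                                       bmi_ref = default_bmi_reference()) {
  .weighted_threshold(age, models, weights, bmi_ref, prior_fracture = 0)
}

.weighted_threshold <- function(age, models, weights, bmi_ref,
                                prior_fracture) {
  eths <- unique(weights$ethnicity)
  missing_models <- setdiff(eths, names(models))
  if (length(missing_models))
    stop("weights name ethnicities without a hazard model: ",
         paste(missing_models, collapse = ", "), call. = FALSE)
  vapply(age, function(a) {
    total <- 0
    for (e in eths) {
      w <- .weight_at(weights, e, a)
      if (w == 0) next
      prof <- risk_profile(age = a, bmi = .bmi_at(bmi_ref, e, a),
                           prior_fracture = prior_fracture)
      total <- total + w * ten_year_probability(prof, models[[e]])$mof_pct
    }
    total
  }, numeric(1))
}

#' Upper assessment threshold from the intervention threshold
#'
#' Set at `uat_factor` (default 1.2) times the intervention threshold and
#' capped at 100%; above it treatment is recommended without a BMD test.
#' The factor is applied to the unrounded IT; any display rounding happens
#' afterwards.
#'
#' @param it_pct Intervention threshold(s) in percent, within \[0, 100\].
#' @param uat_factor Multiplier (default 1.2).
#' @return Upper assessment threshold(s) in percent.
#' @examples
#' upper_assessment_threshold(13.07)  # 15.684
#' @export
upper_assessment_threshold <- function(it_pct, uat_factor = 1.2) {
  if (any(it_pct < 0)) stop("it_pct must be non-negative", call. = FALSE)
  pmin(uat_factor * it_pct, 100)
}

#' Build the age-dependent threshold curve
#'
#' Evaluates the intervention and lower assessment thresholds at every
#' 5-year grid age 40--90 and derives the upper assessment threshold from
#' the unrounded IT. Off-grid ages are linearly interpolated by
#' [threshold_at()]; ages outside \[40, 90\] clamp to the end node with a
#' warning.
#'
#' @inheritParams intervention_threshold
#' @param uat_factor Passed to [upper_assessment_threshold()].
#' @return An object of class `threshold_curve`.
#' @seealso [read_threshold_curve()] to load a printed/published table
#'   verbatim instead of deriving the curve from an engine.
#' @export
build_threshold_curve <- function(models = default_hazard_models(),
                                  weights = default_population_weights(),
                                  bmi_ref = default_bmi_reference(),
                                  uat_factor = 1.2) {
  ages <- seq(40, 90, 5)
  it <- intervention_threshold(ages, models, weights, bmi_ref)
  lat <- lower_assessment_threshold(ages, models, weights, bmi_ref)
  new_threshold_curve(ages, it, lat,
                      upper_assessment_threshold(it, uat_factor),
                      uat_factor, source = "engine")
}

new_threshold_curve <- function(ages, it_pct, lat_pct, uat_pct,
                                uat_factor = 1.2, source = "engine") {
  if (is.unsorted(ages, strictly = TRUE))
    stop("threshold curve ages must be strictly increasing", call. = FALSE)
  if (any(lat_pct >= it_pct) || any(it_pct >= uat_pct))
    stop("threshold ordering violated: need LAT < IT < UAT at every age",
         call. = FALSE)
  structure(list(ages = ages, it_pct = it_pct, lat_pct = lat_pct,
                 uat_pct = uat_pct, uat_factor = uat_factor,
                 source = source),
            class = "threshold_curve")
}

#' Look up thresholds at arbitrary ages
#'
#' Linear interpolation between the curve's grid ages; ages outside the
#' grid are clamped to the nearest end node with a warning.
#'
#' @param curve A [threshold_curve][build_threshold_curve()].
#' @param age Vector of ages in years.
#' @return `data.frame` with columns `age`, `it_pct`, `lat_pct`, `uat_pct`.
#' @export
threshold_at <- function(curve, age) {
  lo <- min(curve$ages); hi <- max(curve$ages)
  if (any(age < lo | age > hi)) {
    warning("age(s) outside [", lo, ", ", hi,
            "] clamped to the end of the threshold curve", call. = FALSE)
    age <- pmin(pmax(age, lo), hi)
  }
  data.frame(
    age = age,
    it_pct = approx(curve$ages, curve$it_pct, xout = age)$y,
    lat_pct = approx(curve$ages, curve$lat_pct, xout = age)$y,
    uat_pct = approx(curve$ages, curve$uat_pct, xout = age)$y)
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat("<threshold_curve> (", x$source, "), UAT factor ", x$uat_factor,
      "\n", sep = "")
  print(data.frame(age = x$ages, it_pct = round(x$it_pct, 2),
                   lat_pct = round(x$lat_pct, 2),
                   uat_pct = round(x$uat_pct, 2)), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.threshold_curve <- function(x, ...) {
  data.frame(age = x$ages, it_pct = x$it_pct, lat_pct = x$lat_pct,
             uat_pct = x$uat_pct)
}

#' Plot the assessment zones of a threshold curve
#'
#' Shades the treat zone (above the UAT), the BMD-assessment band (between
#' the LAT and UAT) and the no-treatment zone (below the LAT) against age.
#'
#' @param x A `threshold_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.threshold_curve <- function(x, ...) {
  ymax <- max(x$uat_pct) * 1.05
  graphics::plot(NA, xlim = range(x$ages), ylim = c(0, ymax),
                 xlab = "Age (years)",
                 ylab = "10-year MOF probability (%)", ...)
  a <- x$ages
  polygon(c(a, rev(a)), c(x$uat_pct, rep(ymax, length(a))),
          col = "#f4cccc", border = NA)
  polygon(c(a, rev(a)), c(x$lat_pct, rev(x$uat_pct)),
          col = "#fce5cd", border = NA)
  polygon(c(a, rev(a)), c(rep(0, length(a)), rev(x$lat_pct)),
          col = "#d9ead3", border = NA)
  lines(a, x$it_pct, lwd = 2)
  lines(a, x$lat_pct, lty = 2)
  lines(a, x$uat_pct, lty = 2)
  legend("topleft", bty = "n", lwd = c(2, 1), lty = c(1, 2),
         legend = c("intervention threshold", "assessment thresholds"))
  invisible(x)
}

#' Write / read a threshold curve as CSV
#'
#' `write_threshold_curve()` writes a 2-decimal display file at `path` and,
#' alongside it, a full-precision sidecar (`*_full.csv`) used for exact
#' round-trips. `read_threshold_curve()` loads a curve verbatim from any
#' CSV with columns `age,it_pct,lat_pct,uat_pct` — including a published
#' threshold table — so the triage pathway can run without any probability
#' engine.
#'
#' @param curve A `threshold_curve`.
#' @param path CSV path.
#' @param uat_factor Factor recorded on a loaded curve (default 1.2).
#' @return `read_threshold_curve()` returns a `threshold_curve`;
#'   `write_threshold_curve()` returns `path` invisibly.
#' @export
write_threshold_curve <- function(curve, path) {
  df <- as.data.frame(curve)
  disp <- df
  disp[-1] <- lapply(disp[-1], function(v) sprintf("%.2f", v))
  write.csv(disp, path, row.names = FALSE, quote = FALSE)
  full <- sub("\\.csv$", "_full.csv", path)
  if (identical(full, path)) full <- paste0(path, "_full")
  fdf <- df
  fdf[-1] <- lapply(fdf[-1], function(v) sprintf("%.17g", v))
  write.csv(fdf, full, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_threshold_curve
#' @export
read_threshold_curve <- function(path, uat_factor = 1.2) {
  df <- read.csv(path)
  need <- c("age", "it_pct", "lat_pct", "uat_pct")
  if (!all(need %in% names(df)))
    stop("threshold curve CSV needs columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  df <- df[order(df$age), ]
  new_threshold_curve(df$age, df$it_pct, df$lat_pct, df$uat_pct,
                      uat_factor = uat_factor, source = path)
}

#' Published Singapore threshold table
#'
#' Loads the published age-dependent intervention and assessment thresholds
#' for Singapore (10-year MOF probability, percent, 5-year ages 40--90;
#' e.g. at age 65: IT 13.07, LAT 6.51, UAT 15.68) shipped with the package,
#' for use as an operating curve without any engine.
#'
#' @return A `threshold_curve`.
#' @export
published_threshold_curve <- function() {
  read_threshold_curve(system.file("extdata", "singapore_thresholds.csv",
                                   package = "fraxpath", mustWork = TRUE))
}
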