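one_ethnicity_config <- function(model, bmi = 23) {
  lo <- seq(40, 85, 5)
  list(models = list(test = model),
       weights = population_weights(
         data.frame(ethnicity = "test", age_lo = lo, age_hi = lo + 5,
                    proportion = 1)),
       bmi_ref = bmi_reference(
         data.frame(ethnicity = "test", age_lo = lo, age_hi = lo + 5,
                    bmi = bmi)))
}

test_that("degenerate single-ethnicity weighting returns the engine value", {
  m <- default_hazard_models()$chinese
  cfg <- one_ethnicity_config(m)
  it <- intervention_threshold(65, cfg$models, cfg$weights, cfg$bmi_ref)
  direct <- ten_year_probability(
    risk_profile(65, bmi = 23, prior_fracture = 1), m)$mof_pct
  expect_equal(it, direct, tolerance = 1e-12)
  lat <- lower_assessment_threshold(65, cfg$models, cfg$weights,
                                    cfg$bmi_ref)
  expect_equal(lat, ten_year_probability(risk_profile(65, bmi = 23),
                                         m)$mof_pct, tolerance = 1e-12)
})

test_that("two-ethnicity thresholds are the hand-computed weighted mean", {
  models <- default_hazard_models()[c("chinese", "malay")]
  lo <- seq(40, 85, 5)
  w <- 0.7
  weights <- population_weights(data.frame(
    ethnicity = rep(c("chinese", "malay"), each = length(lo)),
    age_lo = rep(lo, 2), age_hi = rep(lo + 5, 2),
    proportion = rep(c(w, 1 - w), each = length(lo))))
  bmi_ref <- bmi_reference(data.frame(
    ethnicity = rep(c("chinese", "malay"), each = length(lo)),
    age_lo = rep(lo, 2), age_hi = rep(lo + 5, 2),
    bmi = rep(c(23, 26), each = length(lo))))
  p1 <- ten_year_probability(risk_profile(70, bmi = 23,
                                          prior_fracture = 1),
                             models$chinese)$mof_pct
  p2 <- ten_year_probability(risk_profile(70, bmi = 26,
                                          prior_fracture = 1),
                             models$malay)$mof_pct
  it <- intervention_threshold(70, models, weights, bmi_ref)
  expect_equal(it, w * p1 + (1 - w) * p2, tolerance = 1e-12)
  # the weighted threshold lies between the per-ethnicity values
  expect_gte(it, min(p1, p2))
  expect_lte(it, max(p1, p2))
  # a weighted ethnicity without a model is a configuration error
  expect_error(intervention_threshold(70, models["chinese"], weights,
                                      bmi_ref), "without a hazard model")
})

test_that("IT collapses to LAT when the prior-fracture effect vanishes", {
  m <- const_hazard_model(rr_prior = 1 + 1e-12)
  cfg <- one_ethnicity_config(m)
  for (age in c(45, 60, 80))
    expect_equal(
      intervention_threshold(age, cfg$models, cfg$weights, cfg$bmi_ref),
      lower_assessment_threshold(age, cfg$models, cfg$weights,
                                 cfg$bmi_ref),
      tolerance = 1e-9)
})

test_that("upper assessment threshold is a capped pre-rounding multiple", {
  expect_equal(upper_assessment_threshold(13.07), 15.684)
  expect_identical(sprintf("%.2f", upper_assessment_threshold(13.07)),
                   "15.68")
  expect_equal(upper_assessment_threshold(8.35), 10.02)
  expect_equal(upper_assessment_threshold(0), 0)
  expect_equal(upper_assessment_threshold(90), 100)  # capped
  expect_error(upper_assessment_threshold(-1), "non-negative")
})

test_that("the engine-derived curve is ordered and age-monotone", {
  curve <- build_threshold_curve()
  expect_equal(curve$ages, seq(40, 90, 5))
  expect_true(all(curve$lat_pct < curve$it_pct))
  expect_true(all(curve$it_pct < curve$uat_pct))
  # UAT/IT ratio is exactly the factor, before any display rounding
  expect_equal(curve$uat_pct / curve$it_pct, rep(1.2, 11),
               tolerance = 1e-12)
  # IT rises with age for the default Gompertz configuration
  expect_true(all(diff(curve$it_pct) > 0))
  # LAT < IT whenever the prior-fracture RR exceeds 1, swept over the grid
  lat_sweep <- lower_assessment_threshold(curve$ages)
  expect_true(all(lat_sweep < curve$it_pct))
})

test_that("threshold lookup interpolates linearly and clamps with warning", {
  curve <- published_threshold_curve()
  at65 <- threshold_at(curve, 65)
  expect_equal(at65$it_pct, 13.07)
  expect_equal(at65$lat_pct, 6.51)
  expect_equal(at65$uat_pct, 15.68)
  mid <- threshold_at(curve, 62.5)
  expect_equal(mid$it_pct, (8.35 + 13.07) / 2)
  expect_equal(mid$lat_pct, (3.95 + 6.51) / 2)
  expect_warning(lowest <- threshold_at(curve, 30), "clamped")
  expect_equal(lowest$it_pct, 1.51)
})

test_that("curves round-trip through CSV with bit-identical lookups", {
  curve <- build_threshold_curve()
  path <- file.path(withr::local_tempdir(), "curve.csv")
  write_threshold_curve(curve, path)
  reread <- read_threshold_curve(sub("\\.csv$", "_full.csv", path))
  ages <- seq(40, 90, 0.5)
  expect_identical(threshold_at(reread, ages), threshold_at(curve, ages))
  # the display file is rounded to 2 decimals
  disp <- read.csv(path)
  expect_equal(disp$it_pct, round(curve$it_pct, 2), tolerance = 1e-9)
  # disordered or mislabelled files are rejected
  expect_error(new_curve <- read_threshold_curve(
    {p <- tempfile(fileext = ".csv")
     write.csv(data.frame(age = 1), p, row.names = FALSE); p}),
    "needs columns")
})
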