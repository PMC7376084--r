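test_that("triage matches brute-force classification on a hand-built cohort", {
  curve <- published_threshold_curve()
  # six age-65 women hitting all five categories via supplied
  # probabilities (age-65 thresholds: LAT 6.51, IT 13.07, UAT 15.68)
  cohort <- do.call(rbind, lapply(1:6, function(i)
    cohort_row(i, age = 65, bmi = 23)))
  cohort$prior_fracture <- c(1L, 0L, 0L, 0L, 0L, 0L)
  cohort$mof_pct_no_bmd <- c(20, 6.0, 17, 10, 10, 6.51)
  cohort$mof_pct_with_bmd <- c(NA, NA, NA, 13.5, 13.06, 5.0)
  rec <- triage(cohort, curve)
  brute <- function(pf, p0, p1, it, lat, uat) {
    if (pf == 1) "treat_prior_fracture"
    else if (p0 < lat) "no_treat_below_lat"
    else if (p0 > uat) "treat_above_uat"
    else if (p1 >= it) "bmd_then_treat"
    else "bmd_then_no_treat"
  }
  expected <- mapply(brute, cohort$prior_fracture, cohort$mof_pct_no_bmd,
                     cohort$mof_pct_with_bmd, 13.07, 6.51, 15.68)
  expect_equal(rec$category, unname(expected))
  expect_setequal(rec$category, fraxpath:::DISPOSITION_CATEGORIES)
  # boundary ties: both band edges refer for BMD; >= IT with BMD treats
  expect_equal(rec$category[6], "bmd_then_no_treat")   # p0 == LAT -> band
  edge <- cohort[1, ]
  edge$prior_fracture <- 0L
  edge$mof_pct_no_bmd <- 15.68                          # p0 == UAT -> band
  edge$mof_pct_with_bmd <- 13.07                        # == IT -> treat
  expect_equal(triage(edge, curve)$category, "bmd_then_treat")
  # a prior fracture needs no probability at all
  expect_true(is.na(rec$mof_pct_no_bmd[1]))
})

test_that("triage through the engine partitions any cohort exactly", {
  m <- default_hazard_models()$chinese
  curve <- build_threshold_curve()
  truth <- attr(generate_target_cohort(cohort_spec(n = 1500), 21),
                "truth")
  rec <- triage(truth, curve, m)
  expect_equal(nrow(rec), 1500)
  expect_false(anyNA(rec$category))
  counts <- table(factor(rec$category,
                         fraxpath:::DISPOSITION_CATEGORIES))
  expect_equal(sum(counts), 1500)
  # the BMD branch stayed within the assessment band
  band <- rec$category %in% c("bmd_then_treat", "bmd_then_no_treat")
  expect_true(all(rec$mof_pct_no_bmd[band] >= rec$lat_pct[band]))
  expect_true(all(rec$mof_pct_no_bmd[band] <= rec$uat_pct[band]))
  expect_true(all(is.na(rec$mof_pct_with_bmd[!band])))
  # missing T-scores in the band: error without a model, imputed with one
  blanked <- truth
  blanked$fn_tscore <- NA_real_
  expect_error(triage(blanked, curve, m), "imputation is disabled")
  imp <- fit_imputation_model(generate_reference_cohort(3000, 22))
  rec2 <- triage(blanked, curve, m, imputation = imp, seed = 5)
  expect_true(any(rec2$tscore_imputed))
  expect_false(anyNA(rec2$category))
  expect_error(triage(blanked, curve, m, imputation = imp,
                      require_bmd = TRUE), "imputation is disabled")
})

test_that("disposition summary reports the overlapping guidance rows", {
  m <- default_hazard_models()$chinese
  curve <- build_threshold_curve()
  truth <- attr(generate_target_cohort(cohort_spec(n = 1200), 31),
                "truth")
  rec <- triage(truth, curve, m)
  summ <- disposition_summary(rec, truth, m)
  g <- function(x) summ[summ$group == x, ]
  expect_equal(g("entire_cohort")$n, 1200)
  atomic <- summ$n[summ$group %in% fraxpath:::DISPOSITION_CATEGORIES]
  expect_equal(sum(atomic), 1200)                     # exact partition
  expect_equal(sum(summ$pct[summ$group %in%
                              fraxpath:::DISPOSITION_CATEGORIES]), 100,
               tolerance = 1e-9)
  expect_equal(g("otherwise_eligible")$n,
               g("treat_above_uat")$n + g("bmd_then_treat")$n)
  expect_equal(g("bmd_tests")$n,
               g("bmd_then_treat")$n + g("bmd_then_no_treat")$n)
  expect_equal(g("no_treatment")$n,
               g("no_treat_below_lat")$n + g("bmd_then_no_treat")$n)
  # treated women carry higher risk than untreated women
  treated <- rec$category %in% c("treat_prior_fracture",
                                 "treat_above_uat", "bmd_then_treat")
  p <- cohort_probabilities(truth, m)$mof_pct
  expect_gt(mean(p[treated]), mean(p[!treated]))
  expect_error(disposition_summary(rbind(rec, rec), truth), "duplicate")
})

test_that("every-woman-prior-fracture cohorts are all treated", {
  curve <- published_threshold_curve()
  cohort <- do.call(rbind, lapply(1:40, function(i)
    cohort_row(i, age = 60 + i %% 20, bmi = 24, prior_fracture = 1)))
  rec <- triage(cohort, curve, model = NULL)  # no engine needed
  expect_true(all(rec$category == "treat_prior_fracture"))
  summ <- disposition_summary(rec, cohort)
  expect_equal(summ$pct[summ$group == "treat_prior_fracture"], 100)
  expect_equal(summ$n[summ$group == "bmd_tests"], 0)
})

test_that("raising the UAT factor shifts women from treatment to referral", {
  m <- default_hazard_models()$chinese
  truth <- attr(generate_target_cohort(cohort_spec(n = 1500), 41),
                "truth")
  n_above <- function(f) {
    curve <- build_threshold_curve(uat_factor = f)
    rec <- triage(truth, curve, m)
    c(above = sum(rec$category == "treat_above_uat"),
      band = sum(rec$category %in% c("bmd_then_treat",
                                     "bmd_then_no_treat")))
  }
  lo <- n_above(1.1); hi <- n_above(1.4)
  expect_lte(hi[["above"]], lo[["above"]])
  expect_gte(hi[["band"]], lo[["band"]])
})

test_that("calibration bins are left-closed and totals reconcile", {
  m <- const_hazard_model(h_hip = 0, h_mof = 0, h_death = 0.01)
  cohort <- do.call(rbind, lapply(1:50, function(i)
    cohort_row(i, age = 60, bmi = 23, followup_years = 9,
               hip_fracture_observed = 0L)))
  tab0 <- calibration_table(cohort, m)
  expect_true(all(tab0$expected == 0) && all(tab0$observed == 0))

  # a probability exactly on a bin edge lands in the higher bin
  expect_equal(fraxpath:::.prob_bin(2, 1), 2)
  expect_equal(fraxpath:::.prob_bin(2 - 1e-12, 1), 1)
  expect_equal(fraxpath:::.prob_bin(c(0, 0.5, 0.99, 1), 1), c(0, 0, 0, 1))
  # an interior probability is tallied in its own bin
  h <- -log(1 - 0.025) / 10          # 10-y probability 2.5%
  m2 <- const_hazard_model(h_hip = h, h_mof = h, h_death = 0)
  one <- cohort_row(1, age = 60, bmi = 25, followup_years = 10,
                    hip_fracture_observed = 1L)
  tab2 <- calibration_table(one, m2, bin_width = 1)
  expect_equal(tab2$n[tab2$bin_lo == 2], 1)
  expect_equal(tab2$observed[tab2$bin_lo == 2], 1)

  # totals equal the expected-count operation; cumulative rows agree
  mC <- default_hazard_models()$chinese
  truth <- attr(generate_target_cohort(cohort_spec(n = 2000), 51),
                "truth")
  fl <- simulate_followup(truth, mC, seed = 52)
  tab <- calibration_table(fl, mC)
  expect_equal(sum(tab$expected), expected_fracture_count(fl, mC, "hip"),
               tolerance = 1e-9)
  expect_equal(tab$cum_observed[nrow(tab)], sum(fl$hip_fracture_observed))
  bad <- fl; bad$followup_years[1] <- -2
  expect_error(calibration_table(bad, mC), "negative")
})
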