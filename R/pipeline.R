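#' Configuration for a full end-to-end run
#'
#' Bundles every input of [run_full_pipeline()]: problem sizes, one seed
#' per stochastic stage, the threshold configuration and the output
#' directory. All seeds are recorded in the run manifest.
#'
#' @param out_dir Output directory (created if absent).
#' @param n Target-cohort size.
#' @param n_reference Reference-cohort size.
#' @param seed Base seed; per-stage seeds default to offsets of it.
#' @param seeds Named list with `simulate`, `reference`, `impute`,
#'   `followup` (integers).
#' @param spec A [cohort_spec()] for the target cohort (its `n` is
#'   overridden by `n`).
#' @param models Named list of per-ethnicity [hazard_model()]s.
#' @param weights,bmi_ref Threshold configuration (see
#'   [build_threshold_curve()]).
#' @param curve_file Optional CSV of a threshold curve to load verbatim
#'   (e.g. a published table) instead of deriving one from the engine.
#' @param uat_factor Upper-assessment-threshold multiplier.
#' @param osta_cutoff OSTA screen-positive cutoff.
#' @param bin_width Calibration bin width (probability percentage points).
#' @param tscore_noise Add Gaussian residual when imputing T-scores.
#' @param make_plots Write PDF figures alongside the CSVs.
#' @param step Integration step (years).
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, n = 2000, n_reference = 4000, seed = 1,
                       seeds = list(simulate = seed, reference = seed + 1,
                                    impute = seed + 2, followup = seed + 3),
                       spec = cohort_spec(), models = default_hazard_models(),
                       weights = default_population_weights(),
                       bmi_ref = default_bmi_reference(),
                       curve_file = NULL, uat_factor = 1.2,
                       osta_cutoff = -1, bin_width = 1,
                       tscore_noise = TRUE, make_plots = TRUE,
                       step = 0.05) {
  need <- c("simulate", "reference", "impute", "followup")
  if (!all(need %in% names(seeds)))
    stop("seeds must name: ", paste(need, collapse = ", "), call. = FALSE)
  spec$n <- n
  structure(list(out_dir = out_dir, n = n, n_reference = n_reference,
                 seeds = seeds, spec = spec, models = models,
                 weights = weights, bmi_ref = bmi_ref,
                 curve_file = curve_file, uat_factor = uat_factor,
                 osta_cutoff = osta_cutoff, bin_width = bin_width,
                 tscore_noise = tscore_noise, make_plots = make_plots,
                 step = step),
            class = "run_config")
}

.config_hash <- function(config) {
  keep <- config[setdiff(names(config), c("out_dir", "make_plots"))]
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(paste(utils::capture.output(utils::str(keep, digits.d = 15)),
                   collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full case-finding pipeline
#'
#' Executes, in order: synthetic target-cohort generation; reference
#' generation; imputation-model fitting; stochastic imputation of the
#' missing variables; threshold-curve construction (or verbatim load);
#' triage; follow-up simulation on the truth cohort; calibration and
#' disposition audit; OSTA screening check. Writes all artifacts (cohort,
#' truth, reference, imputation model YAML, threshold curve CSVs,
#' disposition records and summary, calibration table, prevalence
#' comparison, manifest, optional PDF figures) into `config$out_dir`.
#' Re-running with the same configuration reproduces every CSV
#' byte-identically.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory artifacts (`summary`,
#'   `records`, `curve`, `calibration`, `osta`, `prevalence`,
#'   `expected_hip`, `observed_hip`, `paths`).
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$out_dir, f)
  engine <- config$models[[1]]

  target <- .stage("simulate",
                   generate_target_cohort(config$spec,
                                          config$seeds$simulate))
  truth <- attr(target, "truth")
  message("simulate: ", nrow(target), " target records")
  reference <- .stage("reference",
                      generate_reference_cohort(config$n_reference,
                                                config$seeds$reference,
                                                config$spec))
  message("reference: ", nrow(reference), " records")
  imp <- .stage("fit-impute", fit_imputation_model(reference))
  imputed <- .stage("impute",
                    impute_missing(target, imp, config$seeds$impute,
                                   noise = config$tscore_noise))
  message("impute: filled ", sum(vapply(target, anyNA, logical(1))),
          " blanked columns")
  curve <- .stage("thresholds", {
    if (!is.null(config$curve_file))
      read_threshold_curve(config$curve_file, config$uat_factor)
    else
      build_threshold_curve(config$models, config$weights,
                            config$bmi_ref, config$uat_factor)
  })
  records <- .stage("triage",
                    triage(imputed, curve, engine, imputation = imp,
                           seed = config$seeds$impute, step = config$step))
  message("triage: ", nrow(records), " dispositions")
  followed <- .stage("followup",
                     simulate_followup(truth, engine,
                                       seed = config$seeds$followup,
                                       step = config$step))
  calib <- .stage("calibration",
                  calibration_table(followed, engine, config$bin_width,
                                    config$step))
  summary_tab <- .stage("summary",
                        disposition_summary(records, imputed, engine,
                                            config$step))
  prev <- .stage("prevalence", prevalence_report(imputed, reference))
  osta <- .stage("osta",
                 suppressMessages(
                   osta_validate(imputed, cutoff = config$osta_cutoff,
                                 seed = config$seeds$impute)))
  expected_hip <- sum(calib$expected)
  observed_hip <- sum(calib$observed)
  message("calibration: expected ", round(expected_hip, 1),
          " vs observed ", observed_hip, " hip fractures")

  write_cohort(imputed, path("cohort.csv"))
  write_cohort(truth, path("truth.csv"))
  write_cohort(reference, path("reference.csv"))
  write_cohort(followed, path("followed.csv"))
  write_imputation_model(imp, path("imputation_model.yaml"))
  write_threshold_curve(curve, path("thresholds.csv"))
  write.csv(records, path("dispositions.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(as.data.frame(summary_tab), path("disposition_summary.csv"),
            row.names = FALSE, quote = FALSE)
  writeLines(utils::capture.output(print(summary_tab)),
             path("disposition_summary.txt"))
  write.csv(calib, path("calibration.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(prev, path("prevalence.csv"), row.names = FALSE, quote = FALSE)
  manifest <- list(package = "fraxpath",
                   version = as.character(packageVersion("fraxpath")),
                   n = config$n, n_reference = config$n_reference,
                   seeds = config$seeds,
                   uat_factor = config$uat_factor,
                   osta_cutoff = config$osta_cutoff,
                   bin_width = config$bin_width,
                   config_hash = .config_hash(config),
                   curve_source = curve$source)
  yaml::write_yaml(manifest, path("manifest.yaml"))
  if (isTRUE(config$make_plots)) {
    pdf(path("thresholds.pdf"), width = 6, height = 5)
    plot(curve, main = "Assessment zones")
    dev.off()
    pdf(path("calibration.pdf"), width = 6, height = 5)
    barplot(rbind(calib$expected, calib$observed), beside = TRUE,
            names.arg = sprintf("%g-%g", calib$bin_lo, calib$bin_hi),
            legend.text = c("expected", "observed"),
            xlab = "10-year hip fracture probability bin (%)",
            ylab = "First hip fractures")
    dev.off()
  }
  invisible(list(summary = summary_tab, records = records, curve = curve,
                 calibration = calib, osta = osta, prevalence = prev,
                 expected_hip = expected_hip, observed_hip = observed_hip,
                 paths = config$out_dir))
}
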