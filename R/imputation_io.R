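#' Read or write an imputation model as YAML
#'
#' One block per factor with `type`, `covariates`, `coef` (named mapping
#' including the intercept) and, for the T-score model, `residual_sd`.
#'
#' @param model An [imputation_model][fit_imputation_model()].
#' @param path File path.
#' @return `read_imputation_model()` returns an `imputation_model`;
#'   `write_imputation_model()` returns `path` invisibly.
#' @export
write_imputation_model <- function(model, path) {
  y <- list(n_reference = model$n_reference,
            factors = lapply(model$factors, function(m) {
              out <- list(type = m$type,
                          covariates = as.list(m$covariates),
                          coef = as.list(m$coef))
              if (!is.null(m$residual_sd)) out$residual_sd <- m$residual_sd
              out
            }))
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

#' @rdname write_imputation_model
#' @export
read_imputation_model <- function(path) {
  y <- yaml::read_yaml(path)
  factors <- lapply(y$factors, function(m) {
    out <- list(type = m$type,
                covariates = as.character(unlist(m$covariates)),
                coef = unlist(m$coef))
    if (!is.null(m$residual_sd)) out$residual_sd <- m$residual_sd
    out
  })
  structure(list(factors = factors, n_reference = y$n_reference),
            class = "imputation_model")
}
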