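# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an IHPP fit
#'
#' @param x An [fit_ihpp()] result.
#' @param ... Unused.
#' @return Tibble `term, estimate, se, z, p_value`.
#' @exportS3Method generics::tidy
tidy.ihpp_fit <- function(x, ...) x$coefficients

#' @rdname tidy.ihpp_fit
#' @exportS3Method generics::glance
glance.ihpp_fit <- function(x, ...) {
  tibble(log_lik = x$log_lik, n_at_risk = x$n_at_risk, n_events = x$n_events,
         colony_treatment_dropped = x$colony_treatment_dropped)
}

#' Tidy a per-second interaction-rate GLM
#'
#' @param x An [fit_rate_glm()] result.
#' @param ... Unused.
#' @return Coefficient tibble (estimate, Wald statistic, 95% CLs, p-value).
#' @exportS3Method generics::tidy
tidy.rate_glm <- function(x, ...) x$coefficients

#' @rdname tidy.rate_glm
#' @exportS3Method generics::glance
glance.rate_glm <- function(x, ...) {
  tibble(deviance = x$fit$deviance, null_deviance = x$fit$null.deviance,
         aic = x$fit$aic, n = length(x$fit$fitted.values))
}

#' Tidy a local-density mixed model
#'
#' @param x An [fit_density_model()] result.
#' @param ... Unused.
#' @return One-row tibble with the high-vs-low effect and Wald test.
#' @exportS3Method generics::tidy
tidy.density_model <- function(x, ...) x$effect

#' @rdname tidy.density_model
#' @exportS3Method generics::glance
glance.density_model <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  tibble(colony_sd = vc$sdcor[vc$grp == "colony"],
         residual_sd = vc$sdcor[vc$grp == "Residual"],
         n = stats::nobs(x$fit))
}

#' Tidy an SDE movement fit
#'
#' @param x An [fit_sde()] result.
#' @param ... Unused.
#' @return The per-cell surface tibble.
#' @exportS3Method generics::tidy
tidy.sde_fit <- function(x, ...) x$surfaces

#' @rdname tidy.sde_fit
#' @exportS3Method generics::glance
glance.sde_fit <- function(x, ...) {
  tibble(beta = x$beta, grid_mm = x$grid_mm, n_cells = nrow(x$surfaces),
         n_records = x$n_records, sigma2 = x$sigma2,
         lambda_drift = x$lambda[["drift"]],
         lambda_motility = x$lambda[["motility"]])
}
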