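#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a dose-model fit
#'
#' One row per model parameter with the point estimate and the bootstrap
#' percentile confidence interval (NA when fitted without a bootstrap or
#' when the parameter was unidentifiable).
#'
#' @param x A `graftkit_fit` from [fit_retention()] or [fit_growth()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `conf.low`,
#'   `conf.high`.
#' @export
tidy.graftkit_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    conf.low = x$ci$lower[match(names(x$estimates), x$ci$term)],
    conf.high = x$ci$upper[match(names(x$estimates), x$ci$term)]
  )
}

#' One-row summary of a dose-model fit
#'
#' @param x A `graftkit_fit`.
#' @param ... Unused.
#' @return A tibble with goodness-of-fit metrics, the residual-trend
#'   diagnostic, site counts and convergence/identifiability flags.
#' @export
glance.graftkit_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    r.squared = x$r_squared,
    mae = x$mae,
    rmse = x$rmse,
    spearman_rho = x$trend$spearman_rho,
    trend_p = x$trend$p_value,
    trend_flagged = x$trend$flagged,
    n_sites = x$n_sites,
    n_excluded_qc = x$n_excluded_qc,
    boot_failures = x$boot_failures,
    converged = x$converged,
    flags = paste(x$flags, collapse = ";")
  )
}

#' Per-site observations, predictions and residuals of a fit
#'
#' @param x A `graftkit_fit`.
#' @param ... Unused.
#' @return The per-site residual tibble (`site_id`, `x`, `observed`,
#'   `predicted`, `residual`).
#' @export
augment.graftkit_fit <- function(x, ...) {
  x$residuals
}
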