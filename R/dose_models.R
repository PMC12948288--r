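#' Needle-track sealing force parameters
#'
#' The retention model is derived from a sealing force along the needle track
#' that opposes cell reflux, assumed \eqn{N(d) = k d^n}. With n = 1 and a
#' retention-sensitivity scale alpha, the lumped retention parameter is
#' beta = alpha * k.
#'
#' @param k Sealing scale (force units per mm^n), k > 0.
#' @param n Depth exponent, n >= 1. Defaults to 1 (the linear assumption).
#' @param alpha Optional retention-sensitivity scale per force unit.
#' @return An object of class `sealing_params`.
#' @export
sealing_params <- function(k, n = 1, alpha = NULL) {
  stopifnot(is.numeric(k), length(k) == 1, k > 0,
            is.numeric(n), length(n) == 1, n >= 1)
  if (!is.null(alpha)) {
    stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0)
  }
  structure(list(k = k, n = n, alpha = alpha), class = "sealing_params")
}

#' Sealing force at an insertion depth
#'
#' \eqn{N(d) = k d^n}: zero at the surface and strictly increasing with depth.
#'
#' @param d Depth in mm (vectorized).
#' @param params A [sealing_params()] object.
#' @return Force in the same arbitrary units as k.
#' @export
sealing_force <- function(d, params) {
  stopifnot(inherits(params, "sealing_params"), is.numeric(d))
  if (any(d < 0)) stop("depth must be non-negative", call. = FALSE)
  params$k * d^params$n
}

#' Retention-versus-depth model
#'
#' Saturating-exponential model of the fraction of injected cells retained at
#' the target after needle withdrawal: \eqn{R(d) = 1 - e^{-\beta d^n}}.
#' Retention is 0 at the surface and approaches 100% asymptotically with
#' depth; a larger beta reaches high retention at shallower depths. The
#' agarose calibration experiment yields beta around 0.24 per mm for neural
#' stem cells.
#'
#' @param beta Retention rate parameter, per mm (per mm^n when n != 1);
#'   beta > 0.
#' @param n Depth exponent inherited from the sealing-force relation;
#'   default 1.
#' @return An object of class `retention_model`.
#' @examples
#' m <- retention_model(beta = 0.24)
#' retention_at_depth(c(0.5, 1.5, 3), m)
#' depth_for_retention(0.5, m)   # depth for 50% retention
#' @export
retention_model <- function(beta, n = 1) {
  stopifnot(is.numeric(beta), length(beta) == 1, beta > 0,
            is.numeric(n), length(n) == 1, n >= 1)
  structure(list(beta = beta, n = n), class = "retention_model")
}

#' @export
print.retention_model <- function(x, ...) {
  cat(sprintf("<retention_model> R(d) = 1 - exp(-%g * d^%g), d in mm\n",
              x$beta, x$n))
  invisible(x)
}

#' Retained fraction at an injection depth
#'
#' @param d Depth in mm (vectorized).
#' @param model A [retention_model()].
#' @return Retained fraction in [0, 1).
#' @export
retention_at_depth <- function(d, model) {
  stopifnot(inherits(model, "retention_model"), is.numeric(d))
  if (any(d < 0)) stop("depth must be non-negative", call. = FALSE)
  1 - exp(-model$beta * d^model$n)
}

#' Depth required for a target retained fraction
#'
#' Analytic inverse of the retention model:
#' \eqn{d = (-\ln(1 - R)/\beta)^{1/n}}. Used by planners to translate a
#' desired retention into an injection depth.
#'
#' @param target Target retained fraction, in [0, 1) (vectorized). 1 is
#'   unreachable (the model saturates asymptotically).
#' @param model A [retention_model()].
#' @return Depth in mm.
#' @export
depth_for_retention <- function(target, model) {
  stopifnot(inherits(model, "retention_model"), is.numeric(target))
  if (any(target < 0) || any(target >= 1)) {
    stop("target retention must lie in [0, 1); 100% is asymptotic",
         call. = FALSE)
  }
  (-log(1 - target) / model$beta)^(1 / model$n)
}

#' Growth-versus-volume model
#'
#' Early graft growth limited by hypoperfusion:
#' \eqn{G(v) = G_{max} (1 - HypoR(v))^\gamma}, where HypoR is the
#' hypoperfused fraction of a spherical graft of volume v
#' ([hypoperfused_fraction_volume()]). G equals Gmax for volumes at or below
#' the threshold volume and decreases strictly beyond it. gamma controls how
#' sharply growth falls with hypoperfusion; the calibration experiments
#' support gamma = 3.
#'
#' @param g_max Maximal growth readout (fold-change of the viability signal
#'   over the assay window), g_max > 0.
#' @param gamma Sensitivity exponent, gamma > 0; default 3.
#' @param margin Oxygenated margin passed to the hypoperfusion model, um.
#' @return An object of class `growth_model`.
#' @examples
#' g <- growth_model(g_max = 1)
#' growth_rate(ul_to_um3(c(0.1, 0.25, 0.5, 1)), g)
#' @export
growth_model <- function(g_max, gamma = 3, margin = 100) {
  stopifnot(is.numeric(g_max), length(g_max) == 1, g_max > 0,
            is.numeric(gamma), length(gamma) == 1, gamma > 0,
            is.numeric(margin), length(margin) == 1, margin > 0)
  structure(list(g_max = g_max, gamma = gamma, margin = margin),
            class = "growth_model")
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf(
    "<growth_model> G(v) = %g * (1 - HypoR(v))^%g, margin %g um (V_th ~ %.2f nL)\n",
    x$g_max, x$gamma, x$margin, um3_to_nl(threshold_volume(x$margin))))
  invisible(x)
}

#' Growth readout predicted for an injected volume
#'
#' @param v Graft volume in um^3 (vectorized; see [ul_to_um3()]).
#' @param model A [growth_model()].
#' @return Growth readout in the units of `g_max`.
#' @export
growth_rate <- function(v, model) {
  stopifnot(inherits(model, "growth_model"), is.numeric(v))
  if (any(v < 0)) stop("volume must be non-negative", call. = FALSE)
  model$g_max * (1 - hypoperfused_fraction_volume(v, model$margin))^model$gamma
}
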