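#' Largest graft volume within a hypoperfusion budget
#'
#' Analytic inverse of the spherical hypoperfusion model: the largest volume
#' whose hypoperfused fraction does not exceed `h`. Solving
#' \eqn{((r - margin)/r)^3 = h} gives \eqn{r = margin / (1 - h^{1/3})}.
#'
#' @param h Acceptable hypoperfused fraction, in [0, 1).
#' @param margin Oxygenated margin thickness, um.
#' @return Volume in um^3 (convert with [um3_to_nl()]).
#' @examples
#' um3_to_nl(max_volume_for_hypoperfusion_budget(0.278))  # ~100 nL
#' @export
max_volume_for_hypoperfusion_budget <- function(h, margin = 100) {
  stopifnot(is.numeric(h), is.numeric(margin), margin > 0)
  if (any(h < 0) || any(h >= 1)) {
    stop("hypoperfusion budget must lie in [0, 1)", call. = FALSE)
  }
  r <- margin / (1 - h^(1 / 3))
  volume_from_radius(r)
}

#' Pulse-elevation injection schedule
#'
#' Splits a total dose into equal boluses delivered at linearly spaced,
#' successively shallower depths with a pause between steps — the
#' pulse-elevation mode that improves superficial retention by letting each
#' bolus settle into the space opened along the needle track. The reference
#' protocol delivers 100 nL as five 20-nL steps at 0.5, 0.4, 0.3, 0.2 and
#' 0.1 mm with 20-s pauses at 0.1 uL/min, followed by a final dwell.
#'
#' @param total_nl Total injected volume, nL.
#' @param d_start_mm Deepest (first) injection depth, mm.
#' @param d_end_mm Shallowest (last) injection depth, mm; must not exceed
#'   `d_start_mm`.
#' @param n_steps Number of boluses; 1 reduces to a single continuous-mode
#'   bolus at `d_start_mm`.
#' @param rate_ul_min Infusion rate, uL/min (default 0.1).
#' @param pause_s Pause between steps, s (default 20).
#' @param final_dwell_s Dwell after the last step before withdrawal, s
#'   (default 300, i.e. 5 min to promote diffusion and reduce backflow).
#' @return An `injection_plan`: a tibble of steps (`step`, `depth_mm`,
#'   `volume_nl`, `pause_after_s`) with the rate, dwell and total volume as
#'   attributes. Any sub-nanolitre remainder from the equal split is assigned
#'   to the deepest step, where predicted retention is highest.
#' @examples
#' pulse_elevation_schedule(100, 0.5, 0.1, 5)
#' @export
pulse_elevation_schedule <- function(total_nl, d_start_mm, d_end_mm,
                                     n_steps, rate_ul_min = 0.1,
                                     pause_s = 20, final_dwell_s = 300) {
  stopifnot(is.numeric(total_nl), total_nl > 0,
            is.numeric(n_steps), n_steps >= 1, n_steps == round(n_steps),
            d_end_mm >= 0, rate_ul_min > 0, pause_s >= 0, final_dwell_s >= 0)
  if (d_end_mm > d_start_mm) {
    stop("`d_end_mm` must not exceed `d_start_mm` (withdrawal is upward)",
         call. = FALSE)
  }
  n_steps <- as.integer(n_steps)
  depths <- if (n_steps == 1) d_start_mm else
    seq(d_start_mm, d_end_mm, length.out = n_steps)
  per <- total_nl / n_steps
  volumes <- rep(per, n_steps)
  volumes[1] <- total_nl - per * (n_steps - 1)  # remainder to deepest step
  steps <- tibble::tibble(
    step = seq_len(n_steps),
    depth_mm = depths,
    volume_nl = volumes,
    pause_after_s = c(rep(pause_s, n_steps - 1), final_dwell_s)
  )
  structure(steps,
            class = c("injection_plan", class(steps)),
            rate_ul_min = rate_ul_min,
            final_dwell_s = final_dwell_s,
            total_nl = total_nl,
            predicted = NULL)
}

#' Attach model predictions to an injection plan
#'
#' Fills per-step predicted retention from the retention model, a
#' volume-weighted aggregate retention (a first-order model-based estimate:
#' each bolus is assumed to be retained according to its own deposition
#' depth), and the hypoperfused fraction of the total delivered volume.
#'
#' @param plan An [pulse_elevation_schedule()] plan.
#' @param retention_model A [retention_model()].
#' @param margin Oxygenated margin for the hypoperfusion prediction, um.
#' @return The plan with a `retention` column added and a `predicted`
#'   attribute: `list(aggregate_retention, hypor_of_total)`. Retrieve with
#'   [plan_predictions()].
#' @examples
#' plan <- pulse_elevation_schedule(100, 0.5, 0.1, 5)
#' plan <- plan_report(plan, retention_model(0.24))
#' plan_predictions(plan)
#' @export
plan_report <- function(plan, retention_model, margin = 100) {
  stopifnot(inherits(plan, "injection_plan"),
            inherits(retention_model, "retention_model"))
  r <- retention_at_depth(plan$depth_mm, retention_model)
  total <- attr(plan, "total_nl")
  w <- plan$volume_nl / total
  plan$retention <- r
  attr(plan, "predicted") <- list(
    aggregate_retention = sum(w * r),
    hypor_of_total = hypoperfused_fraction_volume(nl_to_um3(total), margin)
  )
  plan
}

#' @rdname plan_report
#' @param x An `injection_plan` (for `plan_predictions`).
#' @export
plan_predictions <- function(x) {
  stopifnot(inherits(x, "injection_plan"))
  attr(x, "predicted")
}

#' @export
print.injection_plan <- function(x, ...) {
  cat(sprintf(
    "<injection_plan> %g nL total, %d step(s), %g uL/min, final dwell %g s\n",
    attr(x, "total_nl"), nrow(x), attr(x, "rate_ul_min"),
    attr(x, "final_dwell_s")))
  NextMethod()
  p <- attr(x, "predicted")
  if (!is.null(p)) {
    cat(sprintf(
      "predicted (model-based estimate): aggregate retention %.4f, HypoR of total %.4f\n",
      p$aggregate_retention, p$hypor_of_total))
  }
  invisible(x)
}
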