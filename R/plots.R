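#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a dose-model fit
#'
#' Observed site-level values with the fitted curve overlaid (retention
#' versus depth, or growth/hypoperfusion versus volume).
#'
#' @param object A `graftkit_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.graftkit_fit <- function(object, ...) {
  res <- object$residuals
  xlab <- switch(object$model,
                 retention = "depth (mm)",
                 "injected volume (uL)")
  ylab <- switch(object$model,
                 retention = "retained fraction",
                 growth = "growth readout (fold-change)",
                 hypor = "hypoperfused fraction")
  grid <- seq(min(res$x), max(res$x), length.out = 200)
  est <- object$estimates
  curve <- switch(object$model,
    retention = 1 - exp(-est[["beta"]] * grid),
    growth = .growth_predict(grid, est),
    hypor = hypoperfused_fraction_volume(ul_to_um3(grid), est[["margin"]])
  )
  ggplot2::ggplot(res, ggplot2::aes(x = .data$x, y = .data$observed)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(
      data = tibble::tibble(x = grid, y = curve),
      ggplot2::aes(x = .data$x, y = .data$y),
      colour = "#b2182b"
    ) +
    ggplot2::labs(x = xlab, y = ylab,
                  title = sprintf("%s model fit (R² = %.3f)",
                                  object$model, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot an injection plan
#'
#' Bolus volumes by depth; predicted per-step retention is mapped to colour
#' when present (after [plan_report()]).
#'
#' @param object An `injection_plan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.injection_plan <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$depth_mm,
                                        y = .data$volume_nl))
  p <- if ("retention" %in% names(df)) {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$retention), width = 0.05)
  } else {
    p + ggplot2::geom_col(width = 0.05)
  }
  p +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "depth (mm, deep → shallow)",
                  y = "bolus volume (nL)",
                  title = sprintf("injection schedule (%g nL total)",
                                  attr(object, "total_nl"))) +
    ggplot2::theme_minimal()
}

#' Plot a parameter sensitivity sweep
#'
#' One panel per swept parameter, predicted curves coloured by multiplier.
#'
#' @param sweep Output of [sensitivity_sweep()].
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(sweep) {
  stopifnot(is.data.frame(sweep),
            all(c("parameter", "multiplier", "x", "value") %in% names(sweep)))
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$x, y = .data$value,
                                      colour = factor(.data$multiplier),
                                      group = .data$multiplier)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$parameter)) +
    ggplot2::labs(x = unique(sweep$x_unit)[1], y = "prediction",
                  colour = "multiplier") +
    ggplot2::theme_minimal()
}

#' Plot peri-graft recruitment and calcium dynamics
#'
#' Combines the per-day in-region cell count with the mean normalized
#' peri-graft and distal calcium signal, the standard summary of
#' graft-interface dynamics.
#'
#' @param counts Output of [count_within_radius()].
#' @param calcium Optional tibble with columns `day`, `label`,
#'   `normalized` (e.g. normalized traces joined with proximity labels),
#'   summarised to group means.
#' @return A ggplot object.
#' @export
plot_graft_dynamics <- function(counts, calcium = NULL) {
  p <- ggplot2::ggplot(counts, ggplot2::aes(x = .data$day,
                                            y = .data$n_peri)) +
    ggplot2::geom_line(colour = "#1b7837") +
    ggplot2::geom_point(colour = "#1b7837") +
    ggplot2::labs(x = "day post-transplantation",
                  y = "cells within graft region") +
    ggplot2::theme_minimal()
  if (!is.null(calcium)) {
    means <- calcium |>
      dplyr::group_by(.data$day, .data$label) |>
      dplyr::summarise(mean_norm = mean(.data$normalized), .groups = "drop")
    scale <- max(counts$n_peri) / max(means$mean_norm)
    p <- p +
      ggplot2::geom_line(
        data = means,
        ggplot2::aes(x = .data$day, y = .data$mean_norm * scale,
                     colour = .data$label)
      ) +
      ggplot2::scale_y_continuous(
        sec.axis = ggplot2::sec_axis(~ . / scale,
                                     name = "mean normalized calcium")
      ) +
      ggplot2::labs(colour = NULL)
  }
  p
}
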