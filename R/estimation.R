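#' Fitting configuration
#'
#' Controls the bounded least-squares fits and the site-resampled bootstrap.
#' All randomness in fitting flows from `seed`; no global RNG state is used.
#'
#' @param n_boot Number of nonparametric bootstrap resamples (default 1000).
#' @param ci_level Confidence level for percentile intervals (default 0.95).
#' @param seed Integer seed owned by this configuration.
#' @param bounds Named list of `[lo, hi]` parameter bounds. Defaults:
#'   beta in [0, 50] per mm, gamma in [1e-3, 20], g_max in (0, 1e6],
#'   margin in [1, 2000] um.
#' @param gamma_mode `"fixed:<value>"` (default `"fixed:3"`) or `"free"`.
#' @param gmax_mode `"free"` (default) or `"fixed:<value>"`.
#' @param margin_mode `"fixed:<value>"` (default `"fixed:100"`) or `"free"`;
#'   used when fitting hypoperfused-fraction readouts directly.
#' @param n_grid Number of log-spaced evaluation points used to bracket the
#'   optimum before local refinement (guards against local minima).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_boot = 1000, ci_level = 0.95, seed = 1L,
                       bounds = list(), gamma_mode = "fixed:3",
                       gmax_mode = "free", margin_mode = "fixed:100",
                       n_grid = 60) {
  stopifnot(n_boot >= 1, ci_level > 0, ci_level < 1, n_grid >= 8)
  default_bounds <- list(beta = c(0, 50), gamma = c(1e-3, 20),
                         g_max = c(1e-9, 1e6), margin = c(1, 2000))
  for (nm in names(bounds)) default_bounds[[nm]] <- bounds[[nm]]
  structure(
    list(n_boot = as.integer(n_boot), ci_level = ci_level,
         seed = as.integer(seed), bounds = default_bounds,
         gamma_mode = gamma_mode, gmax_mode = gmax_mode,
         margin_mode = margin_mode, n_grid = as.integer(n_grid)),
    class = "fit_config"
  )
}

# parse "fixed:3" / "free" / numeric into list(free, value)
.parse_mode <- function(mode, what) {
  if (is.numeric(mode)) return(list(free = FALSE, value = mode))
  if (identical(mode, "free")) return(list(free = TRUE, value = NA_real_))
  if (grepl("^fixed:", mode)) {
    return(list(free = FALSE, value = as.numeric(sub("^fixed:", "", mode))))
  }
  stop(sprintf("cannot parse %s mode '%s'", what, mode), call. = FALSE)
}

#' Goodness-of-fit metrics
#'
#' Coefficient of determination (about the observed mean), mean absolute
#' error and root-mean-square error, all in observation units.
#' When the observations have zero variance, R^2 is undefined unless the
#' residuals are all zero; the undefined case is reported as `NA`.
#'
#' @param observed,predicted Numeric vectors of equal length >= 2.
#' @return A one-row tibble with columns `r_squared`, `mae`, `rmse`.
#' @examples
#' goodness_of_fit(c(1, 2, 3), c(1, 2, 4))
#' @export
goodness_of_fit <- function(observed, predicted) {
  stopifnot(is.numeric(observed), is.numeric(predicted),
            length(observed) == length(predicted), length(observed) >= 2)
  res <- observed - predicted
  ss_res <- sum(res^2)
  ss_tot <- sum((observed - mean(observed))^2)
  r2 <- if (ss_tot == 0) {
    if (ss_res == 0) 1 else NA_real_
  } else {
    1 - ss_res / ss_tot
  }
  tibble::tibble(r_squared = r2, mae = mean(abs(res)),
                 rmse = sqrt(mean(res^2)))
}

# cache of permutation matrices for the exact Spearman test
.perm_cache <- new.env(parent = emptyenv())

.all_perms <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  p <- matrix(1L, 1, 1)
  if (n > 1) {
    for (k in 2:n) {
      blocks <- vector("list", k)
      for (pos in 1:k) {
        left <- if (pos > 1) p[, seq_len(pos - 1), drop = FALSE] else NULL
        right <- if (pos <= k - 1) p[, pos:(k - 1), drop = FALSE] else NULL
        blocks[[pos]] <- cbind(left, k, right)
      }
      p <- do.call(rbind, blocks)
    }
  }
  .perm_cache[[key]] <- p
  p
}

#' Spearman trend test on residuals
#'
#' Tests residuals for a monotone trend in a predictor (depth or volume)
#' using the Spearman rank correlation with average ranks for ties. P-values
#' use the exact permutation distribution for n < 10 and the large-sample t
#' approximation otherwise; typical calibration designs have 4-27 sites.
#' Constant residuals (or predictor) give rho = 0 and are never flagged.
#'
#' @param residuals Numeric vector of fit residuals (or a fitted model object
#'   from [fit_retention()] / [fit_growth()], whose residual table is used).
#' @param predictor Numeric vector of the same length (ignored when
#'   `residuals` is a fit object).
#' @param alpha Flagging threshold on the two-sided p-value (default 0.05).
#' @return A one-row tibble with `spearman_rho`, `p_value`, `flagged`.
#' @export
residual_trend <- function(residuals, predictor = NULL, alpha = 0.05) {
  if (inherits(residuals, "graftkit_fit")) {
    predictor <- residuals$residuals$x
    residuals <- residuals$residuals$residual
  }
  stopifnot(is.numeric(residuals), is.numeric(predictor),
            length(residuals) == length(predictor))
  n <- length(residuals)
  if (n < 3) stop("need at least 3 residuals for a trend test", call. = FALSE)
  # residual variation at floating-point noise level (well below any
  # measurable fraction) is treated as constant, not as a trend
  if (stats::sd(residuals) < 1e-8 || stats::sd(predictor) == 0) {
    return(tibble::tibble(spearman_rho = 0, p_value = 1, flagged = FALSE))
  }
  rr <- rank(residuals)
  rp <- rank(predictor)
  rho <- stats::cor(rr, rp)
  p <- if (n < 10) {
    perms <- .all_perms(n)
    rc <- rr - mean(rr)
    pc <- rp - mean(rp)
    num <- matrix(rc[perms], nrow = nrow(perms)) %*% pc
    rho_perm <- as.numeric(num) / sqrt(sum(rc^2) * sum(pc^2))
    mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1) {
    0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(spearman_rho = rho, p_value = p, flagged = p < alpha)
}

# ---- internal optimizer primitives -----------------------------------------

# 1-D bounded minimization: coarse log-spaced grid bracket + local refinement
.minimize_1d <- function(f, lower, upper, n_grid = 60) {
  lo_pos <- max(lower, upper * 1e-8)
  grid <- unique(c(lower, exp(seq(log(lo_pos), log(upper), length.out = n_grid))))
  vals <- vapply(grid, f, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  if (lo == hi) return(list(par = lo, value = vals[i]))
  opt <- stats::optimize(f, lower = lo, upper = hi,
                         tol = .Machine$double.eps^0.5)
  if (opt$objective <= vals[i]) {
    list(par = opt$minimum, value = opt$objective)
  } else {
    list(par = grid[i], value = vals[i])
  }
}

# fast refinement used inside bootstrap refits (bracket from the full fit)
.refit_1d <- function(f, lower, upper) {
  opt <- stats::optimize(f, lower = lower, upper = upper,
                         tol = .Machine$double.eps^0.4)
  opt$minimum
}

# ---- data preparation ------------------------------------------------------

.prepare_retention <- function(data, reference = NULL) {
  stopifnot(is.data.frame(data))
  if (!all(c("depth_mm", "value") %in% names(data))) {
    stop("retention data needs columns `depth_mm` and `value`", call. = FALSE)
  }
  df <- tibble::as_tibble(data)
  if (!"site_id" %in% names(df)) df$site_id <- seq_len(nrow(df))
  if (!"qc_pass" %in% names(df)) df$qc_pass <- TRUE
  if (!"value_kind" %in% names(df)) df$value_kind <- "fraction"
  n_read <- nrow(df)
  df <- dplyr::filter(df, .data$qc_pass)
  n_qc <- n_read - nrow(df)
  ref_rows <- df$value_kind == "reference"
  signal_rows <- df$value_kind == "signal"
  if (any(signal_rows)) {
    ref_value <- if (!is.null(reference)) {
      reference
    } else if (any(ref_rows)) {
      mean(df$value[ref_rows])
    } else {
      stop(paste("signal-mode observations require a delivered-dose",
                 "reference: pass `reference` or include value_kind",
                 "'reference' rows"), call. = FALSE)
    }
    if (!is.numeric(ref_value) || ref_value <= 0) {
      stop("reference signal must be a positive number", call. = FALSE)
    }
    df$value[signal_rows] <- df$value[signal_rows] / ref_value
  }
  df <- df[!ref_rows, , drop = FALSE]
  if (nrow(df) == 0) stop("no observations pass QC", call. = FALSE)
  if (any(df$value < 0 | df$value > 1)) {
    stop("retained fractions must lie in [0, 1] after normalization",
         call. = FALSE)
  }
  if (length(unique(df$depth_mm)) < 2) {
    stop("ill-posed fit: need observations at >= 2 distinct depths",
         call. = FALSE)
  }
  attr(df, "n_excluded_qc") <- n_qc
  df
}

.prepare_growth <- function(data, readout_kind = NULL) {
  stopifnot(is.data.frame(data))
  if (!all(c("volume_ul", "value") %in% names(data))) {
    stop("growth data needs columns `volume_ul` and `value`", call. = FALSE)
  }
  df <- tibble::as_tibble(data)
  if (!"site_id" %in% names(df)) df$site_id <- seq_len(nrow(df))
  if (!"qc_pass" %in% names(df)) df$qc_pass <- TRUE
  df <- dplyr::filter(df, .data$qc_pass)
  if (nrow(df) == 0) stop("no observations pass QC", call. = FALSE)
  kind <- if (!is.null(readout_kind)) {
    readout_kind
  } else if ("readout_kind" %in% names(df)) {
    k <- unique(df$readout_kind)
    if (length(k) != 1) {
      stop("readout_kind must be homogeneous within one fit", call. = FALSE)
    }
    k
  } else {
    "growth"
  }
  kind <- match.arg(kind, c("growth", "hypor"))
  if (any(df$volume_ul <= 0)) {
    stop("volumes must be strictly positive", call. = FALSE)
  }
  if (kind == "hypor" && any(df$value < 0 | df$value > 1)) {
    stop("hypoperfused-fraction readouts must lie in [0, 1]", call. = FALSE)
  }
  if (length(unique(df$volume_ul)) < 2) {
    stop("ill-posed fit: need observations at >= 2 distinct volumes",
         call. = FALSE)
  }
  attr(df, "readout_kind") <- kind
  df
}

# ---- point estimation ------------------------------------------------------

.fit_retention_point <- function(depth, value, cfg) {
  ssr <- function(beta) sum((value - (1 - exp(-beta * depth)))^2)
  b <- cfg$bounds$beta
  opt <- .minimize_1d(ssr, b[1], b[2], cfg$n_grid)
  list(estimates = c(beta = opt$par), flags = character())
}

# profiled growth fit: for fixed gamma the optimal g_max is linear LS
.fit_growth_point <- function(volume_ul, value, cfg) {
  gamma_mode <- .parse_mode(cfg$gamma_mode, "gamma")
  gmax_mode <- .parse_mode(cfg$gmax_mode, "g_max")
  hyp <- hypoperfused_fraction_volume(ul_to_um3(volume_ul), 100)
  flags <- character()
  gb <- cfg$bounds$gamma
  mb <- cfg$bounds$g_max

  if (all(hyp == 0)) {
    # flat model below the threshold volume: gamma drops out entirely
    gmax <- if (gmax_mode$free) mean(value) else gmax_mode$value
    est <- c(g_max = gmax,
             gamma = if (gamma_mode$free) NA_real_ else gamma_mode$value)
    flags <- c(flags, "gamma_unidentifiable")
    return(list(estimates = est, flags = flags))
  }

  base <- 1 - hyp
  gmax_for <- function(gamma) {
    b <- base^gamma
    if (gmax_mode$free) {
      g <- sum(value * b) / sum(b^2)
      min(max(g, mb[1]), mb[2])
    } else {
      gmax_mode$value
    }
  }
  ssr_gamma <- function(gamma) {
    g <- gmax_for(gamma)
    sum((value - g * base^gamma)^2)
  }
  if (gamma_mode$free) {
    opt <- .minimize_1d(ssr_gamma, gb[1], gb[2], cfg$n_grid)
    gamma_hat <- opt$par
    if (gamma_hat <= gb[1] * (1 + 1e-6) || gamma_hat >= gb[2] * (1 - 1e-6)) {
      flags <- c(flags, "gamma_at_bound")
    }
  } else {
    gamma_hat <- gamma_mode$value
  }
  list(estimates = c(g_max = gmax_for(gamma_hat), gamma = gamma_hat),
       flags = flags)
}

.growth_predict <- function(volume_ul, est) {
  gamma <- if (is.na(est[["gamma"]])) 0 else est[["gamma"]]
  est[["g_max"]] *
    (1 - hypoperfused_fraction_volume(ul_to_um3(volume_ul), 100))^gamma
}

.fit_hypor_point <- function(volume_ul, value, cfg) {
  margin_mode <- .parse_mode(cfg$margin_mode, "margin")
  flags <- character()
  v_um3 <- ul_to_um3(volume_ul)
  if (margin_mode$free) {
    ssr <- function(margin) {
      sum((value - hypoperfused_fraction_volume(v_um3, margin))^2)
    }
    b <- cfg$bounds$margin
    opt <- .minimize_1d(ssr, b[1], b[2], cfg$n_grid)
    margin_hat <- opt$par
  } else {
    margin_hat <- margin_mode$value
  }
  list(estimates = c(margin = margin_hat), flags = flags)
}

# ---- bootstrap -------------------------------------------------------------

# site (row) resampling, stratified by the design variable when every
# stratum has >= 2 rows
.bootstrap_indices <- function(group, n_boot, seed) {
  n <- length(group)
  strata <- split(seq_len(n), group)
  stratified <- all(vapply(strata, length, integer(1)) >= 2)
  withr::with_seed(seed, {
    if (stratified) {
      lapply(seq_len(n_boot), function(i) {
        unlist(lapply(strata, function(ix) {
          ix[sample.int(length(ix), length(ix), replace = TRUE)]
        }), use.names = FALSE)
      })
    } else {
      lapply(seq_len(n_boot), function(i) {
        sample.int(n, n, replace = TRUE)
      })
    }
  })
}

.bootstrap_ci <- function(x, group, refit, est, cfg) {
  idx <- .bootstrap_indices(group, cfg$n_boot, cfg$seed)
  draws <- matrix(NA_real_, nrow = cfg$n_boot, ncol = length(est),
                  dimnames = list(NULL, names(est)))
  n_fail <- 0L
  for (i in seq_len(cfg$n_boot)) {
    d <- tryCatch(refit(idx[[i]]), error = function(e) NULL)
    if (is.null(d)) n_fail <- n_fail + 1L else draws[i, ] <- d[names(est)]
  }
  if (n_fail > 0.2 * cfg$n_boot) {
    stop(sprintf(
      "bootstrap unstable: %d of %d resample fits failed (limit 20%%)",
      n_fail, cfg$n_boot), call. = FALSE)
  }
  a <- (1 - cfg$ci_level) / 2
  ci <- tibble::tibble(
    term = names(est),
    lower = unname(vapply(names(est), function(p) {
      .perc_quantile(draws[, p], a)
    }, numeric(1))),
    upper = unname(vapply(names(est), function(p) {
      .perc_quantile(draws[, p], 1 - a)
    }, numeric(1)))
  )
  list(ci = ci, draws = draws, n_fail = n_fail)
}

# canonical bootstrap percentile quantile: the (R+1)*alpha order statistic,
# interpolated on the normal-quantile scale (the boot::boot.ci convention)
.perc_quantile <- function(t, alpha) {
  t <- sort(t[is.finite(t)])
  R <- length(t)
  if (R == 0) return(NA_real_)
  rk <- (R + 1) * alpha
  if (rk <= 1) return(t[1])
  if (rk >= R) return(t[R])
  k <- trunc(rk)
  if (t[k] == t[k + 1]) return(t[k])
  frac <- (stats::qnorm(alpha) - stats::qnorm(k / (R + 1))) /
    (stats::qnorm((k + 1) / (R + 1)) - stats::qnorm(k / (R + 1)))
  t[k] + frac * (t[k + 1] - t[k])
}

# ---- fit result assembly ---------------------------------------------------

.make_fit <- function(model, df, x, observed, predicted, estimates, flags,
                      boot, cfg) {
  gof <- goodness_of_fit(observed, predicted)
  residuals <- tibble::tibble(
    site_id = df$site_id, x = x, observed = observed,
    predicted = predicted, residual = observed - predicted
  )
  trend <- residual_trend(residuals$residual, x)
  structure(
    list(
      model = model,
      estimates = estimates,
      ci = boot$ci,
      boot_draws = boot$draws,
      boot_failures = boot$n_fail,
      r_squared = gof$r_squared, mae = gof$mae, rmse = gof$rmse,
      residuals = residuals,
      trend = trend,
      n_sites = nrow(df),
      n_excluded_qc = attr(df, "n_excluded_qc") %||% 0L,
      converged = TRUE,
      flags = flags,
      config = cfg
    ),
    class = "graftkit_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the retention-versus-depth model
#'
#' Estimates beta in \eqn{R(d) = 1 - e^{-\beta d}} by bounded nonlinear least
#' squares on site-level retained fractions, with percentile confidence
#' intervals from a nonparametric bootstrap that resamples sites (stratified
#' by depth group when every group has at least two sites). Goodness of fit
#' (R^2, MAE, RMSE) and a Spearman residual-trend diagnostic are reported.
#'
#' @param data Data frame with columns `depth_mm` and `value`, and optionally
#'   `site_id`, `qc_pass` (logical; failing sites are excluded as-is, no
#'   automatic outlier rejection) and `value_kind` (`"fraction"` (default),
#'   `"signal"` for raw imaging readouts, or `"reference"` for delivered-dose
#'   reference rows used to normalize signals).
#' @param config A [fit_config()].
#' @param bootstrap Compute bootstrap confidence intervals (default TRUE).
#' @param reference Optional positive scalar: delivered-dose reference signal
#'   for `value_kind == "signal"` rows (overrides in-table reference rows).
#' @return A `graftkit_fit` object; see [tidy.graftkit_fit()] and
#'   [glance.graftkit_fit()] for tabular summaries.
#' @examples
#' obs <- simulate_retention(retention_sim_spec(beta_true = 0.4, sigma = 0,
#'                                              seed = 1))
#' fit <- fit_retention(obs, fit_config(n_boot = 50))
#' tidy(fit)
#' @export
fit_retention <- function(data, config = fit_config(), bootstrap = TRUE,
                          reference = NULL) {
  stopifnot(inherits(config, "fit_config"))
  df <- .prepare_retention(data, reference)
  pt <- .fit_retention_point(df$depth_mm, df$value, config)
  est <- pt$estimates
  boot <- list(ci = tibble::tibble(term = names(est), lower = NA_real_,
                                   upper = NA_real_),
               draws = NULL, n_fail = 0L)
  if (bootstrap) {
    b <- config$bounds$beta
    refit <- function(ix) {
      d <- df$depth_mm[ix]; v <- df$value[ix]
      if (length(unique(d)) < 2) stop("degenerate resample")
      beta <- .refit_1d(function(beta) sum((v - (1 - exp(-beta * d)))^2),
                        b[1], b[2])
      c(beta = beta)
    }
    boot <- .bootstrap_ci(df$value, df$depth_mm, refit, est, config)
  }
  predicted <- 1 - exp(-est[["beta"]] * df$depth_mm)
  .make_fit("retention", df, df$depth_mm, df$value, predicted, est,
            pt$flags, boot, config)
}

#' Fit the hypoperfusion-limited growth model
#'
#' For growth readouts, fits \eqn{G(v) = G_{max}(1 - HypoR(v))^\gamma} with
#' Gmax and/or gamma free according to the configuration (for fixed gamma the
#' optimal Gmax has a closed form; free gamma is profiled and refined over a
#' log-spaced bracket). For hypoperfused-fraction readouts, fits HypoR(v)
#' directly with the oxygenated margin fixed or free. When every observed
#' volume lies at or below the threshold volume the model is flat: Gmax is
#' the mean readout and gamma is reported unidentifiable.
#'
#' @param data Data frame with columns `volume_ul` and `value`, optionally
#'   `site_id`, `qc_pass`, `readout_kind` (all `"growth"` or all `"hypor"`).
#' @param config A [fit_config()]; `gamma_mode`, `gmax_mode` and
#'   `margin_mode` select which parameters are free.
#' @param bootstrap Compute bootstrap confidence intervals (default TRUE).
#' @param readout_kind Override for the readout kind; defaults to the
#'   `readout_kind` column or `"growth"`.
#' @return A `graftkit_fit` object.
#' @examples
#' obs <- simulate_growth(growth_sim_spec(g_max_true = 2, sigma_log = 0,
#'                                        seed = 1))
#' fit <- fit_growth(obs, fit_config(n_boot = 50, gamma_mode = "free"))
#' glance(fit)
#' @export
fit_growth <- function(data, config = fit_config(), bootstrap = TRUE,
                       readout_kind = NULL) {
  stopifnot(inherits(config, "fit_config"))
  df <- .prepare_growth(data, readout_kind)
  kind <- attr(df, "readout_kind")
  if (kind == "growth") {
    pt <- .fit_growth_point(df$volume_ul, df$value, config)
    est <- pt$estimates
    predicted <- .growth_predict(df$volume_ul, est)
    refit <- function(ix) {
      v <- df$volume_ul[ix]; y <- df$value[ix]
      if (length(unique(v)) < 2) stop("degenerate resample")
      .fit_growth_point(v, y, config)$estimates
    }
    model <- "growth"
  } else {
    pt <- .fit_hypor_point(df$volume_ul, df$value, config)
    est <- pt$estimates
    predicted <- hypoperfused_fraction_volume(ul_to_um3(df$volume_ul),
                                              est[["margin"]])
    refit <- function(ix) {
      v <- df$volume_ul[ix]; y <- df$value[ix]
      if (length(unique(v)) < 2) stop("degenerate resample")
      .fit_hypor_point(v, y, config)$estimates
    }
    model <- "hypor"
  }
  boot <- list(ci = tibble::tibble(term = names(est), lower = NA_real_,
                                   upper = NA_real_),
               draws = NULL, n_fail = 0L)
  free_terms <- names(est)[!is.na(est)]
  if (bootstrap && length(free_terms) > 0) {
    boot <- .bootstrap_ci(df$value, df$volume_ul, refit, est, config)
  }
  .make_fit(model, df, df$volume_ul, df$value, predicted, est, pt$flags,
            boot, config)
}

#' Bootstrap percentile confidence intervals for a dose-model fit
#'
#' Thin wrapper that fits the requested model and returns only the percentile
#' confidence intervals from the site-resampled bootstrap.
#'
#' @param data Observation table (see [fit_retention()] / [fit_growth()]).
#' @param model `"retention"` or `"growth"`.
#' @param config A [fit_config()].
#' @return A tibble with columns `term`, `lower`, `upper`.
#' @export
bootstrap_ci <- function(data, model = c("retention", "growth"),
                         config = fit_config()) {
  model <- match.arg(model)
  fit <- switch(model,
                retention = fit_retention(data, config, bootstrap = TRUE),
                growth = fit_growth(data, config, bootstrap = TRUE))
  fit$ci
}

#' @export
print.graftkit_fit <- function(x, ...) {
  cat(sprintf("<graftkit_fit: %s model, %d sites>\n", x$model, x$n_sites))
  est <- x$estimates
  for (p in names(est)) {
    ci <- x$ci[x$ci$term == p, ]
    cat(sprintf("  %-7s %.5g", p, est[[p]]))
    if (nrow(ci) == 1 && !is.na(ci$lower)) {
      cat(sprintf("  [%.5g, %.5g]", ci$lower, ci$upper))
    }
    cat("\n")
  }
  cat(sprintf("  R^2 %.4f | MAE %.4g | RMSE %.4g\n",
              x$r_squared, x$mae, x$rmse))
  cat(sprintf("  residual trend: rho %.3f (p = %.3g)%s\n",
              x$trend$spearman_rho, x$trend$p_value,
              if (x$trend$flagged) " FLAGGED" else ""))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Compare growth-exponent candidates
#'
#' Fits the growth model under each candidate exponent specification (for
#' example fixed gamma = 1, 2, 3 and the free-gamma model) and ranks the
#' fits by RMSE, breaking ties first by the absence of a residual trend and
#' then by the number of free parameters. The `preferred` column marks the
#' simplest un-flagged model (fewest free parameters, RMSE tie-break) —
#' the model-retention rule "keep the simplest model whose residuals show no
#' volume dependence".
#'
#' @param data Growth observation table (see [fit_growth()]).
#' @param candidates Character vector of gamma modes, e.g.
#'   `c("fixed:1", "fixed:2", "fixed:3", "free")`.
#' @param config A [fit_config()]; its `gamma_mode` is overridden per
#'   candidate. Candidate fits skip the bootstrap for speed.
#' @return A tibble with one row per candidate, ordered by rank, carrying the
#'   fit objects in a `fit` list-column. Candidates whose fits error are
#'   retained with the error message and rank last.
#' @export
model_selection_gamma <- function(data,
                                  candidates = c("fixed:1", "fixed:2",
                                                 "fixed:3", "free"),
                                  config = fit_config()) {
  stopifnot(length(candidates) >= 1)
  rows <- purrr::map(candidates, function(cand) {
    cfg <- config
    cfg$gamma_mode <- cand
    fit <- tryCatch(fit_growth(data, cfg, bootstrap = FALSE),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      tibble::tibble(candidate = cand, gamma = NA_real_, g_max = NA_real_,
                     rmse = NA_real_, r_squared = NA_real_,
                     trend_flagged = NA, n_free = NA_integer_,
                     error = conditionMessage(fit), fit = list(NULL))
    } else {
      mode <- .parse_mode(cand, "gamma")
      gmax_free <- .parse_mode(cfg$gmax_mode, "g_max")$free
      tibble::tibble(
        candidate = cand,
        gamma = unname(fit$estimates["gamma"]),
        g_max = unname(fit$estimates["g_max"]),
        rmse = fit$rmse, r_squared = fit$r_squared,
        trend_flagged = fit$trend$flagged,
        n_free = sum(mode$free, gmax_free),
        error = NA_character_, fit = list(fit)
      )
    }
  })
  out <- dplyr::bind_rows(rows)
  # collapse RMSE ties within floating noise so a fixed-gamma exact fit
  # outranks a free-gamma fit that matches it only to optimizer tolerance
  rmse_ok <- out$rmse[!is.na(out$rmse)]
  tol <- if (length(rmse_ok)) 1e-8 + 1e-6 * min(rmse_ok) else 0
  rmse_grp <- if (length(rmse_ok)) {
    vapply(out$rmse, function(r) {
      if (is.na(r)) Inf else min(rmse_ok[abs(rmse_ok - r) <= tol])
    }, numeric(1))
  } else {
    rep(Inf, nrow(out))
  }
  ord <- order(rmse_grp, out$trend_flagged, out$n_free,
               seq_len(nrow(out)))
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  eligible <- !is.na(out$rmse) & !out$trend_flagged
  out$preferred <- FALSE
  if (any(eligible)) {
    cand <- which(eligible)
    cand <- cand[order(out$n_free[cand], rmse_grp[ord][cand])]
    out$preferred[cand[1]] <- TRUE
  }
  out
}

#' Parameter sensitivity sweep
#'
#' Scales each model parameter through multipliers spanning
#' `[1 - fraction, 1 + fraction]` (default +/-20%) and evaluates the
#' predicted curve over a grid, returning a long plot-ready table for
#' robustness visualization.
#'
#' @param model A [retention_model()], [growth_model()], or a fitted
#'   `graftkit_fit` (the point estimates are swept).
#' @param fraction Half-width of the relative sweep (default 0.20).
#' @param n_points Number of multipliers, including 1 when odd (default 5).
#' @param grid Evaluation grid: depths in mm (retention) or volumes in nL
#'   (growth). Sensible defaults cover the calibration designs.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `multiplier`, `x`, `x_unit`,
#'   `value`.
#' @examples
#' sensitivity_sweep(retention_model(0.24), grid = c(0.5, 1.5, 3))
#' @export
sensitivity_sweep <- function(model, fraction = 0.20, n_points = 5,
                              grid = NULL, ...) {
  UseMethod("sensitivity_sweep")
}

.sweep_table <- function(params, fraction, n_points, grid, x_unit, predict) {
  mult <- seq(1 - fraction, 1 + fraction, length.out = n_points)
  purrr::map_dfr(names(params), function(p) {
    purrr::map_dfr(mult, function(m) {
      scaled <- params
      scaled[[p]] <- scaled[[p]] * m
      tibble::tibble(parameter = p, multiplier = m, x = grid,
                     x_unit = x_unit, value = predict(scaled))
    })
  })
}

#' @rdname sensitivity_sweep
#' @export
sensitivity_sweep.retention_model <- function(model, fraction = 0.20,
                                              n_points = 5, grid = NULL,
                                              ...) {
  if (is.null(grid)) grid <- seq(0, 5, by = 0.25)
  .sweep_table(list(beta = model$beta), fraction, n_points, grid, "depth_mm",
               function(p) 1 - exp(-p$beta * grid^model$n))
}

#' @rdname sensitivity_sweep
#' @export
sensitivity_sweep.growth_model <- function(model, fraction = 0.20,
                                           n_points = 5, grid = NULL, ...) {
  if (is.null(grid)) grid <- c(1, 2, 4.2, 10, 25, 100, 250, 500, 1000)
  .sweep_table(
    list(g_max = model$g_max, gamma = model$gamma, margin = model$margin),
    fraction, n_points, grid, "volume_nl",
    function(p) {
      p$g_max *
        (1 - hypoperfused_fraction_volume(nl_to_um3(grid), p$margin))^p$gamma
    }
  )
}

#' @rdname sensitivity_sweep
#' @export
sensitivity_sweep.graftkit_fit <- function(model, fraction = 0.20,
                                           n_points = 5, grid = NULL, ...) {
  est <- model$estimates
  m <- switch(model$model,
    retention = retention_model(est[["beta"]]),
    growth = growth_model(est[["g_max"]],
                          if (is.na(est[["gamma"]])) 3 else est[["gamma"]]),
    stop("sensitivity sweep not defined for model '", model$model, "'",
         call. = FALSE)
  )
  sensitivity_sweep(m, fraction = fraction, n_points = n_points, grid = grid)
}
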