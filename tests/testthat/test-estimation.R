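test_that("goodness-of-fit metrics match hand computations", {
  g <- goodness_of_fit(c(1, 2, 3), c(1, 2, 3))
  expect_equal(g$r_squared, 1)
  expect_equal(g$mae, 0)
  expect_equal(g$rmse, 0)

  g <- goodness_of_fit(c(0, 1), c(0.5, 0.5))
  expect_equal(g$r_squared, 0)
  expect_equal(g$mae, 0.5)
  expect_equal(g$rmse, 0.5)

  g <- goodness_of_fit(c(1, 2, 3), c(1, 2, 4))
  expect_equal(g$r_squared, 0.5)
  expect_equal(g$mae, 1 / 3)
  expect_equal(g$rmse, 1 / sqrt(3))

  # zero observed variance with nonzero residuals: undefined, not -Inf
  expect_true(is.na(goodness_of_fit(c(2, 2, 2), c(1, 2, 3))$r_squared))
  expect_equal(goodness_of_fit(c(2, 2, 2), c(2, 2, 2))$r_squared, 1)
})

test_that("residual trend test matches rank computations and cor.test", {
  t1 <- residual_trend(c(1, 2, 3), c(1, 2, 3))
  expect_equal(t1$spearman_rho, 1)

  t2 <- residual_trend(c(3, 1, 2), c(1, 2, 3))
  expect_equal(t2$spearman_rho, -0.5)

  t3 <- residual_trend(c(0, 0, 0, 0), c(1, 2, 3, 4))
  expect_equal(t3$spearman_rho, 0)
  expect_false(t3$flagged)

  # exact permutation p agrees with cor.test's exact Spearman test (no ties)
  withr::with_seed(5, {
    for (n in c(5, 7, 9)) {
      r <- rnorm(n); p <- rnorm(n)
      mine <- residual_trend(r, p)
      ref <- suppressWarnings(cor.test(r, p, method = "spearman",
                                       exact = TRUE))
      expect_equal(mine$spearman_rho, unname(ref$estimate), tolerance = 1e-12)
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    }
  })
  # large-sample branch agrees with cor.test's t approximation
  withr::with_seed(6, {
    r <- rnorm(20); p <- r + rnorm(20)
    mine <- residual_trend(r, p)
    ref <- cor.test(r, p, method = "spearman", exact = FALSE)
    expect_equal(mine$spearman_rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  })
  expect_error(residual_trend(c(1, 2), c(1, 2)), "at least 3")
})

test_that("noiseless retention data is recovered exactly", {
  obs <- exact_retention_obs(beta = 0.4)
  fit <- fit_retention(obs, fit_config(n_boot = 25, seed = 3))
  expect_equal(unname(fit$estimates["beta"]), 0.4, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$mae, 0, tolerance = 1e-8)
  expect_equal(fit$rmse, 0, tolerance = 1e-8)
  expect_true(all(abs(fit$residuals$residual) < 1e-7))
  expect_false(fit$trend$flagged)
  # every resample refits identically: degenerate interval at the estimate
  expect_equal(fit$ci$lower, fit$ci$upper, tolerance = 1e-6)
  expect_equal(fit$ci$lower, 0.4, tolerance = 1e-5)
})

test_that("NLS optimum matches an exhaustive grid search", {
  obs <- simulate_retention(retention_sim_spec(beta_true = 0.24,
                                               sigma = 0.05, seed = 42))
  fit <- fit_retention(obs, bootstrap = FALSE)
  grid <- seq(0, 2, by = 1e-4)
  d <- obs$depth_mm[obs$value_kind == "fraction"]
  y <- obs$value[obs$value_kind == "fraction"]
  ssr <- vapply(grid, function(b) sum((y - (1 - exp(-b * d)))^2), numeric(1))
  expect_lt(abs(unname(fit$estimates["beta"]) - grid[which.min(ssr)]),
            1e-4 + 1e-9)
})

test_that("retention fitting handles QC flags, signal mode and bad input", {
  obs <- exact_retention_obs(beta = 0.3)
  # signal mode with reference rows: signals are model fractions x 1e5
  sig <- obs
  sig$value <- sig$value * 1e5
  sig$value_kind <- "signal"
  ref <- tibble::tibble(site_id = 100:103, depth_mm = NA, value = 1e5,
                        value_kind = "reference")
  fit <- fit_retention(dplyr::bind_rows(sig, ref), bootstrap = FALSE)
  expect_equal(unname(fit$estimates["beta"]), 0.3, tolerance = 1e-6)
  # explicit reference argument overrides
  fit2 <- fit_retention(sig, bootstrap = FALSE, reference = 1e5)
  expect_equal(unname(fit2$estimates["beta"]), 0.3, tolerance = 1e-6)
  expect_error(fit_retention(sig, bootstrap = FALSE), "reference")

  # QC-failing rows are excluded as-is
  qc <- obs
  qc$qc_pass <- TRUE
  qc$value[1] <- 0.99
  qc$qc_pass[1] <- FALSE
  fit3 <- fit_retention(qc, bootstrap = FALSE)
  expect_equal(unname(fit3$estimates["beta"]), 0.3, tolerance = 1e-6)
  expect_equal(fit3$n_excluded_qc, 1L)

  one_depth <- tibble::tibble(depth_mm = c(1, 1, 1), value = c(.1, .2, .3))
  expect_error(fit_retention(one_depth, bootstrap = FALSE), "ill-posed")
  none <- tibble::tibble(depth_mm = 1:3, value = c(.1, .2, .3),
                         qc_pass = FALSE)
  expect_error(fit_retention(none, bootstrap = FALSE), "QC")
})

test_that("noiseless growth data recovers both parameters", {
  obs <- exact_growth_obs(g_max = 2, gamma = 3)
  fit <- fit_growth(obs, fit_config(n_boot = 25, seed = 4,
                                    gamma_mode = "free"))
  expect_equal(unname(fit$estimates["g_max"]), 2, tolerance = 1e-5)
  expect_equal(unname(fit$estimates["gamma"]), 3, tolerance = 1e-5)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_false(fit$trend$flagged)
})

test_that("growth below the threshold volume is flat and gamma flagged", {
  obs <- tibble::tibble(volume_ul = rep(c(0.001, 0.002, 0.004), each = 3),
                        value = 1.8)
  fit <- fit_growth(obs, bootstrap = FALSE,
                    config = fit_config(gamma_mode = "free"))
  expect_equal(unname(fit$estimates["g_max"]), 1.8)
  expect_true(is.na(fit$estimates["gamma"]))
  expect_true("gamma_unidentifiable" %in% fit$flags)
})

test_that("hypoperfusion readouts can be fitted directly for the margin", {
  v <- rep(c(0.05, 0.1, 0.25, 0.5, 1.0), each = 2)
  obs <- tibble::tibble(
    volume_ul = v,
    value = hypoperfused_fraction_volume(ul_to_um3(v), margin = 130),
    readout_kind = "hypor"
  )
  fit <- fit_growth(obs, fit_config(margin_mode = "free"), bootstrap = FALSE)
  expect_equal(unname(fit$estimates["margin"]), 130, tolerance = 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("bootstrap intervals are seed-deterministic and match boot.ci's
           percentile convention", {
  obs <- simulate_retention(retention_sim_spec(sigma = 0.05, seed = 9))
  cfg <- fit_config(n_boot = 200, seed = 77)
  f1 <- fit_retention(obs, cfg)
  f2 <- fit_retention(obs, cfg)
  expect_identical(f1$ci, f2$ci)
  expect_true(f1$ci$lower <= f1$estimates["beta"])
  expect_true(f1$ci$upper >= f1$estimates["beta"])

  withr::with_seed(42, {
    draws <- rnorm(999)
    b <- structure(list(t0 = 0, t = matrix(draws), R = 999,
                        sim = "ordinary"),
                   class = "boot")
    ref <- boot::boot.ci(b, type = "perc")$percent[4:5]
    expect_equal(graftkit:::.perc_quantile(draws, 0.025), ref[1],
                 tolerance = 1e-10)
    expect_equal(graftkit:::.perc_quantile(draws, 0.975), ref[2],
                 tolerance = 1e-10)
  })
})

test_that("estimator RMSE is nonincreasing as noise shrinks", {
  rmse_beta <- vapply(c(0.1, 0.05, 0.01), function(sigma) {
    err <- vapply(1:200, function(i) {
      obs <- simulate_retention(retention_sim_spec(
        beta_true = 0.24, sigma = sigma, seed = 5000 + i))
      f <- fit_retention(obs, bootstrap = FALSE)
      unname(f$estimates["beta"]) - 0.24
    }, numeric(1))
    sqrt(mean(err^2))
  }, numeric(1))
  expect_true(all(diff(rmse_beta) <= 0))
})

test_that("gamma model selection ranks the generative exponent first", {
  cfg <- fit_config(seed = 1)
  obs3 <- exact_growth_obs(g_max = 2, gamma = 3)
  sel <- model_selection_gamma(obs3, c("fixed:1", "fixed:2", "fixed:3",
                                       "free"), cfg)
  expect_equal(sel$candidate[1], "fixed:3")
  expect_equal(sel$rmse[1], 0, tolerance = 1e-7)

  obs1 <- exact_growth_obs(g_max = 2, gamma = 1)
  sel1 <- model_selection_gamma(obs1, c("fixed:1", "fixed:3"), cfg)
  expect_equal(sel1$candidate[1], "fixed:1")

  single <- model_selection_gamma(obs3, "fixed:2", cfg)
  expect_equal(nrow(single), 1)
  expect_equal(single$candidate, "fixed:2")

  # noisy data from gamma = 3: generative exponent (or free with gamma-hat
  # in [2, 4]) outranks gamma = 1 by RMSE
  noisy <- simulate_growth(growth_sim_spec(g_max_true = 2, gamma_true = 3,
                                           sigma_log = 0.15, seed = 7))
  seln <- model_selection_gamma(noisy, c("fixed:1", "fixed:3", "free"), cfg)
  rank1 <- seln$rank[seln$candidate == "fixed:1"]
  rank3 <- seln$rank[seln$candidate == "fixed:3"]
  rankf <- seln$rank[seln$candidate == "free"]
  gam_f <- seln$gamma[seln$candidate == "free"]
  expect_true(rank3 < rank1 || (rankf < rank1 && gam_f >= 2 && gam_f <= 4))

  # errors propagate per candidate without aborting the others
  bad <- tibble::tibble(volume_ul = c(1, 1, 1), value = c(1, 1, 1))
  selb <- model_selection_gamma(bad, c("fixed:1", "fixed:3"), cfg)
  expect_true(all(!is.na(selb$error)))
})

test_that("sensitivity sweep brackets the baseline curve", {
  m <- retention_model(0.24)
  sw <- sensitivity_sweep(m, fraction = 0.2, n_points = 5, grid = c(1, 3))
  expect_setequal(unique(sw$multiplier), seq(0.8, 1.2, by = 0.1))
  at3 <- sw[sw$x == 3 & sw$parameter == "beta", ]
  expect_equal(min(at3$value), 1 - exp(-0.576), tolerance = 1e-10)
  expect_equal(max(at3$value), 1 - exp(-0.864), tolerance = 1e-10)
  expect_equal(min(at3$value), 0.4379, tolerance = 1e-4)
  expect_equal(max(at3$value), 0.5785, tolerance = 1e-4)
  # scaling beta up strictly increases retention at positive depth
  base <- at3$value[at3$multiplier == 1]
  expect_true(all(at3$value[at3$multiplier > 1] > base))

  sw0 <- sensitivity_sweep(m, fraction = 0, n_points = 3, grid = c(1, 3))
  expect_equal(length(unique(sw0$value[sw0$x == 3])), 1)

  g <- growth_model(2, 3)
  swg <- sensitivity_sweep(g, grid = c(100, 500))
  expect_setequal(unique(swg$parameter), c("g_max", "gamma", "margin"))
})

test_that("tidy, glance and augment expose the fit in broom style", {
  obs <- simulate_retention(retention_sim_spec(sigma = 0.03, seed = 21))
  fit <- fit_retention(obs, fit_config(n_boot = 50, seed = 8))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "conf.low", "conf.high"))
  expect_true(td$conf.low <= td$estimate & td$estimate <= td$conf.high)
  gl <- glance(fit)
  expect_true(all(c("r.squared", "mae", "rmse", "trend_flagged",
                    "n_sites") %in% names(gl)))
  expect_equal(gl$n_sites, 23L)
  au <- augment(fit)
  expect_equal(nrow(au), 23)
  expect_equal(au$observed - au$predicted, au$residual)
})
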