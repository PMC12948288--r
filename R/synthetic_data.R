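#' Specification for simulated retention-versus-depth experiments
#'
#' Emulates the agarose-gel calibration assay: luciferase-expressing cells
#' injected at fixed depths, retained load read out by bioluminescence, with
#' a delivered-dose reference group. The default design mirrors that assay:
#' depths 0.5/1.5/3.0 mm with 7/8/8 replicate sites plus a 4-site reference
#' group (n = 4,7,8,8 overall).
#'
#' @param beta_true True retention parameter, per mm.
#' @param depths Injection depths, mm.
#' @param n_per_depth Replicate sites per depth (same length as `depths`).
#' @param n_reference Sites in the delivered-dose reference group (no depth;
#'   used for signal normalization, excluded from the depth fit).
#' @param noise `"gaussian_additive"` (on the fraction scale, clamped to
#'   [0, 1]) or `"lognormal_multiplicative"` (heavy-tailed, as photon-count
#'   signals are).
#' @param sigma Noise scale: additive SD for the Gaussian model, SD of log
#'   values for the lognormal model. 0 reproduces the model curve exactly.
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `retention_sim_spec`.
#' @export
retention_sim_spec <- function(beta_true = 0.24,
                               depths = c(0.5, 1.5, 3.0),
                               n_per_depth = c(7, 8, 8),
                               n_reference = 4,
                               noise = c("gaussian_additive",
                                         "lognormal_multiplicative"),
                               sigma = 0.05, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(beta_true > 0, sigma >= 0, all(depths >= 0),
            length(n_per_depth) == length(depths), all(n_per_depth >= 1),
            n_reference >= 0)
  structure(
    list(beta_true = beta_true, depths = depths,
         n_per_depth = as.integer(n_per_depth),
         n_reference = as.integer(n_reference),
         noise = noise, sigma = sigma, seed = as.integer(seed)),
    class = "retention_sim_spec"
  )
}

.apply_noise <- function(mu, noise, sigma, lower = 0, upper = 1) {
  y <- switch(noise,
    gaussian_additive = mu + stats::rnorm(length(mu), 0, sigma),
    lognormal_multiplicative =
      mu * exp(stats::rnorm(length(mu), 0, sigma))
  )
  clamped <- sum(y < lower | (is.finite(upper) & y > upper))
  y <- pmin(pmax(y, lower), if (is.finite(upper)) upper else y)
  list(value = y, n_clamped = clamped)
}

#' Simulate a retention-versus-depth observation table
#'
#' Draws site-level retained fractions from \eqn{R(d) = 1 - e^{-\beta d}}
#' plus the configured noise, clamped to [0, 1] (the number of clamped rows
#' is attached as attribute `n_clamped` so fitters can detect boundary
#' pile-up). Reference-group rows carry the delivered-dose readout
#' (fraction 1 before noise) with `value_kind = "reference"`.
#'
#' @param spec A [retention_sim_spec()].
#' @return A tibble with columns `site_id`, `depth_mm` (NA for reference
#'   rows), `value`, `value_kind`, `qc_pass`, directly consumable by
#'   [fit_retention()].
#' @examples
#' obs <- simulate_retention(retention_sim_spec(sigma = 0, seed = 1))
#' fit_retention(obs, bootstrap = FALSE)
#' @export
simulate_retention <- function(spec) {
  stopifnot(inherits(spec, "retention_sim_spec"))
  withr::with_seed(spec$seed, {
    depth <- rep(spec$depths, spec$n_per_depth)
    mu <- 1 - exp(-spec$beta_true * depth)
    noisy <- .apply_noise(mu, spec$noise, spec$sigma)
    ref <- if (spec$n_reference > 0) {
      .apply_noise(rep(1, spec$n_reference), spec$noise, spec$sigma)
    } else {
      list(value = numeric(0), n_clamped = 0L)
    }
    out <- tibble::tibble(
      site_id = sprintf("site_%02d", seq_len(length(depth) +
                                               spec$n_reference)),
      depth_mm = c(depth, rep(NA_real_, spec$n_reference)),
      value = c(noisy$value, ref$value),
      value_kind = c(rep("fraction", length(depth)),
                     rep("reference", spec$n_reference)),
      qc_pass = TRUE
    )
    attr(out, "n_clamped") <- noisy$n_clamped + ref$n_clamped
    out
  })
}

#' Specification for simulated growth-versus-volume experiments
#'
#' Emulates the hydrogel assay: cells injected at four volumes, viability
#' fold-change over the culture window read out by bioluminescence. Default
#' design: volumes 0.1/0.25/0.5/1.0 uL with 8/7/4/4 replicates. The default
#' maximal growth readout of 2 represents a doubling of the viability
#' signal over the assay window for an unconstrained graft.
#'
#' @param g_max_true True maximal growth readout (fold-change).
#' @param gamma_true True sensitivity exponent (default 3).
#' @param volumes Injected volumes, uL.
#' @param n_per_volume Replicate sites per volume.
#' @param noise Noise model (see [retention_sim_spec()]); lognormal
#'   multiplicative by default, keeping readouts positive.
#' @param sigma_log Noise scale (SD of log values under the lognormal
#'   model; additive SD otherwise).
#' @param seed Integer seed.
#' @return An object of class `growth_sim_spec`.
#' @export
growth_sim_spec <- function(g_max_true = 2, gamma_true = 3,
                            volumes = c(0.1, 0.25, 0.5, 1.0),
                            n_per_volume = c(8, 7, 4, 4),
                            noise = c("lognormal_multiplicative",
                                      "gaussian_additive"),
                            sigma_log = 0.15, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(g_max_true > 0, gamma_true > 0, all(volumes > 0),
            length(n_per_volume) == length(volumes), sigma_log >= 0)
  structure(
    list(g_max_true = g_max_true, gamma_true = gamma_true,
         volumes = volumes, n_per_volume = as.integer(n_per_volume),
         noise = noise, sigma_log = sigma_log, seed = as.integer(seed)),
    class = "growth_sim_spec"
  )
}

#' Simulate a growth-versus-volume observation table
#'
#' Draws growth readouts from \eqn{G(v) = G_{max}(1 - HypoR(v))^\gamma}
#' under the configured noise model (readouts stay positive under the
#' default lognormal noise; zero noise reproduces the curve exactly).
#'
#' @param spec A [growth_sim_spec()].
#' @return A tibble with columns `site_id`, `volume_ul`, `value`,
#'   `readout_kind` (`"growth"`), `qc_pass`, consumable by [fit_growth()].
#' @export
simulate_growth <- function(spec) {
  stopifnot(inherits(spec, "growth_sim_spec"))
  withr::with_seed(spec$seed, {
    volume <- rep(spec$volumes, spec$n_per_volume)
    mu <- spec$g_max_true *
      (1 - hypoperfused_fraction_volume(ul_to_um3(volume)))^spec$gamma_true
    noisy <- .apply_noise(mu, spec$noise, spec$sigma_log,
                          lower = 0, upper = Inf)
    out <- tibble::tibble(
      site_id = sprintf("site_%02d", seq_along(volume)),
      volume_ul = volume,
      value = noisy$value,
      readout_kind = "growth",
      qc_pass = TRUE
    )
    attr(out, "n_clamped") <- noisy$n_clamped
    out
  })
}

#' Specification for a simulated graft-interface imaging scene
#'
#' Emulates the longitudinal two-photon readouts at the graft-host
#' interface over days 0-5: somatic calcium intensities of host neurons
#' near (peri-graft, within the 120-um site) and far (distal) from the
#' implantation site, and microglia tracked in 3D as they are recruited to
#' the region. Default dynamics follow the observed qualitative pattern:
#' peri-graft calcium peaks on day 1-2 and returns to near baseline by day
#' 4, while the in-region microglia count peaks on days 2-3.
#'
#' @param n_neurons_peri,n_neurons_distal Neurons inside / outside the site
#'   (defaults 10 and 8).
#' @param calcium_profile_peri,calcium_profile_distal Per-day multipliers of
#'   the baseline corrected intensity (length = number of days).
#' @param baseline_intensity Baseline corrected somatic intensity, a.u.
#' @param background Imaging background level, a.u.
#' @param intensity_sd SD of additive intensity noise, a.u.
#' @param n_microglia Number of tracked microglia.
#' @param recruitment_profile Per-day probability that a microglia occupies
#'   the graft region.
#' @param motility_scale Overall multiplier on microglial step lengths;
#'   0 freezes all cells at their day-0 positions.
#' @param motility_meanlog,motility_sdlog Lognormal per-day step-length
#'   parameters (um scale).
#' @param cell_sdlog SD of the per-cell lognormal motility heterogeneity
#'   (microglial motility varies strongly cell to cell).
#' @param site_radius Graft region radius, um (default 120).
#' @param field_radius Half-extent of the imaging field, um.
#' @param seed Integer seed.
#' @return An object of class `graft_scene_spec`.
#' @export
graft_scene_spec <- function(n_neurons_peri = 10, n_neurons_distal = 8,
                             calcium_profile_peri = c(6, 10, 8, 3, 1.2, 1),
                             calcium_profile_distal = rep(1, 6),
                             baseline_intensity = 50, background = 20,
                             intensity_sd = 4,
                             n_microglia = 20,
                             recruitment_profile =
                               c(0.10, 0.30, 0.75, 0.80, 0.45, 0.30),
                             motility_scale = 1,
                             motility_meanlog = log(8),
                             motility_sdlog = 0.5,
                             cell_sdlog = 0.5,
                             site_radius = 120, field_radius = 300,
                             seed = 1L) {
  stopifnot(n_neurons_peri >= 0, n_neurons_distal >= 0,
            length(calcium_profile_peri) == length(calcium_profile_distal),
            all(calcium_profile_peri > 0), all(calcium_profile_distal > 0),
            baseline_intensity > 0, background >= 0, intensity_sd >= 0,
            n_microglia >= 0,
            length(recruitment_profile) == length(calcium_profile_peri),
            all(recruitment_profile >= 0), all(recruitment_profile <= 1),
            motility_scale >= 0, cell_sdlog >= 0,
            site_radius > 0, field_radius > site_radius)
  structure(
    list(n_neurons_peri = as.integer(n_neurons_peri),
         n_neurons_distal = as.integer(n_neurons_distal),
         calcium_profile_peri = calcium_profile_peri,
         calcium_profile_distal = calcium_profile_distal,
         baseline_intensity = baseline_intensity, background = background,
         intensity_sd = intensity_sd,
         n_microglia = as.integer(n_microglia),
         recruitment_profile = recruitment_profile,
         motility_scale = motility_scale,
         motility_meanlog = motility_meanlog,
         motility_sdlog = motility_sdlog, cell_sdlog = cell_sdlog,
         site_radius = site_radius, field_radius = field_radius,
         seed = as.integer(seed)),
    class = "graft_scene_spec"
  )
}

# uniform point in a disc (r_lo <= r <= r_hi) around the origin
.runif_annulus <- function(n, r_lo, r_hi) {
  r <- sqrt(stats::runif(n, r_lo^2, r_hi^2))
  theta <- stats::runif(n, 0, 2 * pi)
  cbind(x = r * cos(theta), y = r * sin(theta))
}

#' Simulate a graft-interface scene
#'
#' Generates (i) static neuron positions with daily ROI calcium traces
#' whose peri-graft/distal contrast follows the configured profiles, and
#' (ii) 3D microglia tracks whose in-region occupancy follows the
#' recruitment profile, with lognormal per-day step lengths and per-cell
#' motility heterogeneity. With `motility_scale = 0` all microglia stay at
#' their day-0 positions (occupancy is then fixed at its day-0 state).
#'
#' @param spec A [graft_scene_spec()].
#' @return A list with elements `neuron_points` (cell_id, day, x_um, y_um,
#'   z_um), `roi_traces` (cell_id, day, roi_mean, background),
#'   `microglia_tracks` (cell_id, day, x_um, y_um, z_um), and `site`
#'   (a [graft_site()]).
#' @examples
#' scene <- simulate_graft_scene(graft_scene_spec(seed = 7))
#' count_within_radius(scene$microglia_tracks, scene$site)
#' @export
simulate_graft_scene <- function(spec) {
  stopifnot(inherits(spec, "graft_scene_spec"))
  days <- seq_along(spec$recruitment_profile) - 1L
  n_days <- length(days)
  site <- graft_site(0, 0, spec$site_radius)
  withr::with_seed(spec$seed, {
    # --- neurons: static positions, daily calcium traces ---
    n_peri <- spec$n_neurons_peri
    n_dist <- spec$n_neurons_distal
    pos <- rbind(
      .runif_annulus(n_peri, 0, spec$site_radius * 0.95),
      .runif_annulus(n_dist, spec$site_radius * 1.15, spec$field_radius)
    )
    n_neu <- n_peri + n_dist
    neuron_ids <- sprintf("neuron_%02d", seq_len(n_neu))
    neuron_points <- tibble::tibble(
      cell_id = rep(neuron_ids, each = n_days),
      day = rep(days, n_neu),
      x_um = rep(pos[, "x"], each = n_days),
      y_um = rep(pos[, "y"], each = n_days),
      z_um = rep(stats::runif(n_neu, 20, 100), each = n_days)
    )
    mult <- c(rep(list(spec$calcium_profile_peri), n_peri),
              rep(list(spec$calcium_profile_distal), n_dist))
    cell_gain <- exp(stats::rnorm(n_neu, 0, 0.1))
    roi_traces <- tibble::tibble(
      cell_id = rep(neuron_ids, each = n_days),
      day = rep(days, n_neu),
      roi_mean = spec$background +
        spec$baseline_intensity * unlist(mult) *
        rep(cell_gain, each = n_days) +
        stats::rnorm(n_neu * n_days, 0, spec$intensity_sd),
      background = spec$background
    )

    # --- microglia: occupancy-driven 3D tracks ---
    tracks <- vector("list", spec$n_microglia)
    cell_scale <- exp(stats::rnorm(spec$n_microglia, 0, spec$cell_sdlog))
    for (i in seq_len(spec$n_microglia)) {
      xyz <- matrix(NA_real_, n_days, 3)
      inside <- stats::runif(1) < spec$recruitment_profile[1]
      p0 <- if (inside) .runif_annulus(1, 0, spec$site_radius * 0.95) else
        .runif_annulus(1, spec$site_radius * 1.1, spec$field_radius)
      xyz[1, ] <- c(p0[1, "x"], p0[1, "y"], stats::runif(1, 20, 100))
      for (d in seq_len(n_days - 1)) {
        if (spec$motility_scale == 0) {
          xyz[d + 1, ] <- xyz[d, ]
          next
        }
        new_inside <- stats::runif(1) < spec$recruitment_profile[d + 1]
        step <- spec$motility_scale * cell_scale[i] *
          stats::rlnorm(1, spec$motility_meanlog, spec$motility_sdlog)
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        cand <- xyz[d, ] + step * dir
        r_planar <- sqrt(sum(cand[1:2]^2))
        target <- if (new_inside) {
          # pull inside the region if the step left it (recruitment)
          if (r_planar > spec$site_radius * 0.95)
            spec$site_radius * stats::runif(1, 0.3, 0.95) else r_planar
        } else {
          if (r_planar < spec$site_radius * 1.1)
            stats::runif(1, spec$site_radius * 1.1, spec$field_radius) else
              min(r_planar, spec$field_radius)
        }
        if (r_planar > 0 && target != r_planar) {
          cand[1:2] <- cand[1:2] * target / r_planar
        }
        xyz[d + 1, ] <- cand
      }
      tracks[[i]] <- tibble::tibble(
        cell_id = sprintf("microglia_%02d", i),
        day = days, x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3]
      )
    }
    microglia_tracks <- dplyr::bind_rows(tracks)
    list(neuron_points = neuron_points, roi_traces = roi_traces,
         microglia_tracks = microglia_tracks, site = site)
  })
}
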