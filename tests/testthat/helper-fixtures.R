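# Small in-code fixtures shared across test files.

# exact retention observations on the model curve (no noise)
exact_retention_obs <- function(beta, depths = c(0.5, 1.5, 3.0), n = 3) {
  d <- rep(depths, each = n)
  tibble::tibble(
    site_id = seq_along(d),
    depth_mm = d,
    value = 1 - exp(-beta * d)
  )
}

# exact growth observations on the model curve
exact_growth_obs <- function(g_max, gamma,
                             volumes = c(0.1, 0.25, 0.5, 1.0), n = 3) {
  v <- rep(volumes, each = n)
  tibble::tibble(
    site_id = seq_along(v),
    volume_ul = v,
    value = g_max * (1 - hypoperfused_fraction_volume(ul_to_um3(v)))^gamma
  )
}

# track table from a matrix of (day, x, y, z) rows for one cell
one_cell_track <- function(xyz, cell_id = "c1") {
  tibble::tibble(
    cell_id = cell_id,
    day = seq_len(nrow(xyz)) - 1,
    x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3]
  )
}
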