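#' Graft implantation site
#'
#' Circular region (default radius 120 um) centered on the implantation
#' site, used to classify host cells as peri-graft or distal on 2D
#' projections of the imaging field.
#'
#' @param x,y Center coordinates, um, in the field-of-view frame.
#' @param radius Region radius, um (default 120).
#' @return An object of class `graft_site`.
#' @export
graft_site <- function(x = 0, y = 0, radius = 120) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(radius), radius > 0)
  structure(list(x = x, y = y, radius = radius), class = "graft_site")
}

#' @export
print.graft_site <- function(x, ...) {
  cat(sprintf("<graft_site> center (%g, %g) um, radius %g um\n",
              x$x, x$y, x$radius))
  invisible(x)
}

.check_track_cols <- function(data, cols) {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop("track table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Classify tracked cells as peri-graft or distal
#'
#' Labels each (cell, day) point `peri_graft` when its planar (x, y)
#' distance to the site center is at most the site radius (boundary
#' inclusive), `distal` otherwise. The rule is planar because proximity is
#' assessed on 2D projections; z is ignored.
#'
#' @param data Data frame with columns `cell_id`, `day`, `x_um`, `y_um`
#'   (a `z_um` column is allowed and ignored).
#' @param site A [graft_site()].
#' @return The input as a tibble with `distance_um` and `label` columns.
#' @export
classify_proximity <- function(data, site = graft_site()) {
  stopifnot(inherits(site, "graft_site"), is.data.frame(data))
  .check_track_cols(data, c("cell_id", "day", "x_um", "y_um"))
  df <- tibble::as_tibble(data)
  df$distance_um <- sqrt((df$x_um - site$x)^2 + (df$y_um - site$y)^2)
  df$label <- ifelse(df$distance_um <= site$radius, "peri_graft", "distal")
  df
}

#' Per-day count of cells within the graft region
#'
#' Counts distinct cell ids labeled peri-graft on each imaging day — the
#' microglia-recruitment readout. Recruitment to a fresh graft typically
#' rises to a peak around days 2-3 and declines thereafter.
#'
#' @inheritParams classify_proximity
#' @return A tibble with columns `day`, `n_peri`.
#' @export
count_within_radius <- function(data, site = graft_site()) {
  df <- classify_proximity(data, site)
  if (anyDuplicated(df[c("cell_id", "day")])) {
    stop("duplicate (cell_id, day) rows: one point per cell per day",
         call. = FALSE)
  }
  df |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(
      n_peri = dplyr::n_distinct(.data$cell_id[.data$label == "peri_graft"]),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$day)
}

#' 3D migration metrics per tracked cell
#'
#' For each cell, total path length (sum of Euclidean 3D step lengths
#' between consecutive sessions) and net displacement (straight-line
#' distance from first to last position). Path length is always at least
#' the net displacement, with equality only for collinear ordered motion.
#' Cells observed at a single time point get zeros and a flag.
#'
#' @param data Data frame with columns `cell_id`, `day`, `x_um`, `y_um`,
#'   `z_um`.
#' @return A tibble with one row per cell: `cell_id`, `n_points`,
#'   `path_length_um`, `net_displacement_um`, `single_point` flag.
#' @seealso [migration_steps()] for the per-interval step table.
#' @export
migration_metrics <- function(data) {
  stopifnot(is.data.frame(data))
  .check_track_cols(data, c("cell_id", "day", "x_um", "y_um", "z_um"))
  tibble::as_tibble(data) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::summarise(
      n_points = dplyr::n(),
      path_length_um = sum(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2 +
                                  diff(.data$z_um)^2)),
      net_displacement_um = sqrt(
        (dplyr::last(.data$x_um) - dplyr::first(.data$x_um))^2 +
          (dplyr::last(.data$y_um) - dplyr::first(.data$y_um))^2 +
          (dplyr::last(.data$z_um) - dplyr::first(.data$z_um))^2
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      path_length_um = ifelse(.data$n_points < 2, 0, .data$path_length_um),
      net_displacement_um = ifelse(.data$n_points < 2, 0,
                                   .data$net_displacement_um),
      single_point = .data$n_points < 2
    )
}

#' Per-interval migration steps
#'
#' Companion to [migration_metrics()]: one row per consecutive session pair
#' per cell, with the 3D step length.
#'
#' @inheritParams migration_metrics
#' @return A tibble with `cell_id`, `day_from`, `day_to`, `step_um`.
#' @export
migration_steps <- function(data) {
  stopifnot(is.data.frame(data))
  .check_track_cols(data, c("cell_id", "day", "x_um", "y_um", "z_um"))
  tibble::as_tibble(data) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::reframe(
      day_from = .data$day[-dplyr::n()],
      day_to = .data$day[-1],
      step_um = sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2 +
                       diff(.data$z_um)^2)
    )
}

#' Background-subtract and normalize ROI calcium traces
#'
#' Computes background-corrected somatic intensities
#' (`roi_mean - background`, clipped at zero with a flag when negative) and
#' normalizes them to a baseline. The default baseline is the mean corrected
#' intensity on the final imaging day (when peri-graft activity has returned
#' to near baseline); a numeric baseline or `"first_day_mean"` may be given
#' instead.
#'
#' @param data Data frame with columns `cell_id`, `day`, `roi_mean`,
#'   `background`.
#' @param baseline_rule `"final_day_mean"` (default), `"first_day_mean"`, or
#'   a positive number used directly.
#' @return The input as a tibble with `corrected`, `clipped` and
#'   `normalized` columns.
#' @export
normalize_trace <- function(data, baseline_rule = "final_day_mean") {
  stopifnot(is.data.frame(data))
  .check_track_cols(data, c("cell_id", "day", "roi_mean", "background"))
  df <- tibble::as_tibble(data)
  corrected <- df$roi_mean - df$background
  df$clipped <- corrected < 0
  df$corrected <- pmax(corrected, 0)
  baseline <- if (is.numeric(baseline_rule)) {
    baseline_rule
  } else if (identical(baseline_rule, "final_day_mean")) {
    mean(df$corrected[df$day == max(df$day)])
  } else if (identical(baseline_rule, "first_day_mean")) {
    mean(df$corrected[df$day == min(df$day)])
  } else {
    stop("unknown baseline_rule '", baseline_rule, "'", call. = FALSE)
  }
  if (!is.finite(baseline) || baseline <= 0) {
    stop("baseline must be a positive finite value", call. = FALSE)
  }
  df$normalized <- df$corrected / baseline
  df
}

#' Link per-day detections into cell tracks
#'
#' Greedy mutual-nearest-neighbour linking of day t detections to day t+1
#' detections: pairs are matched in order of increasing 3D distance (ties
#' broken by id order), gated at `max_step`; unmatched detections start new
#' tracks. A matched pair is flagged ambiguous when either endpoint had
#' another in-gate candidate. Identity columns from manual curation should
#' be preferred when available; this linker is a convenience for synthetic
#' or pre-curated data.
#'
#' @param data Data frame with columns `day`, `x_um`, `y_um`, `z_um` (any
#'   existing `cell_id` is ignored).
#' @param max_step Maximum allowed per-day displacement, um.
#' @return The input as a tibble with assigned `cell_id` (integers) and an
#'   `ambiguous` flag.
#' @export
link_tracks <- function(data, max_step) {
  stopifnot(is.data.frame(data), is.numeric(max_step), max_step > 0)
  .check_track_cols(data, c("day", "x_um", "y_um", "z_um"))
  df <- tibble::as_tibble(data)
  df$cell_id <- NA_integer_
  df$ambiguous <- FALSE
  ord <- order(df$day)
  days <- sort(unique(df$day))
  next_id <- 1L
  first <- which(df$day == days[1])
  df$cell_id[first] <- seq.int(next_id, length.out = length(first))
  next_id <- next_id + length(first)
  if (length(days) > 1) {
    for (k in seq_len(length(days) - 1)) {
      prev <- which(df$day == days[k])
      cur <- which(df$day == days[k + 1])
      dmat <- outer(prev, cur, function(i, j) {
        sqrt((df$x_um[i] - df$x_um[j])^2 + (df$y_um[i] - df$y_um[j])^2 +
               (df$z_um[i] - df$z_um[j])^2)
      })
      in_gate <- dmat <= max_step
      n_cand_prev <- rowSums(in_gate)
      n_cand_cur <- colSums(in_gate)
      pairs <- which(in_gate, arr.ind = TRUE)
      if (nrow(pairs)) {
        pairs <- pairs[order(dmat[pairs], pairs[, 1], pairs[, 2]), ,
                       drop = FALSE]
        used_prev <- logical(length(prev))
        used_cur <- logical(length(cur))
        for (p in seq_len(nrow(pairs))) {
          i <- pairs[p, 1]; j <- pairs[p, 2]
          if (!used_prev[i] && !used_cur[j]) {
            used_prev[i] <- TRUE
            used_cur[j] <- TRUE
            df$cell_id[cur[j]] <- df$cell_id[prev[i]]
            if (n_cand_prev[i] > 1 || n_cand_cur[j] > 1) {
              df$ambiguous[cur[j]] <- TRUE
            }
          }
        }
      }
      unmatched <- cur[is.na(df$cell_id[cur])]
      if (length(unmatched)) {
        df$cell_id[unmatched] <- seq.int(next_id,
                                         length.out = length(unmatched))
        next_id <- next_id + length(unmatched)
      }
    }
  }
  df
}
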