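test_that("proximity classification is planar and boundary-inclusive", {
  pts <- tibble::tibble(
    cell_id = c("a", "b", "c", "d"),
    day = 0,
    x_um = c(50, 100, 150, 120),
    y_um = 0,
    z_um = c(0, 500, -200, 40)  # z must not matter
  )
  lab <- classify_proximity(pts, graft_site(0, 0, 120))
  expect_equal(lab$label, c("peri_graft", "peri_graft", "distal",
                            "peri_graft"))
  expect_equal(sum(lab$label == "peri_graft"), 3)

  # invariant under rigid in-plane translation of points and center
  shift <- classify_proximity(
    dplyr::mutate(pts, x_um = x_um + 55, y_um = y_um - 31),
    graft_site(55, -31, 120))
  expect_equal(shift$label, lab$label)

  empty <- classify_proximity(pts[0, ], graft_site())
  expect_equal(nrow(empty), 0)
})

test_that("per-day counts tally distinct peri-graft cells", {
  pts <- tibble::tibble(
    cell_id = rep(c("a", "b", "c", "d", "e"), 2),
    day = rep(0:1, each = 5),
    x_um = rep(c(10, 50, 100, 200, 300), 2),
    y_um = 0, z_um = 0
  )
  counts <- count_within_radius(pts, graft_site(0, 0, 120))
  expect_equal(counts$n_peri, c(3, 3))

  # same cell inside across days counts once per day
  one <- tibble::tibble(cell_id = "a", day = 0:4, x_um = 0, y_um = 0,
                        z_um = 0)
  expect_equal(count_within_radius(one, graft_site())$n_peri, rep(1L, 5))

  dup <- dplyr::bind_rows(one, one[1, ])
  expect_error(count_within_radius(dup, graft_site()), "duplicate")

  # radius -> infinity recovers the total number of distinct cells
  big <- count_within_radius(pts, graft_site(0, 0, 1e9))
  expect_equal(big$n_peri, c(5, 5))
})

test_that("migration metrics satisfy the triangle inequality", {
  tr <- one_cell_track(rbind(c(0, 0, 0), c(3, 4, 0), c(3, 4, 12)))
  m <- migration_metrics(tr)
  expect_equal(m$path_length_um, 17)
  expect_equal(m$net_displacement_um, 13)

  still <- one_cell_track(rbind(c(5, 5, 5), c(5, 5, 5), c(5, 5, 5)))
  ms <- migration_metrics(still)
  expect_equal(ms$path_length_um, 0)
  expect_equal(ms$net_displacement_um, 0)

  line <- one_cell_track(rbind(c(0, 0, 0), c(1, 2, 2), c(2, 4, 4)))
  ml <- migration_metrics(line)
  expect_equal(ml$path_length_um, ml$net_displacement_um)

  single <- one_cell_track(rbind(c(1, 2, 3)))
  msng <- migration_metrics(single)
  expect_equal(msng$path_length_um, 0)
  expect_true(msng$single_point)

  # property: path >= net on random tracks
  withr::with_seed(11, {
    for (i in 1:20) {
      tr <- one_cell_track(matrix(rnorm(18, sd = 30), ncol = 3),
                           cell_id = paste0("c", i))
      m <- migration_metrics(tr)
      expect_gte(m$path_length_um, m$net_displacement_um - 1e-9)
    }
  })

  steps <- migration_steps(tr)
  expect_equal(nrow(steps), 5)
  expect_equal(sum(steps$step_um), migration_metrics(tr)$path_length_um)
})

test_that("trace normalization subtracts background and scales to baseline", {
  tr <- tibble::tibble(
    cell_id = "n1", day = 0:5,
    roi_mean = c(100, 60, 40, 30, 30, 30),
    background = 20
  )
  out <- normalize_trace(tr)  # final-day mean baseline = 10
  expect_equal(out$corrected, c(80, 40, 20, 10, 10, 10))
  expect_equal(out$normalized, c(8, 4, 2, 1, 1, 1))
  expect_false(any(out$clipped))

  flat <- tibble::tibble(cell_id = "n", day = 0:3, roi_mean = 50,
                         background = 20)
  expect_equal(normalize_trace(flat)$normalized, rep(1, 4))

  neg <- tibble::tibble(cell_id = "n", day = 0:1, roi_mean = c(10, 50),
                        background = 20)
  outn <- normalize_trace(neg)
  expect_equal(outn$corrected[1], 0)
  expect_true(outn$clipped[1])

  zero <- tibble::tibble(cell_id = "n", day = 0:1, roi_mean = c(50, 20),
                         background = 20)
  expect_error(normalize_trace(zero), "baseline")
  expect_equal(normalize_trace(zero, baseline_rule = 30)$normalized[1], 1)
})

test_that("greedy linking recovers tracks and flags ambiguity", {
  # two well-separated stationary cells over 3 days -> two tracks of 3
  det <- tibble::tibble(
    day = rep(0:2, each = 2),
    x_um = rep(c(0, 500), 3), y_um = 0, z_um = 0
  )
  linked <- link_tracks(det, max_step = 20)
  expect_equal(length(unique(linked$cell_id)), 2)
  expect_equal(as.integer(table(linked$cell_id)), c(3L, 3L))
  expect_false(any(linked$ambiguous))

  # a cell moving 5 um/day stays one continuous track
  mov <- tibble::tibble(day = 0:4, x_um = 5 * (0:4), y_um = 0, z_um = 0)
  lm <- link_tracks(mov, max_step = 20)
  expect_equal(length(unique(lm$cell_id)), 1)

  # too-large steps start new ids
  jump <- tibble::tibble(day = 0:1, x_um = c(0, 100), y_um = 0, z_um = 0)
  lj <- link_tracks(jump, max_step = 20)
  expect_equal(length(unique(lj$cell_id)), 2)

  # two nearby cells drifting toward swapped positions: the greedy
  # minimal-distance matching keeps straight assignments (verified against
  # brute force over the 2x2 assignment) and flags the ambiguity
  sw <- tibble::tibble(
    day = c(0, 0, 1, 1),
    x_um = c(0, 10, 3, 7), y_um = 0, z_um = 0
  )
  ls <- link_tracks(sw, max_step = 20)
  # brute force: straight (3 + 3) beats crossed (7 + 7)
  expect_equal(ls$cell_id[3], ls$cell_id[1])
  expect_equal(ls$cell_id[4], ls$cell_id[2])
  expect_true(any(ls$ambiguous))
})
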