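test_that("drift correction exactly inverts a known rigid drift", {
  cfg <- small_scenario(seed = 6L, n_ctl = 20L, n_tumor = 15L,
                        kill_prob_per_arrest_min = 0)
  sim <- simulate_scenario(cfg)
  drift <- c(0.5, -0.2, 0.1)
  drifted <- sim$tracks %>%
    dplyr::mutate(x = x + frame_index * drift[1],
                  y = y + frame_index * drift[2],
                  z = z + frame_index * drift[3])
  surf_drift <- sim$surfaces
  surf_drift$geometry <- purrr::map2(
    surf_drift$geometry, surf_drift$frame_index,
    ~ spheromotion:::translate_geometry(.x, .y * drift))
  # tumor cells have intrinsic motion, so the estimator also removes their
  # median displacement; the added rigid drift must cancel exactly between
  # the corrected drifted data and the corrected originals
  corr <- drift_correct(drifted, surf_drift)
  base <- drift_correct(sim$tracks, sim$surfaces)
  expect_equal(corr$tracks$x, base$tracks$x, tolerance = 1e-9)
  expect_equal(corr$tracks$y, base$tracks$y, tolerance = 1e-9)
  expect_equal(corr$tracks$z, base$tracks$z, tolerance = 1e-9)
  # per-track average speed recovered to numerical precision
  s0 <- summarize_tracks(base$tracks)
  s1 <- summarize_tracks(corr$tracks)
  expect_equal(s1$average_speed, s0$average_speed, tolerance = 1e-9)
  # centers restored too
  expect_equal(corr$surfaces$geometry[[nrow(corr$surfaces)]]$center,
               base$surfaces$geometry[[nrow(base$surfaces)]]$center,
               tolerance = 1e-9)
})

test_that("drift correction is the identity on drift-free data", {
  cfg <- small_scenario(seed = 8L, n_ctl = 10L, n_tumor = 0L,
                        tumor = motility_params(
                          mean_speed = 0, speed_cv = 0, persistence_kappa = 0,
                          arrest_on_rate = 0, arrest_off_rate = 1,
                          arrest_jitter_sd = 0, infiltration_bias = 0,
                          initial_inside_fraction = 1),
                        n_frames = 11L)
  # stationary tumor reference: median displacement is exactly zero
  cfg$n_tumor <- 12L
  sim <- simulate_scenario(cfg)
  corr <- drift_correct(sim$tracks, sim$surfaces)
  expect_equal(corr$tracks$x, sim$tracks$x)
  expect_equal(corr$tracks$z, sim$tracks$z)
})

test_that("drift correction without any reference objects is an error", {
  tracks <- random_tracks(3, 4)
  expect_error(drift_correct(tracks, NULL),
               class = "spheromotion_drift_error")
})

test_that("per-frame labels match the analytic containment test exactly", {
  cfg <- small_scenario(seed = 12L, n_ctl = 50L, n_tumor = 20L)
  sim <- simulate_scenario(cfg)
  labels <- classify_compartments(sim$tracks, sim$surfaces)
  radii <- purrr::map_dbl(sim$surfaces$geometry, "radius")
  joined <- dplyr::left_join(
    labels,
    dplyr::select(sim$tracks, track_id, frame_index, x, y, z),
    by = c("track_id", "frame_index"))
  brute <- sqrt(joined$x^2 + joined$y^2 + joined$z^2) <=
    radii[joined$frame_index + 1]
  expect_identical(joined$location == "infiltrating", brute)
})

test_that("track-level labels follow the majority rule with ties inside", {
  surfaces <- tibble::tibble(
    frame_index = 0:2, t = c(0, 0.5, 1),
    geometry = list(sphere_geometry(radius = 150),
                    sphere_geometry(radius = 150),
                    sphere_geometry(radius = 150)))
  inside <- make_track(c(50, 0, 0, 50, 1, 0, 50, 2, 0), id = "in")
  mostly_in <- make_track(c(0, 0, 100, 0, 0, 140, 0, 0, 160), id = "mixed")
  lab <- classify_compartments(dplyr::bind_rows(inside, mostly_in), surfaces)
  expect_true(all(lab$location[lab$track_id == "in"] == "infiltrating"))
  expect_identical(unique(lab$track_location[lab$track_id == "mixed"]),
                   "infiltrating")
  # 1 in / 1 out tie -> infiltrating
  tied <- make_track(c(0, 0, 100, 0, 0, 200), id = "tie")
  surfaces2 <- surfaces[1:2, ]
  lab2 <- classify_compartments(tied, surfaces2)
  expect_identical(unique(lab2$track_location), "infiltrating")
})

test_that("time mismatch beyond half a frame interval is an error", {
  surfaces <- tibble::tibble(frame_index = 0L, t = 10,
                             geometry = list(sphere_geometry(radius = 150)))
  track <- make_track(c(0, 0, 0, 1, 0, 0))
  expect_error(classify_compartments(track, surfaces),
               class = "spheromotion_validation_error")
})

test_that("infiltration percentages and counts partition the population", {
  surfaces <- tibble::tibble(frame_index = 0:1, t = c(0, 0.5),
                             geometry = list(sphere_geometry(radius = 150),
                                             sphere_geometry(radius = 150)))
  tracks <- purrr::map_dfr(1:12, function(i) {
    r <- if (i <= 3) 50 else 200
    make_track(c(r, 0, 0, r, 1, 0), id = sprintf("c%02d", i))
  })
  lab <- classify_compartments(tracks, surfaces)
  expect_equal(infiltration_percent(lab, "ctl"), 25)
  all_in <- classify_compartments(
    dplyr::mutate(tracks, x = pmin(x, 100)), surfaces)
  expect_equal(infiltration_percent(all_in, "ctl"), 100)
  expect_error(infiltration_percent(lab, "macrophage"),
               class = "spheromotion_undefined_error")

  counts <- count_compartment(lab, "ctl")
  expect_equal(counts$n[counts$location == "infiltrating"], 3L)
  expect_equal(counts$n[counts$location == "peripheral"], 9L)
  expect_equal(sum(counts$n), dplyr::n_distinct(tracks$track_id))
  empty <- count_compartment(lab[0, ], "ctl")
  expect_equal(sum(empty$n), 0L)
})

test_that("counts are conserved across compartments on simulated data", {
  cfg <- small_scenario(seed = 14L, n_ctl = 35L, n_tumor = 10L)
  sim <- simulate_scenario(cfg)
  lab <- classify_compartments(sim$tracks, sim$surfaces)
  for (ct in c("ctl", "tumor")) {
    counts <- count_compartment(lab, ct)
    expect_equal(sum(counts$n),
                 dplyr::n_distinct(sim$tracks$track_id[
                   sim$tracks$cell_type == ct]))
  }
})
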