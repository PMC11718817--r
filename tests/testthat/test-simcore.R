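test_that("identical config and seed reproduce the output bit for bit", {
  cfg <- small_scenario(seed = 9L)
  a <- simulate_scenario(cfg)
  b <- simulate_scenario(cfg)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(purrr::map_dbl(a$surfaces$geometry, "radius"),
                   purrr::map_dbl(b$surfaces$geometry, "radius"))
})

test_that("per-cell substreams are stable when cells are added", {
  cfg <- small_scenario(seed = 9L, n_ctl = 10L, n_tumor = 0L,
                        kill_prob_per_arrest_min = 0)
  more <- small_scenario(seed = 9L, n_ctl = 15L, n_tumor = 0L,
                         kill_prob_per_arrest_min = 0)
  a <- simulate_scenario(cfg)
  b <- simulate_scenario(more)
  shared <- dplyr::semi_join(b$tracks, a$tracks, by = "track_id")
  expect_equal(as.data.frame(shared), as.data.frame(a$tracks))
})

test_that("zero cell counts give empty track sets, not failures", {
  cfg <- small_scenario(n_ctl = 0L, n_tumor = 5L)
  sim <- simulate_scenario(cfg)
  expect_false(any(sim$tracks$cell_type == "ctl"))
  expect_equal(dplyr::n_distinct(sim$tracks$track_id), 5)
})

test_that("a frame interval at or beyond the video length is rejected", {
  expect_error(scenario_config(frame_interval = 30, video_length = 30),
               class = "spheromotion_config_error")
  expect_error(scenario_config(frame_interval = 45, video_length = 30),
               class = "spheromotion_config_error")
  expect_error(default_scenario("noon"), "arg")
})

test_that("zero arrest-on rate yields no arrested states and zero coefficients", {
  # speeds chosen so motile steps essentially never dip below 2 um/min
  cfg <- small_scenario(
    seed = 21L, n_ctl = 30L, n_tumor = 0L,
    ctl = motility_params(mean_speed = 8, speed_cv = 0.2,
                          arrest_on_rate = 0, arrest_off_rate = 1,
                          infiltration_bias = 0))
  sim <- simulate_scenario(cfg)
  expect_false(any(sim$ground_truth$state[sim$ground_truth$frame_index > 0]
                   == "arrested"))
  prof <- arrest_profiles(instantaneous_velocity(sim$tracks), 2)
  expect_true(all(prof$arrest_coefficient == 0))
})

test_that("arrested-state occupancy matches the discrete-chain stationary value", {
  # two-state chain with per-frame probabilities p = 1 - exp(-rate * dt);
  # its analytic stationary arrested fraction is p_on / (p_on + p_off)
  k_on <- 0.3; k_off <- 0.7; dt <- 0.5
  p_on <- 1 - exp(-k_on * dt); p_off <- 1 - exp(-k_off * dt)
  pi_arr <- p_on / (p_on + p_off)
  cfg <- scenario_config(
    seed = 11L, n_frames = 121L, n_tumor = 0L, n_macrophage = 0L,
    n_ctl = 500L,
    ctl = motility_params(arrest_on_rate = k_on, arrest_off_rate = k_off,
                          contact_arrest_multiplier = 1))
  sim <- simulate_scenario(cfg)
  frac <- sim$ground_truth %>%
    dplyr::filter(.data$frame_index > 0) %>%
    dplyr::group_by(.data$track_id) %>%
    dplyr::summarise(f = mean(.data$state == "arrested"))
  se <- stats::sd(frac$f) / sqrt(nrow(frac))
  expect_lt(abs(mean(frac$f) - pi_arr), 3 * se)
})

test_that("the ballistic limit yields straight tracks", {
  cfg <- small_scenario(
    seed = 2L, n_ctl = 25L, n_tumor = 0L,
    ctl = motility_params(mean_speed = 5, speed_cv = 0.3,
                          persistence_kappa = Inf, arrest_on_rate = 0,
                          arrest_off_rate = 1, infiltration_bias = 0))
  s <- summarize_tracks(simulate_scenario(cfg)$tracks)
  expect_true(all(s$straightness >= 0.99))
})

test_that("tumor cells start inside and the spheroid never grows", {
  cfg <- small_scenario(seed = 4L, n_ctl = 80L, n_tumor = 60L,
                        kill_prob_per_arrest_min = 0.3,
                        contact_radius = 20, volume_decay_per_kill = 0.01)
  sim <- simulate_scenario(cfg)
  first <- dplyr::filter(sim$tracks, .data$cell_type == "tumor",
                         .data$frame_index == 0)
  r0 <- sim$surfaces$geometry[[1]]$radius
  expect_true(all(sqrt(first$x^2 + first$y^2 + first$z^2) <= r0))
  radii <- purrr::map_dbl(sim$surfaces$geometry, "radius")
  expect_true(all(diff(radii) <= 0))
  expect_gt(sum(!is.na(unique(sim$ground_truth$apoptosis_time))), 0)

  nokill <- small_scenario(seed = 4L, n_ctl = 80L, n_tumor = 60L,
                           kill_prob_per_arrest_min = 0)
  radii0 <- purrr::map_dbl(simulate_scenario(nokill)$surfaces$geometry,
                           "radius")
  expect_true(all(radii0 == radii0[1]))
})

test_that("arrested frames read below the 2 um/min threshold", {
  cfg <- small_scenario(seed = 13L, n_ctl = 60L, n_tumor = 0L,
                        n_frames = 61L)
  sim <- simulate_scenario(cfg)
  vel <- instantaneous_velocity(sim$tracks)
  gt <- dplyr::mutate(sim$ground_truth,
                      frame_index = .data$frame_index - 1L)
  m <- dplyr::inner_join(vel, gt, by = c("track_id", "frame_index"))
  arrested_v <- m$velocity[m$state == "arrested"]
  expect_gt(length(arrested_v), 100)
  expect_gte(mean(arrested_v < 2), 0.99)
})

test_that("shipped presets encode the reported condition orderings", {
  wt <- default_scenario("early_4h", "WT", "untreated_mph")
  ko <- default_scenario("early_4h", "Il18r_ko", "untreated_mph")
  nig <- default_scenario("early_4h", "WT", "lps_nigericin_mph")
  expect_gt(ko$ctl$mean_speed, wt$ctl$mean_speed)
  expect_gt(ko$ctl$arrest_on_rate, wt$ctl$arrest_on_rate)
  expect_gt(nig$ctl$mean_speed, wt$ctl$mean_speed)
  expect_lt(nig$ctl$arrest_on_rate, wt$ctl$arrest_on_rate)
  late <- default_scenario("late_18h", "WT", "none")
  early <- default_scenario("early_4h", "WT", "none")
  expect_gt(late$ctl$initial_inside_fraction,
            early$ctl$initial_inside_fraction)
  expect_gt(late$ctl$arrest_on_rate, early$ctl$arrest_on_rate)
})
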