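test_that("volume and fold-change arithmetic", {
  expect_equal(spheroid_volume(sphere_geometry(radius = 150)),
               4 / 3 * pi * 150^3)
  expect_equal(fold_change(200, 100), 0.5)
  expect_equal(fold_change(7, 7), 1)
  expect_error(fold_change(0, 1), class = "spheromotion_validation_error")
  set.seed(51)
  a <- stats::runif(20, 1, 10); b <- stats::runif(20, 1, 10)
  expect_equal(fold_change(a, b), b / a)

  # a sphere shrinking to half its radius loses 7/8 of its volume
  v0 <- spheroid_volume(sphere_geometry(radius = 120))
  v1 <- spheroid_volume(sphere_geometry(radius = 60))
  expect_equal(fold_change(v0, v1), 0.125)
})

test_that("percent increase matches its definition", {
  expect_equal(round(percent_increase(5.55, 11.95)), 115)
  expect_equal(percent_increase(5.55, 11.95), 115.3153, tolerance = 1e-4)
  expect_equal(percent_increase(3, 3), 0)
  expect_equal(percent_increase(1, 2), 100)
  expect_error(percent_increase(0, 2),
               class = "spheromotion_validation_error")
})

test_that("fragment counts equal a brute-force union-find oracle", {
  set.seed(61)
  blob <- function(center, n, sd = 3) {
    sweep(matrix(stats::rnorm(3 * n, sd = sd), ncol = 3), 2, center, "+")
  }
  one <- blob(c(0, 0, 0), 30)
  expect_equal(count_fragments(one, link_radius = 10, min_cells = 5), 1L)
  two <- rbind(blob(c(0, 0, 0), 20), blob(c(100, 0, 0), 20))
  expect_equal(count_fragments(two, link_radius = 10, min_cells = 5), 2L)

  for (i in 1:20) {
    p <- matrix(stats::runif(3 * sample(10:40, 1), 0, 50), ncol = 3)
    lr <- stats::runif(1, 5, 20)
    mc <- sample(1:5, 1)
    expect_equal(count_fragments(p, lr, mc), oracle_fragments(p, lr, mc))
  }
})

test_that("fragment counting is permutation-invariant and monotone in radius", {
  set.seed(71)
  p <- matrix(stats::runif(90, 0, 40), ncol = 3)
  perm <- sample(nrow(p))
  expect_equal(count_fragments(p, 8, 2), count_fragments(p[perm, ], 8, 2))
  counts <- vapply(c(2, 5, 8, 15, 30),
                   function(lr) count_fragments(p, lr, 1), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("rejection summaries combine volumes and fragments", {
  set.seed(81)
  p0 <- matrix(stats::rnorm(120, sd = 20), ncol = 3)
  rs <- rejection_summary(sphere_geometry(radius = 150),
                          sphere_geometry(radius = 75),
                          initial_positions = p0, final_positions = p0,
                          experiment_id = "exp1")
  expect_equal(rs$volume_fold_change, 0.125)
  expect_equal(rs$fragments_initial, rs$fragments_final)
  expect_equal(rs$fragment_fold_change, 1)
})

test_that("apoptosis proximity reports nearest-CTL distances per flag class", {
  ctls <- tibble::tibble(x = c(0, 10), y = 0, z = 0)
  tumor <- tibble::tibble(
    x = c(0, 10, 100, 110), y = 0, z = 0,
    apoptotic = c(TRUE, TRUE, FALSE, FALSE))
  pr <- apoptosis_proximity(tumor, ctls)
  expect_equal(pr$mean_distance_apoptotic, 0)
  expect_equal(pr$mean_distance_alive, 95)
  expect_equal(pr$n_apoptotic, 2L)

  one_ctl <- tibble::tibble(x = 0, y = 0, z = 0)
  tum <- tibble::tibble(x = c(3, 0), y = c(0, 4), z = 0,
                        apoptotic = c(FALSE, FALSE))
  pr2 <- apoptosis_proximity(tum, one_ctl)
  expect_equal(pr2$mean_distance_alive, 3.5)
  expect_true(is.na(pr2$mean_distance_apoptotic))

  # invariance under a rigid motion applied to all positions
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  move <- function(df) {
    m <- as.matrix(df[, c("x", "y", "z")]) %*% t(rot)
    df$x <- m[, 1] + 5; df$y <- m[, 2] - 2; df$z <- m[, 3] + 1
    df
  }
  pr3 <- apoptosis_proximity(move(tumor), move(ctls))
  expect_equal(pr3$mean_distance_alive, pr$mean_distance_alive,
               tolerance = 1e-9)
  expect_equal(pr3$mean_distance_apoptotic, pr$mean_distance_apoptotic,
               tolerance = 1e-9)
})

test_that("contact kills put apoptotic tumor cells nearer to CTLs", {
  closer <- 0
  for (s in 1:20) {
    cfg <- small_scenario(seed = 100L + s, n_ctl = 80L, n_tumor = 60L,
                          n_frames = 41L,
                          kill_prob_per_arrest_min = 0.4,
                          contact_radius = 20,
                          volume_decay_per_kill = 0.003)
    sim <- simulate_scenario(cfg)
    last <- max(sim$tracks$frame_index)
    tum <- dplyr::filter(sim$tracks, cell_type == "tumor",
                         frame_index == last)
    ctl <- dplyr::filter(sim$tracks, cell_type == "ctl",
                         frame_index == last)
    if (!any(tum$apoptotic) || all(tum$apoptotic)) next
    pr <- apoptosis_proximity(tum, ctl)
    if (pr$mean_distance_apoptotic < pr$mean_distance_alive) {
      closer <- closer + 1
    }
  }
  expect_gte(closer, 18)
})
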