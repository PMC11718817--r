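#' Per-cell-type motility parameters
#'
#' Parameters of the persistent-random-walk / two-state arrest model driving
#' one simulated cell type. Motile cells take steps of log-normally
#' distributed speed (given mean and coefficient of variation) in a direction
#' obtained by a concentration-`kappa` perturbation of the previous direction
#' (isotropic at `kappa = 0`, ballistic as `kappa` grows). Cells switch
#' motile/arrested as a discrete-time Markov chain with per-frame switch
#' probabilities `1 - exp(-rate * frame_interval)`; while arrested they
#' jitter around an anchor with per-axis positional noise `arrest_jitter_sd`,
#' chosen so arrested frames read as instantaneous velocity below the
#' 2 um/min arrest threshold with probability at least 0.99. Proximity to a
#' tumor cell multiplies the arrest-on rate by `contact_arrest_multiplier`
#' (antigen-contact-dependent arrest). Peripheral cells drift inward at
#' `infiltration_bias` um/min; `initial_inside_fraction` of cells start
#' inside the spheroid at the first video frame.
#'
#' @param mean_speed mean step speed, um/min.
#' @param speed_cv coefficient of variation of the per-step speed.
#' @param persistence_kappa direction-update concentration (>= 0; `Inf` is
#'   fully ballistic).
#' @param arrest_on_rate,arrest_off_rate two-state switching rates, per min.
#' @param arrest_jitter_sd per-axis positional noise while arrested, um.
#' @param contact_arrest_multiplier factor on `arrest_on_rate` within
#'   `contact_radius` of a tumor cell.
#' @param infiltration_bias inward drift for cells outside the spheroid,
#'   um/min.
#' @param initial_inside_fraction fraction of cells placed inside the
#'   spheroid at the first frame.
#' @return an object of class `"motility_params"`.
#' @export
motility_params <- function(mean_speed = 4,
                            speed_cv = 0.35,
                            persistence_kappa = 6,
                            arrest_on_rate = 0.35,
                            arrest_off_rate = 0.8,
                            arrest_jitter_sd = 0.15,
                            contact_arrest_multiplier = 1,
                            infiltration_bias = 0.5,
                            initial_inside_fraction = 0.25) {
  stopifnot_scalar_number(mean_speed, "mean_speed", min = 0)
  stopifnot_scalar_number(speed_cv, "speed_cv", min = 0)
  if (!(is.numeric(persistence_kappa) && length(persistence_kappa) == 1 &&
        (is.infinite(persistence_kappa) || persistence_kappa >= 0))) {
    abort("`persistence_kappa` must be >= 0 (Inf allowed).",
          class = "spheromotion_config_error")
  }
  stopifnot_scalar_number(arrest_on_rate, "arrest_on_rate", min = 0)
  stopifnot_scalar_number(arrest_off_rate, "arrest_off_rate", min = 0)
  stopifnot_scalar_number(arrest_jitter_sd, "arrest_jitter_sd", min = 0)
  stopifnot_scalar_number(contact_arrest_multiplier,
                          "contact_arrest_multiplier", min = 0)
  stopifnot_scalar_number(infiltration_bias, "infiltration_bias", min = 0)
  stopifnot_scalar_number(initial_inside_fraction, "initial_inside_fraction",
                          min = 0)
  if (initial_inside_fraction > 1) {
    abort("`initial_inside_fraction` must lie in [0, 1].",
          class = "spheromotion_config_error")
  }
  structure(list(
    mean_speed = mean_speed, speed_cv = speed_cv,
    persistence_kappa = persistence_kappa,
    arrest_on_rate = arrest_on_rate, arrest_off_rate = arrest_off_rate,
    arrest_jitter_sd = arrest_jitter_sd,
    contact_arrest_multiplier = contact_arrest_multiplier,
    infiltration_bias = infiltration_bias,
    initial_inside_fraction = initial_inside_fraction
  ), class = "motility_params")
}

#' Scenario configuration for the synthetic coculture
#'
#' Full parameterization of one simulated spheroid coculture video: a tumor
#' spheroid (analytic sphere) seeded with tumor cells, bone-marrow-derived
#' macrophages and cytotoxic T cells at the study's 60,000 : 8,000 : 120,000
#' seeding ratio scaled down 200-fold (300 / 40 / 600 by default), imaged as
#' a 30-min video (61 frames at 0.5 min). Arrested CTLs in contact with a
#' tumor cell can trigger its apoptosis with probability
#' `kill_prob_per_arrest_min * frame_interval` per frame; each kill shrinks
#' the spheroid volume by the fraction `volume_decay_per_kill`.
#'
#' Identical configuration and seed give bit-identical output; per-cell RNG
#' substreams are derived by hashing `(seed, cell id)` so changing one cell
#' count does not perturb the tracks of other cells.
#'
#' @param seed integer root seed.
#' @param frame_interval minutes between frames (> 0).
#' @param n_frames number of frames (>= 2). Alternatively give
#'   `video_length` (minutes); then `frame_interval` must be smaller than
#'   `video_length`.
#' @param video_length optional video length in minutes, overriding
#'   `n_frames`.
#' @param timepoint `"early_4h"` or `"late_18h"` (a label carried into the
#'   output tables).
#' @param spheroid_radius initial spheroid radius, um.
#' @param n_tumor,n_macrophage,n_ctl cell counts (>= 0).
#' @param tumor,macrophage,ctl [motility_params()] per cell type.
#' @param ctl_genotype `"WT"` or `"Il18r_ko"`.
#' @param macrophage_treatment `"none"`, `"untreated_mph"` or
#'   `"lps_nigericin_mph"`.
#' @param kill_prob_per_arrest_min probability per arrested contact-minute
#'   that a CTL kills the contacted tumor cell.
#' @param contact_radius CTL-tumor contact distance, um.
#' @param volume_decay_per_kill fractional spheroid volume loss per kill.
#' @return an object of class `"scenario_config"`.
#' @seealso [default_scenario()] for the shipped condition presets,
#'   [simulate_scenario()] to run it.
#' @export
scenario_config <- function(seed = 1L,
                            frame_interval = 0.5,
                            n_frames = 61L,
                            video_length = NULL,
                            timepoint = c("early_4h", "late_18h"),
                            spheroid_radius = 150,
                            n_tumor = 300L,
                            n_macrophage = 40L,
                            n_ctl = 600L,
                            tumor = motility_params(
                              mean_speed = 0.3, speed_cv = 0.3,
                              persistence_kappa = 0, arrest_on_rate = 0,
                              arrest_off_rate = 1, infiltration_bias = 0,
                              initial_inside_fraction = 1),
                            macrophage = motility_params(
                              mean_speed = 2, speed_cv = 0.4,
                              persistence_kappa = 2, arrest_on_rate = 0.2,
                              arrest_off_rate = 0.6,
                              initial_inside_fraction = 0.3),
                            ctl = motility_params(),
                            ctl_genotype = c("WT", "Il18r_ko"),
                            macrophage_treatment = c("none", "untreated_mph",
                                                     "lps_nigericin_mph"),
                            kill_prob_per_arrest_min = 0.02,
                            contact_radius = 12,
                            volume_decay_per_kill = 0.002) {
  timepoint <- match.arg(timepoint)
  ctl_genotype <- match.arg(ctl_genotype)
  macrophage_treatment <- match.arg(macrophage_treatment)
  stopifnot_scalar_number(frame_interval, "frame_interval", min = 0,
                          strict = TRUE)
  if (!is.null(video_length)) {
    stopifnot_scalar_number(video_length, "video_length", min = 0,
                            strict = TRUE)
    if (frame_interval >= video_length) {
      abort("`frame_interval` must be smaller than the video length.",
            class = "spheromotion_config_error")
    }
    n_frames <- floor(video_length / frame_interval) + 1L
  }
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 2) {
    abort("`n_frames` must be an integer >= 2.",
          class = "spheromotion_config_error")
  }
  for (nm in c("n_tumor", "n_macrophage", "n_ctl")) {
    v <- get(nm)
    if (!(is.numeric(v) && length(v) == 1 && v >= 0 && v == floor(v))) {
      abort(sprintf("`%s` must be a non-negative integer count.", nm),
            class = "spheromotion_config_error")
    }
  }
  stopifnot_scalar_number(spheroid_radius, "spheroid_radius", min = 0,
                          strict = TRUE)
  stopifnot_scalar_number(kill_prob_per_arrest_min, "kill_prob_per_arrest_min",
                          min = 0)
  if (kill_prob_per_arrest_min > 1) {
    abort("`kill_prob_per_arrest_min` must lie in [0, 1].",
          class = "spheromotion_config_error")
  }
  stopifnot_scalar_number(contact_radius, "contact_radius", min = 0)
  stopifnot_scalar_number(volume_decay_per_kill, "volume_decay_per_kill",
                          min = 0)
  if (volume_decay_per_kill >= 1) {
    abort("`volume_decay_per_kill` must lie in [0, 1).",
          class = "spheromotion_config_error")
  }
  for (p in list(tumor, macrophage, ctl)) {
    if (!inherits(p, "motility_params")) {
      abort("`tumor`, `macrophage` and `ctl` must be motility_params().",
            class = "spheromotion_config_error")
    }
  }
  structure(list(
    seed = as.integer(seed), frame_interval = frame_interval,
    n_frames = n_frames, timepoint = timepoint,
    spheroid_radius = spheroid_radius,
    n_tumor = as.integer(n_tumor), n_macrophage = as.integer(n_macrophage),
    n_ctl = as.integer(n_ctl),
    tumor = tumor, macrophage = macrophage, ctl = ctl,
    ctl_genotype = ctl_genotype,
    macrophage_treatment = macrophage_treatment,
    kill_prob_per_arrest_min = kill_prob_per_arrest_min,
    contact_radius = contact_radius,
    volume_decay_per_kill = volume_decay_per_kill
  ), class = "scenario_config")
}

# Number of pre-generated random columns per cell per frame step:
# speed, direction cosine, 3 tangent normals, switch uniform, kill uniform,
# 3 jitter normals.
N_STREAM_COLS <- 10L

# Pre-generate one cell's entire random stream from its substream seed.
# Placement draws come first so the stream layout is stable.
cell_stream <- function(seed, cell_id, n_steps) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, cell_id))
  list(
    placement = stats::runif(3),        # inside?, radius u, shell u
    placement_dir = stats::rnorm(3),    # direction of initial position
    init_state_u = stats::runif(1),
    init_dir = stats::rnorm(3),
    speeds_u = stats::runif(n_steps),   # -> qlnorm
    w_u = stats::runif(n_steps),
    tangent = matrix(stats::rnorm(3 * n_steps), n_steps, 3),
    switch_u = stats::runif(n_steps),
    kill_u = stats::runif(n_steps),
    jitter = matrix(stats::rnorm(3 * n_steps), n_steps, 3)
  )
}

#' Simulate a synthetic spheroid coculture video
#'
#' Runs the agent-based generator described in [scenario_config()]: tumor
#' cells quasi-uniform inside the spheroid with small jitter motion, CTLs
#' and macrophages split inside/outside per their `initial_inside_fraction`,
#' persistent random walks with two-state motile/arrested switching,
#' contact-dependent arrest, contact-kill-driven spheroid shrinkage, and
#' per-frame spheroid geometry.
#'
#' @param config a [scenario_config()].
#' @return an object of class `"simulation_output"`: a list with
#'   \describe{
#'     \item{tracks}{native-schema track tibble (see [read_track_table()]).}
#'     \item{surfaces}{surface-series tibble of per-frame spheres.}
#'     \item{ground_truth}{tibble `(track_id, frame_index, state,
#'       apoptosis_time)`; `state` at frame `i > 0` is the true
#'       motile/arrested state governing the step from frame `i - 1` to
#'       `i`, frame 0 carries the initial state.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
simulate_scenario <- function(config) {
  if (!inherits(config, "scenario_config")) {
    abort("`config` must be a scenario_config().",
          class = "spheromotion_config_error")
  }
  nf <- config$n_frames
  dt <- config$frame_interval
  n_steps <- nf - 1L
  R0 <- config$spheroid_radius

  specs <- list(
    tumor = list(n = config$n_tumor, pars = config$tumor, prefix = "tum"),
    macrophage = list(n = config$n_macrophage, pars = config$macrophage,
                      prefix = "mph"),
    ctl = list(n = config$n_ctl, pars = config$ctl, prefix = "ctl")
  )

  cells <- purrr::imap(specs, function(sp, type) {
    if (sp$n == 0) return(NULL)
    purrr::map(seq_len(sp$n), function(i) {
      id <- sprintf("%s_%04d", sp$prefix, i)
      st <- cell_stream(config$seed, id, n_steps)
      pars <- sp$pars
      # initial placement: inside with prob initial_inside_fraction,
      # quasi-uniform in the ball (radius 0.95 R) or in a peripheral shell
      inside <- st$placement[1] < pars$initial_inside_fraction
      dir0 <- unit_vector3(st$placement_dir)
      r <- if (inside) {
        0.95 * R0 * st$placement[2]^(1 / 3)
      } else {
        R0 + 5 + 35 * st$placement[3]
      }
      pi_arr <- if (pars$arrest_on_rate + pars$arrest_off_rate > 0) {
        pars$arrest_on_rate / (pars$arrest_on_rate + pars$arrest_off_rate)
      } else 0
      lp <- lognormal_pars(max(pars$mean_speed, 1e-12), pars$speed_cv)
      list(
        id = id, type = type, pars = pars, stream = st,
        pos = r * dir0,
        dir = unit_vector3(st$init_dir),
        arrested = st$init_state_u < pi_arr,
        speeds = if (pars$mean_speed > 0) {
          stats::qlnorm(st$speeds_u, lp$meanlog, lp$sdlog)
        } else rep(0, n_steps),
        anchor = r * dir0,
        apoptotic = FALSE, apoptosis_time = NA_real_
      )
    })
  })
  cells <- purrr::compact(cells)
  flat <- purrr::flatten(unname(cells))
  n_cells <- length(flat)

  # per-frame storage
  ids <- purrr::map_chr(flat, "id")
  types <- purrr::map_chr(flat, "type")
  pos <- do.call(rbind, purrr::map(flat, "pos"))
  if (is.null(pos)) pos <- matrix(numeric(0), 0, 3)
  dirs <- do.call(rbind, purrr::map(flat, "dir"))
  arrested <- purrr::map_lgl(flat, "arrested")
  anchors <- pos
  apoptotic <- rep(FALSE, n_cells)
  apoptosis_time <- rep(NA_real_, n_cells)

  tumor_idx <- which(types == "tumor")
  ctl_idx <- which(types == "ctl")

  positions <- array(NA_real_, c(n_cells, 3, nf))
  if (n_cells > 0) positions[, , 1] <- pos
  states <- matrix(NA_character_, n_cells, nf)
  states[, 1] <- ifelse(arrested, "arrested", "motile")
  apopt_flags <- matrix(FALSE, n_cells, nf)

  radius <- numeric(nf)
  radius[1] <- R0
  volume <- spheroid_volume(sphere_geometry(radius = R0))

  for (f in seq_len(n_steps)) {
    r_now <- radius[f]
    # contact with a living tumor cell (CTLs only drive kills; the contact
    # multiplier applies to any non-tumor cell near a living tumor cell)
    alive_tumor <- tumor_idx[!apoptotic[tumor_idx]]
    nearest_tumor <- rep(NA_integer_, n_cells)
    in_contact <- rep(FALSE, n_cells)
    if (length(alive_tumor) > 0 && n_cells > length(tumor_idx)) {
      non_tumor <- which(types != "tumor")
      tp <- pos[alive_tumor, , drop = FALSE]
      for (i in non_tumor) {
        d2 <- (tp[, 1] - pos[i, 1])^2 + (tp[, 2] - pos[i, 2])^2 +
          (tp[, 3] - pos[i, 3])^2
        j <- which.min(d2)
        if (d2[j] <= config$contact_radius^2) {
          in_contact[i] <- TRUE
          nearest_tumor[i] <- alive_tumor[j]
        }
      }
    }

    kills <- 0L
    for (i in seq_len(n_cells)) {
      cell <- flat[[i]]
      pars <- cell$pars
      st <- cell$stream
      if (apoptotic[i]) {
        # apoptotic tumor cells stop moving and keep their flag
        positions[i, , f + 1] <- pos[i, ]
        states[i, f + 1] <- "arrested"
        apopt_flags[i, f + 1] <- TRUE
        next
      }
      # state switch (Markov chain, per-frame probabilities)
      k_on <- pars$arrest_on_rate *
        if (in_contact[i]) pars$contact_arrest_multiplier else 1
      if (arrested[i]) {
        p_off <- 1 - exp(-pars$arrest_off_rate * dt)
        if (st$switch_u[f] < p_off) {
          arrested[i] <- FALSE
        }
      } else {
        p_on <- 1 - exp(-k_on * dt)
        if (st$switch_u[f] < p_on) {
          arrested[i] <- TRUE
          anchors[i, ] <- pos[i, ]
        }
      }
      if (arrested[i]) {
        pos[i, ] <- anchors[i, ] + pars$arrest_jitter_sd * st$jitter[f, ]
        # contact kill: an arrested CTL on a living tumor cell
        if (types[i] == "ctl" && in_contact[i] &&
            !is.na(nearest_tumor[i]) && !apoptotic[nearest_tumor[i]] &&
            st$kill_u[f] < config$kill_prob_per_arrest_min * dt) {
          j <- nearest_tumor[i]
          apoptotic[j] <- TRUE
          apoptosis_time[j] <- f * dt
          kills <- kills + 1L
        }
      } else {
        w <- vmf_cosine(st$w_u[f], pars$persistence_kappa)
        dirs[i, ] <- perturb_directions(matrix(dirs[i, ], 1), w,
                                        matrix(st$tangent[f, ], 1))
        step <- dirs[i, ] * cell$speeds[f] * dt
        # inward drift for cells outside the spheroid
        rad <- sqrt(sum(pos[i, ]^2))
        if (types[i] != "tumor" && rad > r_now && pars$infiltration_bias > 0) {
          step <- step - pos[i, ] / rad * pars$infiltration_bias * dt
        }
        pos[i, ] <- pos[i, ] + step
      }
      positions[i, , f + 1] <- pos[i, ]
      states[i, f + 1] <- if (arrested[i]) "arrested" else "motile"
      apopt_flags[i, f + 1] <- apoptotic[i]
    }
    if (kills > 0) {
      volume <- volume * (1 - config$volume_decay_per_kill)^kills
      radius[f + 1] <- (volume * 3 / (4 * pi))^(1 / 3)
    } else {
      radius[f + 1] <- radius[f]
    }
  }

  t_vec <- (seq_len(nf) - 1) * dt
  tracks <- if (n_cells == 0) {
    tibble(track_id = character(), cell_type = character(),
           genotype = character(), treatment = character(),
           frame_index = integer(), t = numeric(), x = numeric(),
           y = numeric(), z = numeric(), apoptotic = logical())
  } else {
    tibble(
      track_id = rep(ids, each = nf),
      cell_type = rep(types, each = nf),
      genotype = ifelse(rep(types, each = nf) == "ctl",
                        config$ctl_genotype, "n/a"),
      treatment = ifelse(rep(types, each = nf) == "macrophage",
                         config$macrophage_treatment, "n/a"),
      frame_index = rep(seq_len(nf) - 1L, n_cells),
      t = rep(t_vec, n_cells),
      x = as.vector(t(matrix(positions[, 1, ], n_cells, nf))),
      y = as.vector(t(matrix(positions[, 2, ], n_cells, nf))),
      z = as.vector(t(matrix(positions[, 3, ], n_cells, nf))),
      apoptotic = ifelse(rep(types, each = nf) == "tumor",
                         as.vector(t(apopt_flags)), NA)
    ) %>% dplyr::arrange(.data$track_id, .data$frame_index)
  }

  ground_truth <- if (n_cells == 0) {
    tibble(track_id = character(), frame_index = integer(),
           state = character(), apoptosis_time = numeric())
  } else {
    tibble(
      track_id = rep(ids, each = nf),
      frame_index = rep(seq_len(nf) - 1L, n_cells),
      state = as.vector(t(states)),
      apoptosis_time = rep(apoptosis_time, each = nf)
    ) %>% dplyr::arrange(.data$track_id, .data$frame_index)
  }

  surfaces <- tibble(
    frame_index = seq_len(nf) - 1L,
    t = t_vec,
    geometry = purrr::map(radius, ~ sphere_geometry(c(0, 0, 0), .x))
  )

  structure(list(tracks = tracks, surfaces = surfaces,
                 ground_truth = ground_truth, config = config),
            class = "simulation_output")
}

#' @export
print.simulation_output <- function(x, ...) {
  cat(sprintf(
    "<simulation_output> %d tracks x %d frames (%s, CTL %s, macrophages %s)\n",
    dplyr::n_distinct(x$tracks$track_id), x$config$n_frames,
    x$config$timepoint, x$config$ctl_genotype, x$config$macrophage_treatment))
  invisible(x)
}
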