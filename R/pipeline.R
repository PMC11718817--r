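#' Run the full analysis pipeline
#'
#' Orchestrates the complete workflow on one video: optional drift
#' correction, compartment classification, per-track kinematics, arrest
#' statistics at the arrest threshold, rejection readouts and cohort
#' summary tables. Input is either a [scenario_config()] (the video is
#' simulated) or paths to track and surface files.
#'
#' @param config a [scenario_config()], or `NULL` when reading files.
#' @param track_path,surface_path input files (native dialect) when
#'   `config` is `NULL`.
#' @param arrest_threshold arrest threshold, um/min.
#' @param drift_correction apply [drift_correct()] before analysis.
#' @param count_frame frame index for infiltration counts (`NULL`: first).
#' @return an object of class `"motility_report"`: a list of tibbles
#'   (`per_track`, `group_summary`, `infiltration`, `counts`, `rejection`,
#'   `proximity`), the `density` curve of CTL arrest coefficients (when
#'   estimable), and a `manifest` recording parameters, seed and exclusions.
#' @export
run_pipeline <- function(config = NULL, track_path = NULL,
                         surface_path = NULL, arrest_threshold = 2,
                         drift_correction = TRUE, count_frame = NULL) {
  if (!is.null(config)) {
    sim <- simulate_scenario(config)
    tracks <- sim$tracks
    surfaces <- sim$surfaces
  } else {
    if (is.null(track_path) || is.null(surface_path)) {
      abort("Provide either `config` or both `track_path` and `surface_path`.",
            class = "spheromotion_config_error")
    }
    tracks <- read_track_table(track_path)
    surfaces <- read_surface_series(surface_path)
    sim <- NULL
  }
  if (drift_correction) {
    corrected <- drift_correct(tracks, surfaces)
    tracks <- corrected$tracks
    surfaces <- corrected$surfaces
  }

  labels <- classify_compartments(tracks, surfaces)
  track_loc <- dplyr::distinct(labels, .data$track_id, .data$track_location)

  summaries <- summarize_tracks(tracks) %>%
    dplyr::left_join(track_loc, by = "track_id")
  velocities <- instantaneous_velocity(tracks)
  profiles <- arrest_profiles(velocities, threshold = arrest_threshold) %>%
    dplyr::left_join(track_loc, by = "track_id")
  per_track <- summaries %>%
    dplyr::left_join(
      dplyr::select(profiles, "track_id", "arrest_coefficient", "n_arrests",
                    "total_arrest_time"),
      by = "track_id")

  group_summary <- cohort_summary(
    per_track,
    group_keys = c("cell_type", "genotype", "treatment", "track_location"),
    metrics = c("average_speed", "track_displacement", "track_length",
                "straightness", "track_duration", "arrest_coefficient"))

  cell_types <- unique(tracks$cell_type)
  infiltration <- purrr::map_dfr(cell_types, function(ct) {
    tibble(cell_type = ct,
           frame_index = if (is.null(count_frame)) {
             min(labels$frame_index)
           } else as.integer(count_frame),
           infiltration_percent = infiltration_percent(labels, ct,
                                                       count_frame))
  })
  counts <- purrr::map_dfr(cell_types, count_compartment, labels = labels,
                           frame = count_frame)

  first_geom <- surfaces$geometry[[1]]
  last_geom <- surfaces$geometry[[nrow(surfaces)]]
  last_frame <- max(tracks$frame_index)
  tumor_first <- dplyr::filter(tracks, .data$cell_type == "tumor",
                               .data$frame_index == min(tracks$frame_index))
  tumor_last <- dplyr::filter(tracks, .data$cell_type == "tumor",
                              .data$frame_index == last_frame)
  rejection <- rejection_summary(
    first_geom, last_geom,
    initial_positions = if (nrow(tumor_first) > 1) tumor_first else NULL,
    final_positions = if (nrow(tumor_last) > 1) tumor_last else NULL)

  ctl_last <- dplyr::filter(tracks, .data$cell_type == "ctl",
                            .data$frame_index == last_frame)
  proximity <- if (nrow(tumor_last) > 0 && nrow(ctl_last) > 0 &&
                   !all(is.na(tumor_last$apoptotic))) {
    apoptosis_proximity(tumor_last, ctl_last)
  } else {
    tibble(mean_distance_alive = NA_real_,
           mean_distance_apoptotic = NA_real_,
           n_alive = NA_integer_, n_apoptotic = NA_integer_)
  }

  ctl_coeffs <- profiles$arrest_coefficient[profiles$cell_type == "ctl"]
  density <- if (length(ctl_coeffs) >= 2 && stats::sd(ctl_coeffs) > 0) {
    arrest_density(ctl_coeffs)
  } else NULL

  manifest <- tibble(
    package_version = as.character(utils::packageVersion("spheromotion")),
    seed = if (!is.null(config)) config$seed else NA_integer_,
    source = if (!is.null(config)) "simulated" else track_path,
    arrest_threshold = arrest_threshold,
    drift_correction = drift_correction,
    n_tracks = dplyr::n_distinct(tracks$track_id),
    n_frames = dplyr::n_distinct(tracks$frame_index),
    n_straightness_excluded = sum(!per_track$straightness_defined),
    parameter_hash = object_hash(list(
      config = if (!is.null(config)) unclass(config) else NULL,
      arrest_threshold = arrest_threshold,
      drift_correction = drift_correction, count_frame = count_frame)))

  structure(list(per_track = per_track, group_summary = group_summary,
                 infiltration = infiltration, counts = counts,
                 rejection = rejection, proximity = proximity,
                 density = density, manifest = manifest,
                 simulation = sim),
            class = "motility_report")
}

#' @export
print.motility_report <- function(x, ...) {
  cat(sprintf("<motility_report> %d tracks, %d group-summary rows\n",
              nrow(x$per_track), nrow(x$group_summary)))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes every table of a [run_pipeline()] report as deterministic
#' delimited text (fixed row and column order), so identical runs produce
#' byte-identical bundles.
#'
#' @param report a `"motility_report"`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(tb, name) {
    readr::write_csv(tb, file.path(dir, paste0(name, ".csv")),
                     progress = FALSE)
  }
  wr(dplyr::select(report$per_track, -dplyr::any_of("durations")),
     "per_track")
  wr(report$group_summary, "group_summary")
  wr(report$infiltration, "infiltration")
  wr(report$counts, "counts")
  wr(report$rejection, "rejection")
  wr(report$proximity, "proximity")
  if (!is.null(report$density)) wr(report$density, "arrest_density")
  wr(report$manifest, "manifest")
  if (!is.null(report$simulation)) {
    write_track_table(report$simulation$tracks, file.path(dir, "tracks.csv"))
    write_surface_series(report$simulation$surfaces,
                         file.path(dir, "surfaces.csv"))
    readr::write_csv(report$simulation$ground_truth,
                     file.path(dir, "ground_truth.csv"), progress = FALSE)
  }
  invisible(dir)
}

#' Run the full condition grid
#'
#' Simulates and analyzes every condition of [condition_grid()] with one
#' replicate each, returning the stacked group summaries labelled by
#' condition.
#'
#' @param seed root seed; each condition uses a distinct derived seed.
#' @param n_tumor,n_macrophage,n_ctl optional cell-count overrides applied
#'   to every condition (smaller grids for quick looks).
#' @param ... passed to [run_pipeline()].
#' @return a tibble of group-summary rows with `timepoint`, `ctl_genotype`
#'   and `macrophage_treatment` columns.
#' @export
run_condition_grid <- function(seed = 1L, n_tumor = NULL,
                               n_macrophage = NULL, n_ctl = NULL, ...) {
  grid <- condition_grid()
  purrr::pmap_dfr(grid, function(timepoint, ctl_genotype,
                                 macrophage_treatment) {
    cfg <- default_scenario(timepoint, ctl_genotype, macrophage_treatment,
                            seed = substream_seed(
                              seed, paste(timepoint, ctl_genotype,
                                          macrophage_treatment)))
    if (!is.null(n_tumor)) cfg$n_tumor <- as.integer(n_tumor)
    if (!is.null(n_macrophage) && cfg$n_macrophage > 0) {
      cfg$n_macrophage <- as.integer(n_macrophage)
    }
    if (!is.null(n_ctl)) cfg$n_ctl <- as.integer(n_ctl)
    rep <- run_pipeline(cfg, ...)
    rep$group_summary %>%
      dplyr::mutate(timepoint = timepoint, ctl_genotype = ctl_genotype,
                    macrophage_treatment = macrophage_treatment,
                    .before = 1)
  })
}
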