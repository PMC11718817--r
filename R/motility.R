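#' Instantaneous velocity series
#'
#' Per-track instantaneous velocities by forward differences:
#' `v_i = |r_{i+1} - r_i| / frame_interval`, one sample per consecutive
#' frame pair. Forward differences keep each velocity sample aligned with
#' one frame pair, so the arrest mask derived from it is a run-length
#' object over frame pairs.
#'
#' @param tracks native-schema track tibble (validated; uniform sampling).
#' @return a tibble with one row per frame pair: `track_id`, `cell_type`,
#'   `genotype`, `treatment`, `frame_index` (of the pair's first frame),
#'   `t_mid` (pair midpoint, minutes), `velocity` (um/min) and
#'   `frame_interval`.
#' @examples
#' tr <- tibble::tibble(track_id = "a", cell_type = "ctl", genotype = "WT",
#'                      treatment = "n/a", frame_index = 0:1, t = c(0, 0.5),
#'                      x = c(0, 1), y = 0, z = 0, apoptotic = NA)
#' instantaneous_velocity(tr)$velocity  # 2 um/min
#' @export
instantaneous_velocity <- function(tracks) {
  validate_tracks(tracks)
  if (nrow(tracks) == 0) {
    return(tibble(track_id = character(), cell_type = character(),
                  genotype = character(), treatment = character(),
                  frame_index = integer(), t_mid = numeric(),
                  velocity = numeric(), frame_interval = numeric()))
  }
  tracks %>%
    dplyr::arrange(.data$track_id, .data$frame_index) %>%
    dplyr::group_by(.data$track_id, .data$cell_type, .data$genotype,
                    .data$treatment) %>%
    dplyr::mutate(
      dt = dplyr::lead(.data$t) - .data$t,
      step = sqrt((dplyr::lead(.data$x) - .data$x)^2 +
                    (dplyr::lead(.data$y) - .data$y)^2 +
                    (dplyr::lead(.data$z) - .data$z)^2)) %>%
    dplyr::filter(!is.na(.data$dt)) %>%
    dplyr::transmute(.data$frame_index,
                     t_mid = .data$t + .data$dt / 2,
                     velocity = .data$step / .data$dt,
                     frame_interval = .data$dt) %>%
    dplyr::ungroup()
}

#' Per-track kinematic summaries
#'
#' The exported track-level motility parameters: track length (summed step
#' norms), track displacement (start-to-end vector distance), track duration
#' (`(n - 1) * frame_interval`), average speed (track length over duration),
#' and straightness (displacement over length; 1 = directional, 0 =
#' confined). Straightness is undefined for a zero-length track and is
#' returned as `NA` with `straightness_defined = FALSE`; cohort summaries
#' exclude such tracks from straightness means.
#'
#' @param tracks native-schema track tibble.
#' @return a tibble with one row per track: identity and metadata columns
#'   plus `n_samples`, `track_duration`, `track_length`,
#'   `track_displacement`, `average_speed`, `straightness`,
#'   `straightness_defined`.
#' @export
summarize_tracks <- function(tracks) {
  validate_tracks(tracks)
  tracks %>%
    dplyr::arrange(.data$track_id, .data$frame_index) %>%
    dplyr::group_by(.data$track_id, .data$cell_type, .data$genotype,
                    .data$treatment) %>%
    dplyr::summarise(
      n_samples = dplyr::n(),
      track_duration = max(.data$t) - min(.data$t),
      track_length = sum(sqrt(diff(.data$x)^2 + diff(.data$y)^2 +
                                diff(.data$z)^2)),
      track_displacement = sqrt(
        (dplyr::last(.data$x) - dplyr::first(.data$x))^2 +
          (dplyr::last(.data$y) - dplyr::first(.data$y))^2 +
          (dplyr::last(.data$z) - dplyr::first(.data$z))^2),
      .groups = "drop") %>%
    dplyr::mutate(
      average_speed = .data$track_length / .data$track_duration,
      straightness_defined = .data$track_length > 0,
      straightness = dplyr::if_else(
        .data$straightness_defined,
        .data$track_displacement / .data$track_length, NA_real_))
}

#' Cohort mean and SD tables
#'
#' Group-wise mean, sample standard deviation (n - 1 denominator) and group
#' size for each kinematic metric, the form in which condition comparisons
#' are reported (bar graphs of mean +/- SD). Tracks with undefined
#' straightness are excluded from the straightness rows, with the exclusion
#' count reported. Groups of size 1 carry `sd = 0` and `sd_defined = FALSE`.
#'
#' @param summaries a [summarize_tracks()] result (optionally joined with
#'   compartment or condition columns to group by).
#' @param group_keys character vector of grouping columns.
#' @param metrics which metric columns to summarize.
#' @return a long tibble `(group columns, metric, mean, sd, n, n_excluded,
#'   sd_defined)`.
#' @export
cohort_summary <- function(summaries,
                           group_keys = c("cell_type", "genotype",
                                          "treatment"),
                           metrics = c("average_speed", "track_displacement",
                                       "track_length", "straightness",
                                       "track_duration")) {
  missing <- setdiff(c(group_keys, metrics), names(summaries))
  if (length(missing) > 0) {
    abort(sprintf("Columns not present in `summaries`: %s",
                  paste(missing, collapse = ", ")),
          class = "spheromotion_validation_error")
  }
  long <- summaries %>%
    dplyr::select(dplyr::all_of(c(group_keys, metrics))) %>%
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "value")
  long %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_keys, "metric")))) %>%
    dplyr::summarise(
      n_excluded = sum(is.na(.data$value)),
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = dplyr::if_else(sum(!is.na(.data$value)) > 1,
                          stats::sd(.data$value, na.rm = TRUE), 0),
      sd_defined = sum(!is.na(.data$value)) > 1,
      .groups = "drop") %>%
    dplyr::filter(.data$n > 0) %>%
    dplyr::select(dplyr::all_of(group_keys), "metric", "mean", "sd", "n",
                  "n_excluded", "sd_defined")
}
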