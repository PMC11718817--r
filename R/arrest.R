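#' Arrest profiles from instantaneous velocities
#'
#' Thresholds each track's instantaneous-velocity series at the arrest
#' threshold (default 2 um/min): a velocity sample strictly below the
#' threshold is an arrested frame pair. The arrest coefficient is the
#' fraction of a track's velocity samples below threshold — the fraction of
#' time the cell stays in arrest — and arrest durations are the lengths, in
#' minutes, of maximal consecutive runs of below-threshold samples.
#'
#' @param velocities an [instantaneous_velocity()] tibble.
#' @param threshold arrest threshold, um/min (> 0). Velocities exactly at
#'   the threshold count as motile.
#' @return a tibble with one row per track: `track_id`, metadata columns,
#'   `threshold`, `n_samples`, `arrest_coefficient`, `n_arrests`,
#'   `total_arrest_time` (minutes) and a `durations` list-column of
#'   per-arrest durations in minutes.
#' @examples
#' tr <- tibble::tibble(track_id = "a", cell_type = "ctl", genotype = "WT",
#'                      treatment = "n/a", frame_index = 0:4,
#'                      t = seq(0, 2, 0.5), x = c(0, 0.1, 0.2, 3, 6),
#'                      y = 0, z = 0, apoptotic = NA)
#' arrest_profiles(instantaneous_velocity(tr))
#' @export
arrest_profiles <- function(velocities, threshold = 2) {
  stopifnot_scalar_number(threshold, "threshold", min = 0, strict = TRUE)
  if (nrow(velocities) == 0) {
    abort("Empty velocity series.", class = "spheromotion_validation_error")
  }
  velocities %>%
    dplyr::arrange(.data$track_id, .data$frame_index) %>%
    dplyr::group_by(.data$track_id, .data$cell_type, .data$genotype,
                    .data$treatment) %>%
    dplyr::summarise(
      threshold = threshold,
      n_samples = dplyr::n(),
      arrest_coefficient = mean(.data$velocity < threshold),
      durations = list(run_durations(.data$velocity < threshold,
                                     .data$frame_interval[1])),
      .groups = "drop") %>%
    dplyr::mutate(
      n_arrests = purrr::map_int(.data$durations, length),
      total_arrest_time = purrr::map_dbl(.data$durations, sum))
}

# Lengths in minutes of maximal TRUE runs of a logical mask.
run_durations <- function(mask, frame_interval) {
  r <- rle(mask)
  r$lengths[r$values] * frame_interval
}

#' Arrest durations, one row per arrest
#'
#' Unnests the `durations` list-column of [arrest_profiles()] into a long
#' table suitable for pooled violin/density displays.
#'
#' @param profiles an [arrest_profiles()] result.
#' @return a tibble `(track_id, metadata, duration)` with one row per
#'   maximal arrest run; tracks without arrests contribute no rows.
#' @export
arrest_durations <- function(profiles) {
  profiles %>%
    dplyr::select("track_id", "cell_type", "genotype", "treatment",
                  "durations") %>%
    tidyr::unnest_longer("durations", values_to = "duration") %>%
    dplyr::filter(!is.na(.data$duration))
}

#' Density curve of arrest coefficients
#'
#' Gaussian-kernel density of arrest coefficients on their natural support
#' `[0, 1]`, with boundary reflection at both ends so no probability mass
#' leaks outside the interval. Peaks of the curve mark accumulations of
#' arrest coefficients in the cohort. Bandwidth defaults to Silverman's
#' rule-of-thumb ([stats::bw.nrd0()]).
#'
#' @param coefficients numeric vector of arrest coefficients in `[0, 1]`
#'   (at least two finite values).
#' @param bandwidth kernel bandwidth; `NULL` for Silverman's rule. All-equal
#'   coefficients make the automatic bandwidth degenerate — pass an explicit
#'   one in that case.
#' @param n_grid number of evaluation points on `[0, 1]`.
#' @return a tibble of class `"density_curve"` with columns `x` and
#'   `density`, and attributes `bandwidth` and `metric`.
#' @export
arrest_density <- function(coefficients, bandwidth = NULL, n_grid = 512) {
  x <- coefficients[is.finite(coefficients)]
  if (length(x) < 2) {
    abort("At least two finite arrest coefficients are required.",
          class = "spheromotion_validation_error")
  }
  if (any(x < 0 | x > 1)) {
    abort("Arrest coefficients must lie in [0, 1].",
          class = "spheromotion_validation_error")
  }
  if (is.null(bandwidth)) {
    if (stats::sd(x) == 0) {
      abort(paste("Automatic bandwidth is degenerate (identical values);",
                  "supply `bandwidth` explicitly."),
            class = "spheromotion_bandwidth_error")
    }
    bandwidth <- stats::bw.nrd0(x)
  }
  stopifnot_scalar_number(bandwidth, "bandwidth", min = 0, strict = TRUE)
  grid <- seq(0, 1, length.out = n_grid)
  # reflect the sample at both boundaries: x -> -x and x -> 2 - x
  dens <- vapply(grid, function(g) {
    sum(stats::dnorm(g, mean = x, sd = bandwidth) +
          stats::dnorm(g, mean = -x, sd = bandwidth) +
          stats::dnorm(g, mean = 2 - x, sd = bandwidth))
  }, numeric(1)) / length(x)
  out <- tibble(x = grid, density = dens)
  attr(out, "bandwidth") <- bandwidth
  attr(out, "metric") <- "arrest_coefficient"
  class(out) <- c("density_curve", class(out))
  out
}

#' Plot-ready pause timeline
#'
#' One row per velocity sample with its midpoint time and whether it falls
#' below the arrest threshold — the data behind instantaneous-velocity
#' traces with the threshold drawn as a dashed line.
#'
#' @inheritParams arrest_profiles
#' @param threshold arrest threshold, um/min (>= 0 here; strict inequality,
#'   so a zero threshold flags nothing).
#' @return a tibble `(track_id, t, velocity, below_threshold, threshold)`.
#' @export
pause_timeline <- function(velocities, threshold = 2) {
  stopifnot_scalar_number(threshold, "threshold", min = 0)
  velocities %>%
    dplyr::transmute(.data$track_id, t = .data$t_mid, .data$velocity,
                     below_threshold = .data$velocity < threshold,
                     threshold = threshold)
}
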