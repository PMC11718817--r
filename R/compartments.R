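#' Rigid drift correction for tracks and surfaces
#'
#' Removes per-frame rigid translation shared by all objects (stage or
#' sample drift). The frame-to-frame drift is estimated as the componentwise
#' median displacement of tumor-cell positions between consecutive frames;
#' when no tumor tracks are present the surface centroid displacement is
#' used instead. Estimated drifts are accumulated and subtracted from all
#' spots and surface geometries; frame 0 is left unchanged.
#'
#' @param tracks native-schema track tibble.
#' @param surfaces surface-series tibble (may be `NULL` when tumor tracks
#'   exist).
#' @return a list with corrected `tracks` and `surfaces`.
#' @export
drift_correct <- function(tracks, surfaces = NULL) {
  frames <- sort(unique(tracks$frame_index))
  tumor <- dplyr::filter(tracks, .data$cell_type == "tumor")
  if (nrow(tumor) > 0) {
    wide <- tumor %>%
      dplyr::arrange(.data$track_id, .data$frame_index) %>%
      dplyr::group_by(.data$track_id) %>%
      dplyr::mutate(dx = .data$x - dplyr::lag(.data$x),
                    dy = .data$y - dplyr::lag(.data$y),
                    dz = .data$z - dplyr::lag(.data$z)) %>%
      dplyr::ungroup() %>%
      dplyr::filter(!is.na(.data$dx))
    step <- wide %>%
      dplyr::group_by(.data$frame_index) %>%
      dplyr::summarise(dx = stats::median(.data$dx),
                       dy = stats::median(.data$dy),
                       dz = stats::median(.data$dz), .groups = "drop")
  } else if (!is.null(surfaces) && nrow(surfaces) > 1) {
    cent <- do.call(rbind, purrr::map(surfaces$geometry, geometry_centroid))
    step <- tibble(
      frame_index = surfaces$frame_index[-1],
      dx = diff(cent[, 1]), dy = diff(cent[, 2]), dz = diff(cent[, 3]))
  } else {
    abort(paste("No tumor tracks and no multi-frame surface series:",
                "disable drift correction for this input."),
          class = "spheromotion_drift_error")
  }
  offsets <- tibble(frame_index = frames) %>%
    dplyr::left_join(step, by = "frame_index") %>%
    dplyr::mutate(dplyr::across(c("dx", "dy", "dz"),
                                ~ tidyr::replace_na(.x, 0))) %>%
    dplyr::mutate(ox = cumsum(.data$dx), oy = cumsum(.data$dy),
                  oz = cumsum(.data$dz))
  corrected <- tracks %>%
    dplyr::left_join(offsets[, c("frame_index", "ox", "oy", "oz")],
                     by = "frame_index") %>%
    dplyr::mutate(x = .data$x - .data$ox,
                  y = .data$y - .data$oy,
                  z = .data$z - .data$oz) %>%
    dplyr::select(-"ox", -"oy", -"oz")
  if (!is.null(surfaces)) {
    off_map <- offsets[match(surfaces$frame_index, offsets$frame_index), ]
    surfaces$geometry <- purrr::pmap(
      list(surfaces$geometry, off_map$ox, off_map$oy, off_map$oz),
      function(g, ox, oy, oz) translate_geometry(g, -c(ox, oy, oz)))
  }
  list(tracks = corrected, surfaces = surfaces)
}

#' Classify spots as spheroid-infiltrating or peripheral
#'
#' Labels every (track, frame) spot by the sign of its distance to the
#' spheroid surface of the matching frame: signed distance <= 0 (inside or
#' on the surface) is `"infiltrating"`, positive is `"peripheral"`. Track
#' frame times are matched to surface frames by nearest time within half a
#' frame interval. The per-track label is the majority of its frame labels,
#' with ties counted as infiltrating.
#'
#' @param tracks native-schema track tibble.
#' @param surfaces surface-series tibble.
#' @return a tibble of class `"compartment_labels"` with one row per
#'   (track, frame): `track_id`, `cell_type`, `frame_index`, `t`,
#'   `signed_distance`, `location`, plus the per-track majority label
#'   `track_location`.
#' @export
classify_compartments <- function(tracks, surfaces) {
  if (nrow(tracks) == 0) {
    out <- tibble(track_id = character(), cell_type = character(),
                  frame_index = integer(), t = numeric(),
                  signed_distance = numeric(), location = character(),
                  track_location = character())
    class(out) <- c("compartment_labels", class(out))
    return(out)
  }
  dt <- if (dplyr::n_distinct(tracks$t) > 1) {
    min(diff(sort(unique(tracks$t))))
  } else 1
  surf_t <- surfaces$t
  idx <- vapply(tracks$t, function(ti) {
    j <- which.min(abs(surf_t - ti))
    if (abs(surf_t[j] - ti) > dt / 2 + 1e-9) NA_integer_ else j
  }, integer(1))
  if (anyNA(idx)) {
    missing_t <- sort(unique(tracks$t[is.na(idx)]))
    abort(sprintf(
      "No surface frame within half a frame interval of track time(s): %s",
      paste(utils::head(format(missing_t), 5), collapse = ", ")),
      class = "spheromotion_validation_error")
  }
  sd_vals <- numeric(nrow(tracks))
  for (j in sort(unique(idx))) {
    rows <- which(idx == j)
    sd_vals[rows] <- signed_distance(
      surfaces$geometry[[j]],
      as.matrix(tracks[rows, c("x", "y", "z")]))
  }
  labels <- tracks %>%
    dplyr::transmute(.data$track_id, .data$cell_type, .data$frame_index,
                     .data$t,
                     signed_distance = sd_vals,
                     location = ifelse(sd_vals <= 0, "infiltrating",
                                       "peripheral"))
  per_track <- labels %>%
    dplyr::group_by(.data$track_id) %>%
    dplyr::summarise(
      track_location = ifelse(
        mean(.data$location == "infiltrating") >= 0.5,
        "infiltrating", "peripheral"),
      .groups = "drop")
  out <- dplyr::left_join(labels, per_track, by = "track_id")
  class(out) <- c("compartment_labels", class(out))
  out
}

#' Infiltration percentage at one frame
#'
#' Percentage of cells of one type located inside the spheroid at the given
#' frame: `100 * infiltrating / (infiltrating + peripheral)`. The study
#' reports one value per video, computed here at the first frame by default.
#'
#' @param labels a [classify_compartments()] result.
#' @param cell_type which cell type to count.
#' @param frame frame index at which to count (default: first frame present).
#' @return percentage in `[0, 100]`.
#' @export
infiltration_percent <- function(labels, cell_type = "ctl", frame = NULL) {
  if (is.null(frame)) frame <- min(labels$frame_index)
  at <- dplyr::filter(labels, .data$cell_type == !!cell_type,
                      .data$frame_index == !!frame)
  if (nrow(at) == 0) {
    abort(sprintf("No cells of type '%s' at frame %d.", cell_type, frame),
          class = "spheromotion_undefined_error")
  }
  100 * mean(at$location == "infiltrating")
}

#' Per-compartment cell counts at one frame
#'
#' @inheritParams infiltration_percent
#' @param location `"infiltrating"`, `"peripheral"`, or both (default).
#' @return a tibble `(cell_type, location, n)`; absent combinations count 0.
#' @export
count_compartment <- function(labels, cell_type = "ctl",
                              location = c("infiltrating", "peripheral"),
                              frame = NULL) {
  location <- match.arg(location, several.ok = TRUE)
  if (is.null(frame)) {
    frame <- if (nrow(labels) > 0) min(labels$frame_index) else 0L
  }
  at <- dplyr::filter(labels, .data$cell_type == !!cell_type,
                      .data$frame_index == !!frame)
  tibble(cell_type = cell_type, location = location) %>%
    dplyr::left_join(dplyr::count(at, .data$location), by = "location") %>%
    dplyr::mutate(n = as.integer(tidyr::replace_na(.data$n, 0L)))
}
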