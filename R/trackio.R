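#' Read a track table
#'
#' Reads time-lapse 3D cell tracks from delimited text. Two dialects are
#' supported: the package's `"native"` schema (one row per cell per frame with
#' columns `track_id, cell_type, genotype, treatment, frame_index, t, x, y, z,
#' apoptotic`; time in minutes, coordinates in micrometers) and
#' `"imaris_position_export"`, the conventional column layout of a position
#' export from 3D tracking software (`Position X`, `Position Y`, `Position Z`,
#' `Unit`, `Time`, `TrackID`). The Imaris-style `Time` column is a 1-based
#' frame number; wall-clock time is reconstructed from `frame_interval`.
#' Positions in mm are converted to um.
#'
#' Validation is total: any malformed input raises a classed error
#' (`spheromotion_schema_error` or `spheromotion_validation_error`) and no
#' partially constructed table is returned. Tracks need at least two samples,
#' strictly increasing times, uniform frame spacing (tolerance 1e-6 min) and
#' finite coordinates.
#'
#' @param path file to read.
#' @param dialect `"native"` or `"imaris_position_export"`.
#' @param frame_interval minutes between frames; used only by the Imaris
#'   dialect to reconstruct `t` from the 1-based frame number.
#' @param cell_type,genotype,treatment metadata applied to every track read
#'   through the Imaris dialect (that export carries none).
#' @return a tibble with the native columns, ordered by `track_id` then
#'   `frame_index`.
#' @export
read_track_table <- function(path,
                             dialect = c("native", "imaris_position_export"),
                             frame_interval = 0.5,
                             cell_type = "ctl",
                             genotype = "n/a",
                             treatment = "n/a") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("Track file not found: %s", path),
          class = "spheromotion_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (dialect == "native") {
    need <- c("track_id", "cell_type", "genotype", "treatment",
              "frame_index", "t", "x", "y", "z", "apoptotic")
    missing <- setdiff(need, names(raw))
    if (length(missing) > 0) {
      abort(sprintf("Track table is missing mandatory column(s): %s",
                    paste(missing, collapse = ", ")),
            class = "spheromotion_schema_error")
    }
    tab <- raw %>%
      dplyr::mutate(track_id = as.character(.data$track_id),
                    frame_index = as.integer(.data$frame_index),
                    apoptotic = as.logical(.data$apoptotic))
  } else {
    need <- c("Position X", "Position Y", "Position Z", "Unit", "Time",
              "TrackID")
    missing <- setdiff(need, names(raw))
    if (length(missing) > 0) {
      abort(sprintf("Imaris position export is missing mandatory column(s): %s",
                    paste(missing, collapse = ", ")),
            class = "spheromotion_schema_error")
    }
    unit <- unique(raw[["Unit"]])
    if (!all(unit %in% c("um", "µm", "mm"))) {
      abort(sprintf("Unknown position unit(s): %s (expected um or mm)",
                    paste(setdiff(unit, c("um", "µm", "mm")),
                          collapse = ", ")),
            class = "spheromotion_validation_error")
    }
    scale <- ifelse(raw[["Unit"]] == "mm", 1000, 1)
    tab <- tibble(
      track_id = as.character(raw[["TrackID"]]),
      cell_type = cell_type,
      genotype = genotype,
      treatment = treatment,
      frame_index = as.integer(raw[["Time"]]) - 1L,
      t = (as.integer(raw[["Time"]]) - 1L) * frame_interval,
      x = raw[["Position X"]] * scale,
      y = raw[["Position Y"]] * scale,
      z = raw[["Position Z"]] * scale,
      apoptotic = NA
    )
  }
  tab <- dplyr::arrange(tab, .data$track_id, .data$frame_index)
  validate_tracks(tab)
  tab
}

#' Validate a track table
#'
#' Checks the native-schema invariants: unique `(track_id, frame_index)`,
#' at least two samples per track, strictly increasing time, uniform frame
#' spacing within 1e-6 min, and finite coordinates. Raises a classed
#' validation error naming the offending track; returns the table invisibly.
#'
#' @param tracks a native-schema track tibble.
#' @export
validate_tracks <- function(tracks) {
  if (nrow(tracks) == 0) return(invisible(tracks))
  if (!all(is.finite(tracks$x) & is.finite(tracks$y) & is.finite(tracks$z))) {
    bad <- unique(tracks$track_id[!is.finite(tracks$x) |
                                    !is.finite(tracks$y) |
                                    !is.finite(tracks$z)])
    abort(sprintf("Non-finite coordinates in track(s): %s",
                  paste(utils::head(bad, 5), collapse = ", ")),
          class = "spheromotion_validation_error")
  }
  dup <- duplicated(tracks[, c("track_id", "frame_index")])
  if (any(dup)) {
    abort(sprintf("Duplicate (track_id, frame_index) pairs, e.g. track %s",
                  tracks$track_id[which(dup)[1]]),
          class = "spheromotion_validation_error")
  }
  per <- tracks %>%
    dplyr::group_by(.data$track_id) %>%
    dplyr::summarise(
      n = dplyr::n(),
      monotone = all(diff(.data$t) > 0),
      uniform = dplyr::n() < 3 ||
        max(abs(diff(diff(.data$t)))) <= 1e-6,
      .groups = "drop")
  if (any(per$n < 2)) {
    abort(sprintf("Track(s) with fewer than 2 samples: %s",
                  paste(utils::head(per$track_id[per$n < 2], 5),
                        collapse = ", ")),
          class = "spheromotion_validation_error")
  }
  if (!all(per$monotone)) {
    abort(sprintf("Non-monotone time within track(s): %s",
                  paste(utils::head(per$track_id[!per$monotone], 5),
                        collapse = ", ")),
          class = "spheromotion_validation_error")
  }
  if (!all(per$uniform)) {
    abort(sprintf("Non-uniform frame spacing (tolerance 1e-6 min) in track(s): %s",
                  paste(utils::head(per$track_id[!per$uniform], 5),
                        collapse = ", ")),
          class = "spheromotion_validation_error")
  }
  invisible(tracks)
}

#' Write a track table
#'
#' Writes the native delimited-text schema with deterministic column order
#' and rows sorted by `track_id` then `frame_index`, so identical tables
#' produce byte-identical files.
#'
#' @param tracks a native-schema track tibble (validated before writing).
#' @param path output file.
#' @export
write_track_table <- function(tracks, path) {
  cols <- c("track_id", "cell_type", "genotype", "treatment",
            "frame_index", "t", "x", "y", "z", "apoptotic")
  if (nrow(tracks) > 0) validate_tracks(tracks)
  out <- tracks[do.call(order, tracks[, c("track_id", "frame_index")]),
                cols, drop = FALSE]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read or write a spheroid surface series
#'
#' A surface series holds the spheroid geometry at every video frame. Two
#' plain-text layouts are supported and auto-detected on read:
#' \describe{
#'   \item{sphere series}{CSV with columns `frame_index, t, cx, cy, cz,
#'     radius` (um).}
#'   \item{mesh series}{a `SURFOFF` block file: header line `SURFOFF`, the
#'     number of frames, then per frame a line `frame <index> <t>`, a line
#'     `<n_vertices> <n_faces>`, the vertex coordinates and 1-based triangle
#'     indices. Watertightness is validated on read; a non-watertight frame
#'     raises an error reporting the number of open edges.}
#' }
#'
#' @param path file to read or write.
#' @return `read_surface_series()` returns a tibble with columns
#'   `frame_index`, `t` and a `geometry` list-column of `"sphere"` /
#'   `"trimesh"` objects.
#' @export
read_surface_series <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Surface file not found: %s", path),
          class = "spheromotion_io_error")
  }
  first <- readLines(path, n = 1)
  if (identical(trimws(first), "SURFOFF")) {
    return(read_mesh_series(path))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("frame_index", "t", "cx", "cy", "cz", "radius")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("Sphere series is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "spheromotion_schema_error")
  }
  if (any(raw$radius <= 0)) {
    abort("Sphere series contains non-positive radii.",
          class = "spheromotion_validation_error")
  }
  tibble(
    frame_index = as.integer(raw$frame_index),
    t = raw$t,
    geometry = purrr::pmap(raw, function(frame_index, t, cx, cy, cz, radius, ...) {
      sphere_geometry(c(cx, cy, cz), radius)
    })
  )
}

read_mesh_series <- function(path) {
  lines <- readLines(path)
  n_frames <- as.integer(lines[2])
  pos <- 3
  frames <- vector("list", n_frames)
  meta <- matrix(NA_real_, n_frames, 2)
  for (k in seq_len(n_frames)) {
    hdr <- strsplit(trimws(lines[pos]), "\\s+")[[1]]
    if (hdr[1] != "frame") {
      abort(sprintf("Malformed mesh series at line %d: expected 'frame'.", pos),
            class = "spheromotion_schema_error")
    }
    meta[k, ] <- as.numeric(hdr[2:3])
    counts <- as.integer(strsplit(trimws(lines[pos + 1]), "\\s+")[[1]])
    nv <- counts[1]; nf <- counts[2]
    vtx <- do.call(rbind, lapply(lines[(pos + 2):(pos + 1 + nv)], function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    }))
    fcs <- do.call(rbind, lapply(lines[(pos + 2 + nv):(pos + 1 + nv + nf)],
                                 function(l) {
      as.integer(strsplit(trimws(l), "\\s+")[[1]])
    }))
    frames[[k]] <- mesh_geometry(vtx, fcs)  # validates watertightness
    pos <- pos + 2 + nv + nf
  }
  tibble(frame_index = as.integer(meta[, 1]), t = meta[, 2], geometry = frames)
}

#' @rdname read_surface_series
#' @param series a surface-series tibble (`frame_index`, `t`, `geometry`).
#' @export
write_surface_series <- function(series, path) {
  geoms <- series$geometry
  if (all(purrr::map_lgl(geoms, inherits, "sphere"))) {
    out <- tibble(
      frame_index = as.integer(series$frame_index),
      t = series$t,
      cx = purrr::map_dbl(geoms, ~ .x$center[1]),
      cy = purrr::map_dbl(geoms, ~ .x$center[2]),
      cz = purrr::map_dbl(geoms, ~ .x$center[3]),
      radius = purrr::map_dbl(geoms, "radius")
    )
    readr::write_csv(out, path, progress = FALSE)
    return(invisible(path))
  }
  if (!all(purrr::map_lgl(geoms, inherits, "trimesh"))) {
    abort("A surface series must be all spheres or all meshes to be written.",
          class = "spheromotion_io_error")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("SURFOFF", as.character(nrow(series))), con)
  for (k in seq_len(nrow(series))) {
    g <- geoms[[k]]
    writeLines(sprintf("frame %d %.10g", series$frame_index[k], series$t[k]),
               con)
    writeLines(sprintf("%d %d", nrow(g$vertices), nrow(g$faces)), con)
    writeLines(apply(g$vertices, 1, function(r) {
      paste(sprintf("%.10g", r), collapse = " ")
    }), con)
    writeLines(apply(g$faces, 1, paste, collapse = " "), con)
  }
  invisible(path)
}
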