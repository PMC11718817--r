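#' Fold change and percent increase
#'
#' `fold_change()` is the ratio final/initial used for overnight spheroid
#' volume and fragment-count readouts; `percent_increase()` is
#' `100 * (late - early) / early`, the arithmetic behind statements such as
#' a count rising by 115% between timepoints.
#'
#' @param initial,early positive baseline value.
#' @param final,late later value.
#' @return a dimensionless ratio (`fold_change`) or a percentage
#'   (`percent_increase`).
#' @examples
#' fold_change(200, 100)        # 0.5
#' percent_increase(5.55, 11.95) # ~115.3
#' @export
fold_change <- function(initial, final) {
  if (!all(is.finite(initial)) || any(initial <= 0)) {
    abort("`initial` must be positive and finite.",
          class = "spheromotion_validation_error")
  }
  final / initial
}

#' @rdname fold_change
#' @export
percent_increase <- function(early, late) {
  if (!all(is.finite(early)) || any(early <= 0)) {
    abort("`early` must be positive and finite.",
          class = "spheromotion_validation_error")
  }
  100 * (late - early) / early
}

#' Count spheroid fragments by single-linkage clustering
#'
#' Number of spheroid fragments at one frame, defined as connected
#' components of the graph joining tumor-cell positions within
#' `link_radius`, keeping components with at least `min_cells` cells.
#' By default `link_radius` is twice the mean nearest-neighbor distance of
#' the supplied positions.
#'
#' @param positions n x 3 matrix or a data frame with `x`, `y`, `z` columns
#'   (um) — tumor-cell positions at one frame.
#' @param link_radius linkage distance, um; `NULL` for the default.
#' @param min_cells minimum component size to count as a fragment.
#' @return integer fragment count (0 when nothing survives the size filter).
#' @export
count_fragments <- function(positions, link_radius = NULL, min_cells = 5) {
  p <- if (is.data.frame(positions)) {
    as.matrix(positions[, c("x", "y", "z")])
  } else {
    to_point_matrix(positions)
  }
  n <- nrow(p)
  if (n == 0) return(0L)
  d <- as.matrix(stats::dist(p))
  if (is.null(link_radius)) {
    if (n < 2) {
      abort("Cannot derive a default link_radius from fewer than 2 cells.",
            class = "spheromotion_validation_error")
    }
    diag(d) <- Inf
    link_radius <- 2 * mean(apply(d, 1, min))
    diag(d) <- 0
  }
  stopifnot_scalar_number(link_radius, "link_radius", min = 0, strict = TRUE)
  # connected components via label propagation on the adjacency matrix
  adj <- d <= link_radius
  comp <- seq_len(n)
  repeat {
    new_comp <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]),
                       numeric(1))
    if (all(new_comp == comp)) break
    comp <- new_comp
  }
  sizes <- table(comp)
  sum(sizes >= min_cells)
}

#' Rejection summary for one experiment
#'
#' Spheroid volume and fragment-count fold changes between an initial and a
#' final observation — the tumor-rejection readouts. "Overnight" fold change
#' is operationalized as the final frame of the late video over the first
#' frame of the early video.
#'
#' @param initial_geometry,final_geometry spheroid geometries
#'   ([sphere_geometry()] or [mesh_geometry()]).
#' @param initial_positions,final_positions tumor-cell positions at the two
#'   frames (for fragment counting); `NULL` to skip fragment readouts.
#' @param experiment_id identifier carried into the output row.
#' @param link_radius,min_cells passed to [count_fragments()]; the default
#'   link radius is derived from the initial frame and reused for the final
#'   frame.
#' @return a one-row tibble with volumes, fragment counts and fold changes.
#' @export
rejection_summary <- function(initial_geometry, final_geometry,
                              initial_positions = NULL,
                              final_positions = NULL,
                              experiment_id = "experiment",
                              link_radius = NULL, min_cells = 5) {
  v0 <- spheroid_volume(initial_geometry)
  v1 <- spheroid_volume(final_geometry)
  out <- tibble(
    experiment_id = experiment_id,
    volume_initial = v0, volume_final = v1,
    volume_fold_change = fold_change(v0, v1),
    fragments_initial = NA_integer_, fragments_final = NA_integer_,
    fragment_fold_change = NA_real_)
  if (!is.null(initial_positions) && !is.null(final_positions)) {
    p0 <- if (is.data.frame(initial_positions)) {
      as.matrix(initial_positions[, c("x", "y", "z")])
    } else to_point_matrix(initial_positions)
    if (is.null(link_radius)) {
      d <- as.matrix(stats::dist(p0)); diag(d) <- Inf
      link_radius <- 2 * mean(apply(d, 1, min))
    }
    f0 <- count_fragments(initial_positions, link_radius, min_cells)
    f1 <- count_fragments(final_positions, link_radius, min_cells)
    out$fragments_initial <- as.integer(f0)
    out$fragments_final <- as.integer(f1)
    out$fragment_fold_change <- if (f0 > 0) f1 / f0 else NA_real_
  }
  out
}

#' Apoptosis-proximity statistic
#'
#' For every tumor cell at the final frame, the distance to its nearest
#' CTL; means are reported separately for apoptotic (caspase-positive) and
#' alive tumor cells. Distances are centroid-to-centroid; `cell_radius`
#' subtracts a fixed cell radius for a surface-to-centroid reading.
#'
#' @param tumor tibble of tumor cells at one frame with columns `x`, `y`,
#'   `z` and logical `apoptotic`.
#' @param ctls tibble or matrix of CTL positions at the same frame
#'   (`x`, `y`, `z`).
#' @param cell_radius fixed radius (um) subtracted from every distance
#'   (floored at 0).
#' @return a one-row tibble `(mean_distance_alive, mean_distance_apoptotic,
#'   n_alive, n_apoptotic)`; an empty flag class yields `NA` for its mean.
#' @export
apoptosis_proximity <- function(tumor, ctls, cell_radius = 0) {
  if (nrow(tumor) == 0) {
    abort("At least one tumor cell is required.",
          class = "spheromotion_validation_error")
  }
  cp <- if (is.data.frame(ctls)) as.matrix(ctls[, c("x", "y", "z")]) else
    to_point_matrix(ctls)
  if (nrow(cp) == 0) {
    abort("At least one CTL is required.",
          class = "spheromotion_validation_error")
  }
  tp <- as.matrix(tumor[, c("x", "y", "z")])
  nearest <- vapply(seq_len(nrow(tp)), function(i) {
    sqrt(min((cp[, 1] - tp[i, 1])^2 + (cp[, 2] - tp[i, 2])^2 +
               (cp[, 3] - tp[i, 3])^2))
  }, numeric(1))
  nearest <- pmax(nearest - cell_radius, 0)
  flag <- as.logical(tumor$apoptotic)
  tibble(
    mean_distance_alive = if (any(!flag)) mean(nearest[!flag]) else NA_real_,
    mean_distance_apoptotic = if (any(flag)) mean(nearest[flag]) else
      NA_real_,
    n_alive = sum(!flag),
    n_apoptotic = sum(flag))
}
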