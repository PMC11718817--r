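#' Spheroid surface geometries
#'
#' The spheroid surface at one video frame is either an analytic sphere or a
#' closed (watertight) triangle mesh. Both support signed distance queries,
#' containment tests, centroids, and enclosed volume; the downstream
#' compartment and rejection analyses are geometry-agnostic.
#'
#' @param center numeric length-3, sphere center in micrometers.
#' @param radius sphere radius in micrometers; must be positive.
#' @return `sphere_geometry()` returns an object of class `"sphere"`;
#'   `mesh_geometry()` an object of class `"trimesh"`.
#' @examples
#' s <- sphere_geometry(c(0, 0, 0), 150)
#' signed_distance(s, c(50, 0, 0))   # -100, inside
#' @export
sphere_geometry <- function(center = c(0, 0, 0), radius) {
  stopifnot_scalar_number(radius, "radius", min = 0, strict = TRUE)
  if (length(center) != 3 || !all(is.finite(center))) {
    abort("`center` must be three finite coordinates (um).",
          class = "spheromotion_geometry_error")
  }
  structure(list(center = as.numeric(center), radius = as.numeric(radius)),
            class = "sphere")
}

#' @rdname sphere_geometry
#' @param vertices numeric matrix, one vertex per row, columns x/y/z in um.
#' @param faces integer matrix of 1-based vertex indices, one triangle per row.
#' @param validate check watertightness (every edge shared by exactly two
#'   faces). Disable only for meshes already validated on read.
#' @export
mesh_geometry <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3 || !all(is.finite(vertices))) {
    abort("`vertices` must be an n x 3 matrix of finite coordinates.",
          class = "spheromotion_geometry_error")
  }
  if (any(faces < 1) || any(faces > nrow(vertices))) {
    abort("`faces` contains vertex indices outside 1..nrow(vertices).",
          class = "spheromotion_geometry_error")
  }
  m <- structure(list(vertices = vertices, faces = faces), class = "trimesh")
  if (validate) {
    bad <- boundary_edge_count(m)
    if (bad > 0) {
      abort(sprintf(
        "Mesh is not watertight: %d edge(s) are not shared by exactly 2 faces.",
        bad), class = "spheromotion_mesh_error")
    }
  }
  m
}

# Number of edges not shared by exactly two faces.
boundary_edge_count <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  sum(table(key) != 2)
}

#' Signed distance from a point to the spheroid surface
#'
#' Negative inside the spheroid, positive outside, zero on the surface.
#' For a sphere this is `|p - center| - R`; for a watertight mesh it is the
#' unsigned distance to the nearest triangle with the sign determined by
#' ray-parity containment. Points within 1e-9 um of the surface count as
#' inside, matching the infiltrating/peripheral boundary convention.
#'
#' @param geometry a `"sphere"` or `"trimesh"` object.
#' @param points numeric length-3 vector or an n x 3 matrix (um).
#' @return numeric vector of signed distances in micrometers.
#' @export
signed_distance <- function(geometry, points) {
  UseMethod("signed_distance")
}

#' @export
signed_distance.sphere <- function(geometry, points) {
  p <- to_point_matrix(points)
  d <- sqrt(colSums((t(p) - geometry$center)^2)) - geometry$radius
  as.numeric(d)
}

#' @export
signed_distance.trimesh <- function(geometry, points) {
  p <- to_point_matrix(points)
  ud <- vapply(seq_len(nrow(p)), function(i) {
    min(point_triangle_distances(geometry, p[i, ]))
  }, numeric(1))
  inside <- mesh_contains(geometry, p)
  ifelse(inside, -ud, ud)
}

to_point_matrix <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 3) {
      abort("`points` must be length-3 or an n x 3 matrix.",
            class = "spheromotion_geometry_error")
    }
    points <- matrix(points, ncol = 3)
  }
  m <- as.matrix(points)
  if (ncol(m) != 3) {
    abort("`points` must have three coordinate columns.",
          class = "spheromotion_geometry_error")
  }
  m
}

# Distances from one point to every triangle of a mesh (vectorized over
# faces). Standard region-based closest-point-on-triangle computation.
point_triangle_distances <- function(mesh, p) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  ab <- b - a
  ac <- c_ - a
  ap <- matrix(p, nrow(a), 3, byrow = TRUE) - a

  d1 <- rowSums(ab * ap)
  d2 <- rowSums(ac * ap)
  bp <- matrix(p, nrow(a), 3, byrow = TRUE) - b
  d3 <- rowSums(ab * bp)
  d4 <- rowSums(ac * bp)
  cp <- matrix(p, nrow(a), 3, byrow = TRUE) - c_
  d5 <- rowSums(ab * cp)
  d6 <- rowSums(ac * cp)

  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2

  closest <- matrix(NA_real_, nrow(a), 3)
  done <- rep(FALSE, nrow(a))

  set_pts <- function(idx, pts) {
    closest[idx & !done, ] <<- pts[idx & !done, , drop = FALSE]
    done <<- done | idx
  }

  set_pts(d1 <= 0 & d2 <= 0, a)                                 # vertex A
  set_pts(d3 >= 0 & d4 <= d3, b)                                # vertex B
  set_pts(d6 >= 0 & d5 <= d6, c_)                               # vertex C
  vdenom <- d1 / pmax(d1 - d3, .Machine$double.xmin)
  set_pts(vc <= 0 & d1 >= 0 & d3 <= 0, a + vdenom * ab)         # edge AB
  wdenom <- d2 / pmax(d2 - d6, .Machine$double.xmin)
  set_pts(vb <= 0 & d2 >= 0 & d6 <= 0, a + wdenom * ac)         # edge AC
  udenom <- (d4 - d3) / pmax((d4 - d3) + (d5 - d6), .Machine$double.xmin)
  set_pts(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0,
          b + udenom * (c_ - b))                                # edge BC
  denom <- pmax(va + vb + vc, .Machine$double.xmin)
  set_pts(rep(TRUE, nrow(a)),
          a + (vb / denom) * ab + (vc / denom) * ac)            # interior

  sqrt(rowSums((closest - matrix(p, nrow(a), 3, byrow = TRUE))^2))
}

# Ray-parity containment: cast a ray in a fixed direction, count triangle
# crossings (Moller-Trumbore), odd = inside. The ray direction is slightly
# irrational to dodge edge-on hits on axis-aligned fixtures.
mesh_contains <- function(mesh, points) {
  p <- to_point_matrix(points)
  dir <- c(0.57735026918962573, 0.26726124191242440, 0.77151674981045959)
  dir <- dir / sqrt(sum(dir^2))
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  # h = dir x e2 (constant dir)
  h <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
             dir[3] * e2[, 1] - dir[1] * e2[, 3],
             dir[1] * e2[, 2] - dir[2] * e2[, 1])
  det <- rowSums(e1 * h)
  ok <- abs(det) > 1e-12
  vapply(seq_len(nrow(p)), function(i) {
    s <- matrix(p[i, ], nrow(a), 3, byrow = TRUE) - a
    u <- rowSums(s * h) / det
    q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
               s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
               s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
    vv <- (q[, 1] * dir[1] + q[, 2] * dir[2] + q[, 3] * dir[3]) / det
    tt <- rowSums(q * e2) / det
    hit <- ok & u >= 0 & vv >= 0 & (u + vv) <= 1 & tt > 1e-12
    sum(hit) %% 2 == 1
  }, logical(1))
}

#' Enclosed spheroid volume
#'
#' Volume in cubic micrometers of the region bounded by the surface:
#' \eqn{(4/3)\pi R^3} for a sphere, and the absolute signed-tetrahedron sum
#' (divergence theorem) for a watertight triangle mesh.
#'
#' @inheritParams signed_distance
#' @return volume in um^3.
#' @examples
#' spheroid_volume(sphere_geometry(radius = 150))
#' @export
spheroid_volume <- function(geometry) {
  UseMethod("spheroid_volume")
}

#' @export
spheroid_volume.sphere <- function(geometry) {
  4 / 3 * pi * geometry$radius^3
}

#' @export
spheroid_volume.trimesh <- function(geometry) {
  bad <- boundary_edge_count(geometry)
  if (bad > 0) {
    abort(sprintf("Cannot compute volume of a non-watertight mesh (%d open edges).",
                  bad), class = "spheromotion_mesh_error")
  }
  v <- geometry$vertices
  f <- geometry$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cross_bc <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
                    b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
                    b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  abs(sum(rowSums(a * cross_bc)) / 6)
}

# Centroid of a geometry (sphere center; mesh vertex mean).
geometry_centroid <- function(geometry) {
  if (inherits(geometry, "sphere")) return(geometry$center)
  colMeans(geometry$vertices)
}

# Translate a geometry rigidly.
translate_geometry <- function(geometry, offset) {
  if (inherits(geometry, "sphere")) {
    geometry$center <- geometry$center + offset
    return(geometry)
  }
  geometry$vertices <- sweep(geometry$vertices, 2, offset, "+")
  geometry
}

#' Icosphere triangulation of a sphere
#'
#' Subdivided icosahedron with vertices projected onto a sphere. Useful to
#' exercise the mesh code paths against the analytic sphere answers.
#'
#' @param radius sphere radius in um.
#' @param subdivisions number of 4-to-1 face subdivisions (0 gives the
#'   icosahedron's 20 faces; each level multiplies faces by 4).
#' @param center sphere center.
#' @return a `"trimesh"` geometry.
#' @export
icosphere_mesh <- function(radius = 1, subdivisions = 2, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(parent = emptyenv())
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      v <<- rbind(v, (v[i, ] + v[j, ]) / 2)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    newf <- matrix(0L, 0, 3)
    for (k in seq_len(nrow(f))) {
      i <- f[k, 1]; j <- f[k, 2]; l <- f[k, 3]
      a <- midpoint(i, j); b <- midpoint(j, l); c_ <- midpoint(l, i)
      newf <- rbind(newf, c(i, a, c_), c(j, b, a), c(l, c_, b), c(a, b, c_))
    }
    f <- newf
  }
  v <- v / row_norms(v) * radius
  v <- sweep(v, 2, center, "+")
  mesh_geometry(v, f)
}
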