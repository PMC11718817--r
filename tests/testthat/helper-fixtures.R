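# Fixture builders and independent brute-force oracles used across tests.
# All fixtures are generated in code under fixed seeds; nothing binary.

make_track <- function(positions, id = "trk1", dt = 0.5, cell_type = "ctl",
                       genotype = "WT", treatment = "n/a",
                       apoptotic = NA) {
  p <- if (is.matrix(positions)) positions else
    matrix(positions, ncol = 3, byrow = TRUE)
  tibble::tibble(
    track_id = id, cell_type = cell_type, genotype = genotype,
    treatment = treatment,
    frame_index = seq_len(nrow(p)) - 1L,
    t = (seq_len(nrow(p)) - 1L) * dt,
    x = p[, 1], y = p[, 2], z = p[, 3],
    apoptotic = apoptotic)
}

random_tracks <- function(n_tracks, n_frames, dt = 0.5, seed = 1) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n_tracks), function(i) {
    make_track(t(replicate(n_frames, stats::rnorm(3, sd = 5))),
               id = sprintf("rnd_%03d", i), dt = dt)
  })
}

# Axis-aligned cube as 8 vertices / 12 triangles, outward-oriented.
cube_mesh_raw <- function(side = 1, center = c(0, 0, 0)) {
  h <- side / 2
  v <- rbind(
    c(-h, -h, -h), c(h, -h, -h), c(h, h, -h), c(-h, h, -h),
    c(-h, -h, h), c(h, -h, h), c(h, h, h), c(-h, h, h))
  v <- sweep(v, 2, center, "+")
  f <- rbind(
    c(1, 3, 2), c(1, 4, 3),   # bottom (z = -h)
    c(5, 6, 7), c(5, 7, 8),   # top
    c(1, 2, 6), c(1, 6, 5),   # front (y = -h)
    c(2, 3, 7), c(2, 7, 6),   # right
    c(3, 4, 8), c(3, 8, 7),   # back
    c(4, 1, 5), c(4, 5, 8))   # left
  list(vertices = v, faces = f)
}

cube_mesh <- function(side = 1, center = c(0, 0, 0)) {
  cm <- cube_mesh_raw(side, center)
  spheromotion::mesh_geometry(cm$vertices, cm$faces)
}

# Independent ray-parity containment oracle: rays along +z (the package
# implementation uses a different, oblique ray direction).
oracle_ray_parity <- function(vertices, faces, p) {
  crossings <- 0
  for (k in seq_len(nrow(faces))) {
    a <- vertices[faces[k, 1], ]
    b <- vertices[faces[k, 2], ]
    c_ <- vertices[faces[k, 3], ]
    # project onto xy; check p is inside triangle and surface above p
    d <- (b[2] - c_[2]) * (a[1] - c_[1]) + (c_[1] - b[1]) * (a[2] - c_[2])
    if (abs(d) < 1e-14) next
    l1 <- ((b[2] - c_[2]) * (p[1] - c_[1]) +
             (c_[1] - b[1]) * (p[2] - c_[2])) / d
    l2 <- ((c_[2] - a[2]) * (p[1] - c_[1]) +
             (a[1] - c_[1]) * (p[2] - c_[2])) / d
    l3 <- 1 - l1 - l2
    if (l1 < 0 || l2 < 0 || l3 < 0) next
    zhit <- l1 * a[3] + l2 * b[3] + l3 * c_[3]
    if (zhit > p[3] + 1e-12) crossings <- crossings + 1
  }
  crossings %% 2 == 1
}

# Brute-force O(n^2) union-find over the pairwise-distance graph.
oracle_fragments <- function(p, link_radius, min_cells) {
  n <- nrow(p)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && sqrt(sum((p[i, ] - p[j, ])^2)) <= link_radius) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, numeric(1))
  sum(table(roots) >= min_cells)
}

# Textbook Welch statistic and two-tailed p, written independently.
oracle_welch <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

# Textbook Grubbs statistic and critical value, written independently.
oracle_grubbs <- function(x, alpha = 0.05) {
  n <- length(x)
  g <- max(abs(x - mean(x))) / stats::sd(x)
  tq <- stats::qt(1 - alpha / (2 * n), n - 2)
  list(g = g, critical = (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2)))
}

# A tiny simulated scenario used by several suites (fast, fixed seed).
small_scenario <- function(seed = 5L, n_ctl = 40L, n_tumor = 30L,
                           n_frames = 31L, ...) {
  cfg <- spheromotion::default_scenario("early_4h", "WT", "none",
                                        seed = seed)
  cfg$n_ctl <- as.integer(n_ctl)
  cfg$n_tumor <- as.integer(n_tumor)
  cfg$n_macrophage <- 0L
  cfg$n_frames <- as.integer(n_frames)
  extra <- list(...)
  for (nm in names(extra)) cfg[[nm]] <- extra[[nm]]
  cfg
}
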