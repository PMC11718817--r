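# Internal helpers shared across modules.

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Polynomial rolling hash over the bytes of a string, folded into
# [1, 2^31 - 2]. Used to derive per-cell RNG substreams and the run-manifest
# parameter hash: stable across platforms, needs no external digest
# dependency. All arithmetic stays below 2^53 so doubles are exact.
string_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 0
  for (b in bytes) h <- (h * 1048573 + b) %% 2147483563
  as.integer(h + 1)
}

# Deterministic substream seed for one simulated cell.
substream_seed <- function(seed, cell_id) {
  string_hash(paste0("spheromotion:", seed, ":", cell_id))
}

# Short hex-ish hash of an R object (via its deparsed form) for run manifests.
object_hash <- function(x) {
  sprintf("%08x", string_hash(paste(deparse(x), collapse = "\n")))
}

# Row-wise Euclidean norms of an n x 3 matrix.
row_norms <- function(m) sqrt(rowSums(m * m))

# Normalize rows of an n x 3 matrix to unit length; zero rows stay zero.
normalize_rows <- function(m) {
  n <- row_norms(m)
  n[n == 0] <- 1
  m / n
}

# One uniform unit vector in R^3 from three standard normals.
unit_vector3 <- function(z) {
  n <- sqrt(sum(z^2))
  if (n == 0) c(1, 0, 0) else z / n
}

# Sample the cosine w of the angle between consecutive directions for a
# von Mises-Fisher perturbation with concentration kappa, by inverse CDF
# from a uniform u. kappa = 0 gives the isotropic cosine (w = 2u - 1);
# kappa = Inf gives w = 1 (ballistic limit).
vmf_cosine <- function(u, kappa) {
  if (!is.finite(kappa)) return(rep(1, length(u)))
  if (kappa == 0) return(2 * u - 1)
  if (kappa < 1e-6) return(2 * u - 1)
  # stable form of 1 + log(u + (1 - u) e^{-2k}) / k
  w <- 1 + (log(u + (1 - u) * exp(-2 * kappa))) / kappa
  pmin(1, pmax(-1, w))
}

# Rotate previous unit directions `mu` (n x 3) to new directions with
# cosines `w` against mu and uniformly random tangent components built
# from the standard-normal matrix `z` (n x 3).
perturb_directions <- function(mu, w, z) {
  # component of z orthogonal to mu
  proj <- rowSums(z * mu)
  tang <- z - proj * mu
  tn <- row_norms(tang)
  deg <- tn < 1e-12
  if (any(deg)) {
    # fall back to an arbitrary orthogonal direction
    alt <- cbind(-mu[, 2], mu[, 1], rep(0, nrow(mu)))
    altn <- row_norms(alt)
    alt[altn < 1e-12, ] <- matrix(rep(c(0, -1, 0), sum(altn < 1e-12)),
                                  ncol = 3, byrow = TRUE)
    tang[deg, ] <- alt[deg, , drop = FALSE]
    tn <- row_norms(tang)
  }
  tang <- tang / tn
  s <- sqrt(pmax(0, 1 - w^2))
  normalize_rows(w * mu + s * tang)
}

# log-normal parameters from a desired mean and coefficient of variation
lognormal_pars <- function(mean, cv) {
  sdlog2 <- log(1 + cv^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

stopifnot_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict) x > min else x >= min)
  if (!ok) {
    abort(sprintf("`%s` must be a single finite number %s %s.",
                  name, if (strict) ">" else ">=", format(min)),
          class = "spheromotion_config_error")
  }
  invisible(x)
}
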