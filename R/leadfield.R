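#' Construct a lead field object
#'
#' A lead field couples unit-amplitude cortical sources to scalp electrode
#' potentials: `y = M x + eps`, with `M` of size d channels x n sources.
#' Sources use a fixed-orientation model (one column per source).
#'
#' @param matrix numeric d x n gain matrix (arbitrary linear potential units).
#' @param channel_labels character vector of d unique electrode labels.
#' @param channel_positions numeric d x 3 electrode positions, mm.
#' @param source_positions numeric n x 3 source positions, mm.
#' @param source_orientations numeric n x 3 unit orientation vectors.
#' @return An object of class `leadfield`.
#' @export
leadfield <- function(matrix, channel_labels, channel_positions,
                      source_positions, source_orientations) {
  matrix <- as.matrix(matrix)
  channel_positions <- as.matrix(channel_positions)
  source_positions <- as.matrix(source_positions)
  source_orientations <- as.matrix(source_orientations)
  d <- nrow(matrix); n <- ncol(matrix)
  if (d < 2 || n < 2)
    stop("leadfield needs at least 2 channels and 2 sources", call. = FALSE)
  if (!all(is.finite(matrix)))
    stop("leadfield matrix has non-finite entries", call. = FALSE)
  if (length(channel_labels) != d)
    stop_mismatch("channel_labels length", length(channel_labels), d)
  if (anyDuplicated(channel_labels))
    stop("channel_labels must be unique", call. = FALSE)
  if (!identical(dim(channel_positions), c(d, 3L)))
    stop_mismatch("channel_positions dim", paste(dim(channel_positions), collapse = "x"),
                  paste0(d, "x3"))
  if (!identical(dim(source_positions), c(n, 3L)))
    stop_mismatch("source_positions dim", paste(dim(source_positions), collapse = "x"),
                  paste0(n, "x3"))
  if (!identical(dim(source_orientations), c(n, 3L)))
    stop_mismatch("source_orientations dim", paste(dim(source_orientations), collapse = "x"),
                  paste0(n, "x3"))
  onorm <- sqrt(rowSums(source_orientations^2))
  if (any(abs(onorm - 1) > 1e-9))
    stop("source_orientations rows must have unit norm", call. = FALSE)
  ctr <- colMeans(source_positions)
  src_r <- sqrt(rowSums(sweep(source_positions, 2, ctr)^2))
  ch_r <- sqrt(rowSums(sweep(channel_positions, 2, ctr)^2))
  if (any(ch_r < max(src_r) - 1e-6))
    stop("channel_positions must lie outside or on the source bounding sphere",
         call. = FALSE)
  structure(list(matrix = matrix,
                 channel_labels = as.character(channel_labels),
                 channel_positions = channel_positions,
                 source_positions = source_positions,
                 source_orientations = source_orientations),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %d channels x %d sources\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' @export
dim.leadfield <- function(x) dim(x$matrix)

# Quasi-uniform points on the unit sphere (golden-angle spiral).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Seeded uniform random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qrd)
  q <- q %*% diag(sign(diag(qr.R(qrd))))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

# Legendre-series coefficients for the scalp potential of a radial unit dipole
# inside three concentric conductive shells. Radii are scaled to the outer
# radius (rho3 = 1); `b` is the dipole radius in the same scale. Returns
# c[1..order] such that V(gamma) = sum_n c_n P_n(cos gamma) / (4 pi sigma1)
# on the outer surface (potentials in arbitrary linear units).
#
# Per degree n the interior/shell expansions are matched at both interfaces
# (continuity of V and of sigma dV/dr) with a zero-current outer boundary;
# shell bases are scaled so the 5x5 systems stay well conditioned at high n.
shell_series_coefs <- function(b, rho, sigma, order) {
  rho1 <- rho[1]; rho2 <- rho[2]
  s1 <- sigma[1]; s2 <- sigma[2]; s3 <- sigma[3]
  coefs <- numeric(order)
  for (n in seq_len(order)) {
    p1 <- n * b^(n - 1) / rho1^(n + 1)          # primary potential at rho1
    pd1 <- -(n + 1) * n * b^(n - 1) / rho1^(n + 2)  # its radial derivative
    t12 <- (rho1 / rho2)^n
    t12b <- (rho1 / rho2)^(n + 1)
    # unknowns: A1, A2, B2, A3, B3 in scaled bases
    A <- rbind(
      c(1, -t12, -1, 0, 0),
      c(s1 * n / rho1, -s2 * n / rho1 * t12, s2 * (n + 1) / rho1, 0, 0),
      c(0, 1, t12b, -rho2^n, -1),
      c(0, s2 * n / rho2, -s2 * (n + 1) / rho2 * t12b,
        -s3 * n * rho2^(n - 1), s3 * (n + 1) / rho2),
      c(0, 0, 0, n, -(n + 1) * rho2^(n + 1)))
    rhs <- c(-p1, -s1 * pd1, 0, 0, 0)
    u <- solve(A, rhs)
    coefs[n] <- u[4] + u[5] * rho2^(n + 1)
  }
  coefs / (4 * pi * s1)
}

# Evaluate sum_n c_n P_n(x) for a matrix of x = cos(gamma) values.
legendre_series <- function(coefs, x) {
  p_prev <- array(1, dim = dim(x))
  p_cur <- x
  acc <- coefs[1] * p_cur
  if (length(coefs) >= 2) {
    for (n in 2:length(coefs)) {
      p_next <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
      acc <- acc + coefs[n] * p_next
      p_prev <- p_cur
      p_cur <- p_next
    }
  }
  acc
}

#' Analytic three-shell spherical lead field
#'
#' Deterministic, download-free stand-in for a realistic volume-conductor
#' model: electrodes quasi-uniform on the outer (scalp) shell, radially
#' oriented sources quasi-uniform on an inner cortical sphere, and gains from
#' the analytic concentric-three-shell dipole potential (Legendre series,
#' truncated at `series_order`). Defaults model brain/skull/scalp shells of
#' 80/86/92 mm with conductivities 0.33/0.0042/0.33 S/m.
#'
#' @param n_channels number of electrodes (>= 2).
#' @param n_sources number of cortical sources (>= 2).
#' @param shell_radii strictly increasing brain/skull/scalp radii, mm.
#' @param shell_conductivities positive conductivities, S/m.
#' @param seed integer seed controlling the (rotated) electrode layout; the
#'   same arguments and seeds give a bit-identical lead field.
#' @param source_seed integer seed controlling the source-grid rotation
#'   (default `seed + 1000`). Keep `seed` fixed and vary `source_seed` /
#'   `n_sources` to build forward and inverse models that share the
#'   electrode array but not the source grid, so inverse solutions are never
#'   computed on the grid that generated the data.
#' @param source_radius radius of the cortical source sphere, mm (inside the
#'   innermost shell).
#' @param series_order truncation order of the Legendre series. The default
#'   (100) keeps the truncation error below ~1e-8 relative for the default
#'   geometry.
#' @return A [leadfield].
#' @export
#' @examples
#' lf <- build_spherical_leadfield(32, 60, seed = 1)
#' dim(lf$matrix)
build_spherical_leadfield <- function(n_channels, n_sources,
                                      shell_radii = c(80, 86, 92),
                                      shell_conductivities = c(0.33, 0.0042, 0.33),
                                      seed = 1,
                                      source_seed = seed + 1000,
                                      source_radius = 71,
                                      series_order = 100) {
  if (n_channels < 2) stop("n_channels must be >= 2", call. = FALSE)
  if (n_sources < 2) stop("n_sources must be >= 2", call. = FALSE)
  if (length(shell_radii) != 3 || any(diff(shell_radii) <= 0))
    stop("invalid geometry: shell_radii must be 3 strictly increasing values",
         call. = FALSE)
  if (length(shell_conductivities) != 3 || any(shell_conductivities <= 0))
    stop("shell_conductivities must be 3 positive values", call. = FALSE)
  if (source_radius <= 0 || source_radius >= shell_radii[1])
    stop("source_radius must lie inside the innermost shell", call. = FALSE)

  r3 <- shell_radii[3]
  rho <- shell_radii[1:2] / r3
  b <- source_radius / r3

  local_seed(seed, {
    ch_dir <- fibonacci_sphere(n_channels) %*% random_rotation()
  })
  local_seed(source_seed, {
    src_dir <- fibonacci_sphere(n_sources) %*% random_rotation()
  })
  coefs <- shell_series_coefs(b, rho, shell_conductivities, series_order)
  cosg <- ch_dir %*% t(src_dir)
  cosg[cosg > 1] <- 1
  cosg[cosg < -1] <- -1
  M <- legendre_series(coefs, cosg)

  leadfield(matrix = M,
            channel_labels = sprintf("E%03d", seq_len(n_channels)),
            channel_positions = ch_dir * r3,
            source_positions = src_dir * source_radius,
            source_orientations = src_dir)
}
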