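#' Spherical head specification
#'
#' Analytic forward model geometry: sensors on the surface of a unit
#' conducting sphere, dipolar sources strictly inside with fixed unit
#' orientations. Stands in for a subject-specific boundary-element model;
#' adequate for the region-level simulations and inverse tests shipped
#' here.
#'
#' @param sensor_positions n_sensors x 3 matrix of unit-sphere coordinates.
#' @param source_positions n_sources x 3 matrix, all with radius < 1.
#' @param source_orientations n_sources x 3 matrix of unit vectors (a zero
#'   row is allowed only for a source at the origin, where the radial
#'   direction is undefined).
#' @param sensor_names,source_ids labels; defaults generated.
#' @return An object of class `spherical_head`.
#' @export
spherical_head <- function(sensor_positions, source_positions,
                           source_orientations,
                           sensor_names = NULL, source_ids = NULL) {
  sensor_positions <- as.matrix(sensor_positions)
  source_positions <- as.matrix(source_positions)
  source_orientations <- as.matrix(source_orientations)
  rs <- sqrt(rowSums(sensor_positions^2))
  if (any(abs(rs - 1) > 1e-6))
    stop("all sensors must lie on the unit sphere surface")
  rq <- sqrt(rowSums(source_positions^2))
  if (any(rq >= 1 - 1e-9))
    stop("source on/outside the sphere (radius must be < 1): source ",
         paste(which(rq >= 1 - 1e-9), collapse = ", "))
  no <- sqrt(rowSums(source_orientations^2))
  bad <- abs(no - 1) > 1e-6 & !(no < 1e-12 & rq < 1e-12)
  if (any(bad))
    stop("source orientations must be unit vectors")
  if (is.null(sensor_names))
    sensor_names <- sprintf("S%02d", seq_len(nrow(sensor_positions)))
  if (is.null(source_ids)) source_ids <- seq_len(nrow(source_positions))
  structure(list(sensor_positions = sensor_positions,
                 source_positions = source_positions,
                 source_orientations = source_orientations,
                 sensor_names = sensor_names, source_ids = source_ids),
            class = "spherical_head")
}

#' Standard 10--20 electrode coordinates on the unit sphere
#'
#' 21 scalp electrodes of the international 10--20 system placed on an
#' idealized spherical head (vertex Cz at the pole, nasion towards +y,
#' right ear towards +x). Angles follow the conventional 10/20 percentage
#' spacing; ear electrodes A1/A2 sit below the equator.
#'
#' @return matrix 21 x 3 with rownames = electrode labels.
#' @export
montage_1020 <- function() {
  # label, inclination from vertex (deg), azimuth (deg, 0 = right ear,
  # 90 = nasion, counter-clockwise seen from above)
  tab <- rbind(
    c("Fp1",  90, 108), c("Fp2",  90,  72),
    c("F7",   90, 144), c("F3",   60, 129), c("Fz",  45,  90),
    c("F4",   60,  51), c("F8",   90,  36),
    c("T3",   90, 180), c("C3",   45, 180), c("Cz",   0,   0),
    c("C4",   45,   0), c("T4",   90,   0),
    c("T5",   90, 216), c("P3",   60, 231), c("Pz",  45, 270),
    c("P4",   60, 309), c("T6",   90, 324),
    c("O1",   90, 252), c("O2",   90, 288),
    c("A1",  115, 180), c("A2",  115,   0))
  incl <- as.numeric(tab[, 2]) * pi / 180
  az <- as.numeric(tab[, 3]) * pi / 180
  xyz <- cbind(sin(incl) * cos(az), sin(incl) * sin(az), cos(incl))
  rownames(xyz) <- tab[, 1]
  colnames(xyz) <- c("x", "y", "z")
  xyz
}

#' Deterministic region-centroid source grid
#'
#' Places `n` sources quasi-uniformly at radius `radius` inside the unit
#' sphere: `n/2` points from a Fibonacci lattice on the left (x < 0)
#' hemisphere, mirrored through the x = 0 plane for the right hemisphere.
#' Orientations are radial.
#'
#' @param n even number of sources.
#' @param radius source shell radius (< 1), default 0.75.
#' @return list with `positions` and `orientations` (n x 3 each).
#' @export
source_grid <- function(n, radius = 0.75) {
  stopifnot(n %% 2 == 0, radius > 0, radius < 1)
  m <- n / 2
  i <- seq_len(m) - 0.5
  # Fibonacci lattice on the upper hemisphere, then tilt into x < 0
  z <- i / m                       # cos(inclination) in (0, 1): upper half
  phi <- pi * (1 + sqrt(5)) * i
  pts <- cbind(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
  # rotate upper hemisphere (+z) onto left hemisphere (-x)
  rot <- matrix(c(0, 0, -1,  0, 1, 0,  1, 0, 0), 3, 3, byrow = TRUE)
  left <- pts %*% t(rot)
  right <- left; right[, 1] <- -right[, 1]
  pos <- radius * rbind(left, right)
  list(positions = pos, orientations = radial_orientations(pos))
}

#' Radial orientations for source positions
#'
#' Unit vectors along each position; a source at the origin has no defined
#' radial direction and gets the zero vector (hence a zero dipole moment).
#'
#' @param positions n x 3 matrix.
#' @return n x 3 matrix of unit (or zero) vectors.
#' @export
radial_orientations <- function(positions) {
  positions <- as.matrix(positions)
  r <- sqrt(rowSums(positions^2))
  ori <- positions / ifelse(r > 1e-12, r, 1)
  ori[r <= 1e-12, ] <- 0
  ori
}

#' Default spherical head for the packaged pipeline
#'
#' 21-channel 10--20 montage on the unit sphere with `n_regions` radial
#' region-centroid sources at radius 0.75.
#'
#' @param n_regions number of sources (default 68).
#' @param source_radius source shell radius.
#' @return A [spherical_head].
#' @export
default_head <- function(n_regions = 68L, source_radius = 0.75) {
  el <- montage_1020()
  src <- source_grid(n_regions, radius = source_radius)
  spherical_head(el, src$positions, src$orientations,
                 sensor_names = rownames(el),
                 source_ids = seq_len(n_regions))
}

#' Lead field of the homogeneous conducting sphere
#'
#' Analytic surface potential of a current dipole inside a homogeneous
#' conducting sphere with insulating exterior (unit radius, conductivity
#' `sigma`), evaluated by its exact Legendre expansion: with the dipole at
#' radius b on the polar axis, radial moment m_r and tangential moment m_t,
#'
#'   V(theta, phi) = 1/(4 pi sigma) sum_{n>=1} (2n+1)/n b^{n-1}
#'                   [ n m_r P_n(cos theta) + m_t P_n^1(cos theta) cos phi ]
#'
#' (P_n^1 without the Condon--Shortley phase). The series is truncated when
#' the geometric tail bound falls below 1e-14.
#'
#' @param head a [spherical_head].
#' @param sigma conductivity in S/m (default 0.33; a common scalp/brain
#'   value). Only a global scale for unit-radius geometry.
#' @return A [lead_field]: sensors x sources matrix of scalp potential per
#'   unit dipole moment.
#' @export
make_lead_field <- function(head, sigma = 0.33) {
  stopifnot(inherits(head, "spherical_head"))
  ns <- nrow(head$sensor_positions)
  nq <- nrow(head$source_positions)
  G <- matrix(0, ns, nq)
  for (q in seq_len(nq)) {
    G[, q] <- sphere_dipole_potential(head$sensor_positions,
                                      head$source_positions[q, ],
                                      head$source_orientations[q, ],
                                      sigma = sigma)
  }
  zero_pos <- sqrt(rowSums(head$source_positions^2)) < 1e-12
  if (any(colSums(abs(G)) < 1e-300 & !zero_pos))
    stop("lead field has an all-zero column for an off-centre source")
  lead_field(G, sensor_names = head$sensor_names,
             source_ids = head$source_ids)
}

# Potential at unit-sphere surface points `sensors` (n x 3) of a unit
# conducting sphere, from a dipole at `pos` with moment vector `mom`.
sphere_dipole_potential <- function(sensors, pos, mom, sigma = 0.33,
                                    tol = 1e-14) {
  sensors <- as.matrix(sensors)
  b <- sqrt(sum(pos^2))
  if (b >= 1 - 1e-9) stop("dipole on/outside the sphere")
  if (sum(mom^2) < 1e-300) return(rep(0, nrow(sensors)))
  if (b < 1e-12) {
    # central dipole: only the n = 1 term survives
    return(3 * (sensors %*% mom)[, 1] / (4 * pi * sigma))
  }
  rq <- pos / b
  m_r <- sum(mom * rq)
  t_vec <- mom - m_r * rq
  m_t <- sqrt(sum(t_vec^2))
  t_hat <- if (m_t > 1e-14) t_vec / m_t else c(0, 0, 0)

  cth <- pmin(pmax(sensors %*% rq, -1), 1)[, 1]   # cos(theta) per sensor
  perp <- sensors - outer(cth, rq)                 # sensor component normal to axis
  pn <- sqrt(rowSums(perp^2))
  cph <- ifelse(pn > 1e-14, (perp %*% t_hat)[, 1] / pn, 0)
  sth <- sqrt(pmax(1 - cth^2, 0))

  n_terms <- max(60L, ceiling(log(tol) / log(max(b, 0.05))))
  # Legendre recurrences: P_n and Q_n = sin(theta) * dP_n/dcos
  p_prev <- rep(1, length(cth)); p_cur <- cth
  tot <- 3 * (m_r * p_cur + m_t * sth * cph)    # n = 1: P_1 = c, P_1^1 = sin
  fpow <- 1
  for (n in 2:n_terms) {
    p_next <- ((2 * n - 1) * cth * p_cur - (n - 1) * p_prev) / n
    p_prev <- p_cur; p_cur <- p_next
    # P_n^1 = n (P_{n-1} - c P_n) / sin(theta); 0 at the poles
    pn1 <- ifelse(sth > 1e-12, n * (p_prev - cth * p_cur) / sth, 0)
    fpow <- fpow * b
    tot <- tot + (2 * n + 1) / n * fpow *
      (n * m_r * p_cur + m_t * pn1 * cph)
  }
  tot / (4 * pi * sigma)
}

#' Lead field container
#'
#' @param G sensors x sources matrix: scalp potential per unit dipole
#'   moment.
#' @param sensor_names,source_ids labels.
#' @return An object of class `lead_field`.
#' @export
lead_field <- function(G, sensor_names = NULL, source_ids = NULL) {
  G <- as.matrix(G)
  if (any(!is.finite(G))) stop("lead field must be finite")
  if (is.null(sensor_names)) sensor_names <- sprintf("S%02d", seq_len(nrow(G)))
  if (is.null(source_ids)) source_ids <- seq_len(ncol(G))
  rownames(G) <- sensor_names
  structure(list(G = G, sensor_names = sensor_names, source_ids = source_ids),
            class = "lead_field")
}

#' Read/write a lead field as TSV (sensors x sources, row/col names kept)
#' @param lf a [lead_field]; `path` file path.
#' @return `read_lead_field` returns a [lead_field].
#' @export
write_lead_field <- function(lf, path) {
  tab <- as.data.frame(lf$G)
  colnames(tab) <- paste0("src", lf$source_ids)
  tab <- cbind(sensor = lf$sensor_names, tab)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lead_field
#' @export
read_lead_field <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  G <- as.matrix(tab[, -1, drop = FALSE])
  lead_field(G, sensor_names = tab[[1]],
             source_ids = as.integer(sub("^src", "", colnames(G))))
}
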