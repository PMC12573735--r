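# Wall-force construction: for an impact direction n-hat the molecule is
# compressed between two rigid walls. The total force is the impact pressure
# times the molecular cross-section pi R^2; it is split uniformly over the
# atoms, each atom pushed toward the dividing plane through the origin
# perpendicular to n-hat.

#' Impact direction in spherical coordinates
#'
#' @param theta Polar angle in `[0, pi]` (radians).
#' @param phi Azimuthal angle (radians); reduced modulo `2*pi`.
#' @return An object of class `direction`: list with `theta`, `phi` and the
#'   Cartesian `unit_vector` `(sin(theta)cos(phi), sin(theta)sin(phi),
#'   cos(theta))`.
#' @export
#' @examples
#' direction(pi / 2, 0)$unit_vector  # x axis
direction <- function(theta, phi) {
  stopifnot(length(theta) == 1L, length(phi) == 1L,
            is.finite(theta), is.finite(phi))
  if (theta < 0 || theta > pi) stop("theta must lie in [0, pi]")
  phi <- phi %% (2 * pi)
  structure(list(theta = theta, phi = phi,
                 unit_vector = c(sin(theta) * cos(phi),
                                 sin(theta) * sin(phi),
                                 cos(theta))),
            class = "direction")
}

as_unit_vector <- function(dir) {
  if (inherits(dir, "direction")) dir$unit_vector
  else {
    v <- as.numeric(dir)
    stopifnot(length(v) == 3L)
    v / sqrt(sum(v^2))
  }
}

#' Milling model configuration
#'
#' Collects the tunable parameters of the wall-force model.
#'
#' @param pressure Impact pressure P in GPa (>= 0). Ball-milling impact
#'   pressures are typically of the order of a few GPa.
#' @param grid_n Polar grid size N; the angular sweep uses N polar times 2N
#'   azimuthal midpoint nodes (2N^2 directions). N = 100 gives stable
#'   averages.
#' @param delta_mode Per-atom padding \eqn{\delta_i} added to the molecular
#'   radius: `"vdw"` (van der Waals radii, the default), `"none"`
#'   (\eqn{\delta_i = 0}), or `"constant"` (a single value, see
#'   `delta_constant`).
#' @param delta_constant Padding in Angstrom when `delta_mode = "constant"`.
#' @param radius_mode `"directional"` (default): R(theta, phi) is the
#'   maximal distance of any padded atom from the compression axis, i.e. the
#'   radius of the cross-section actually presented to the walls;
#'   `"global"`: the direction-independent bound
#'   \eqn{R = \max_i(\lVert r_i\rVert + \delta_i)}.
#' @param weight_scheme How the total force is split over atoms; only
#'   `"uniform"` (\eqn{\alpha_i = 1/N_{atoms}}) is implemented.
#' @return An object of class `milling_config`.
#' @export
milling_config <- function(pressure = 1, grid_n = 100,
                           delta_mode = c("vdw", "none", "constant"),
                           delta_constant = NULL,
                           radius_mode = c("directional", "global"),
                           weight_scheme = "uniform") {
  delta_mode <- match.arg(delta_mode)
  radius_mode <- match.arg(radius_mode)
  stopifnot(length(pressure) == 1L, is.finite(pressure), pressure >= 0,
            length(grid_n) == 1L, grid_n >= 1, grid_n == as.integer(grid_n))
  if (delta_mode == "constant") {
    if (is.null(delta_constant) || !is.finite(delta_constant) ||
        delta_constant < 0) {
      stop("delta_mode = 'constant' requires a nonnegative delta_constant")
    }
  } else {
    delta_constant <- NULL
  }
  if (!identical(weight_scheme, "uniform")) {
    stop("unknown weight scheme '", weight_scheme,
         "': only 'uniform' is implemented")
  }
  structure(list(pressure = pressure, grid_n = as.integer(grid_n),
                 delta_mode = delta_mode, delta_constant = delta_constant,
                 radius_mode = radius_mode, weight_scheme = weight_scheme),
            class = "milling_config")
}

#' @export
print.milling_config <- function(x, ...) {
  cat("Milling configuration\n")
  cat("  pressure   :", x$pressure, "GPa\n")
  cat("  grid       : N =", x$grid_n, "(", 2 * x$grid_n^2, "directions )\n")
  cat("  delta mode :", x$delta_mode,
      if (x$delta_mode == "constant") paste0("(", x$delta_constant, " A)"),
      "\n")
  cat("  radius mode:", x$radius_mode, "\n")
  invisible(x)
}

# Per-atom padding radii delta_i for the configured mode.
delta_radii <- function(structure, config) {
  switch(config$delta_mode,
         vdw = structure$vdw_radii,
         none = rep(0, n_atoms(structure)),
         constant = rep(config$delta_constant, n_atoms(structure)))
}

#' Molecular radius for an impact direction
#'
#' In `"global"` mode this is the direction-independent
#' \eqn{R = \max_i(\lVert r_i\rVert + \delta_i)}; in `"directional"` mode it
#' is the maximal perpendicular distance of any atom from the compression
#' axis plus its padding, which tracks the nonspherical shape of the
#' molecule. The structure must already be centered at its mass-weighted
#' centroid.
#'
#' @param structure Centered [molecular_structure()].
#' @param dir A [direction()] (or length-3 vector, normalised internally).
#' @param config A [milling_config()].
#' @return Radius in Angstrom.
#' @export
directional_radius <- function(structure, dir, config = milling_config()) {
  delta <- delta_radii(structure, config)
  coords <- structure$coordinates
  if (config$radius_mode == "global") {
    max(sqrt(rowSums(coords^2)) + delta)
  } else {
    n_hat <- as_unit_vector(dir)
    proj <- drop(coords %*% n_hat)
    perp2 <- pmax(rowSums(coords^2) - proj^2, 0)
    max(sqrt(perp2) + delta)
  }
}

#' Partition atoms into forward/backward hemispheres
#'
#' The plane through the origin perpendicular to the impact direction splits
#' the (centered) molecule in two: atom i is `"forward"` iff
#' \eqn{r_i \cdot \hat n \ge 0}, else `"backward"`. Atoms exactly on the
#' plane are assigned forward by convention.
#'
#' @inheritParams directional_radius
#' @return Character vector (`"forward"`/`"backward"`), one entry per atom.
#' @export
partition_hemispheres <- function(structure, dir) {
  n_hat <- as_unit_vector(dir)
  ifelse(drop(structure$coordinates %*% n_hat) >= 0, "forward", "backward")
}

#' Total compressive wall force
#'
#' \eqn{F_{mec}(\theta,\phi) = P \cdot \pi R(\theta,\phi)^2}, with
#' 1 GPa Angstrom^2 = 0.01 nN.
#'
#' @param pressure Impact pressure in GPa.
#' @param radius Molecular radius in Angstrom.
#' @return Force in nN.
#' @export
#' @examples
#' total_force(1, 1)     # 0.0314 nN
#' total_force(1, 6.68)  # about 1.4 nN
total_force <- function(pressure, radius) {
  stopifnot(all(pressure >= 0), all(radius >= 0))
  pressure * pi * radius^2 * gpa_angstrom2_to_nn
}

#' Build the wall-force field for one impact direction
#'
#' Computes the molecular radius, the hemisphere partition and the per-atom
#' force vectors \eqn{F_i = \alpha_i F_{mec} \hat n_i} with uniform weights
#' \eqn{\alpha_i = 1/N_{atoms}} and \eqn{\hat n_i = -\hat n} for forward
#' atoms, \eqn{+\hat n} for backward atoms: both walls push the molecule
#' toward the dividing plane.
#'
#' @inheritParams directional_radius
#' @return An object of class `wall_force_field`: list with `direction`,
#'   `radius` (Angstrom), `cross_section` (Angstrom^2), `total_force` (nN),
#'   `hemisphere` (per-atom labels) and `atom_forces` (n x 3 matrix, nN).
#' @export
build_force_field <- function(structure, dir, config = milling_config()) {
  if (!inherits(dir, "direction")) {
    v <- as_unit_vector(dir)
    dir <- direction(acos(max(-1, min(1, v[3L]))), atan2(v[2L], v[1L]))
  }
  n_hat <- dir$unit_vector
  radius <- directional_radius(structure, dir, config)
  f_mec <- total_force(config$pressure, radius)
  hemi <- partition_hemispheres(structure, dir)
  sign_i <- ifelse(hemi == "forward", -1, 1)
  n <- n_atoms(structure)
  forces <- (f_mec / n) * sign_i %o% n_hat
  structure(
    list(direction = dir, radius = radius, cross_section = pi * radius^2,
         total_force = f_mec, hemisphere = hemi, atom_forces = forces,
         config = config),
    class = "wall_force_field")
}

#' @export
print.wall_force_field <- function(x, ...) {
  cat("Wall-force field\n")
  cat(sprintf("  direction : theta = %.4f, phi = %.4f rad\n",
              x$direction$theta, x$direction$phi))
  cat(sprintf("  radius    : %.4f Angstrom (cross-section %.3f A^2)\n",
              x$radius, x$cross_section))
  cat(sprintf("  F_mec     : %.5f nN over %d atoms (%d forward / %d backward)\n",
              x$total_force, length(x$hemisphere),
              sum(x$hemisphere == "forward"),
              sum(x$hemisphere == "backward")))
  invisible(x)
}
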