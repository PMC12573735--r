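# Mechanical work along the reaction displacement and its directional map.
# The forces are frozen at the reactant frame (they are taken constant along
# the reaction path), so the line integral of the work reduces to the dot
# product of the per-atom forces with the aligned displacements. Sign
# convention: positive work lowers the barrier, delta_Ea_mec = -W_mec.

#' Mechanical work of a wall-force field along the reaction displacement
#'
#' \eqn{W_{mec} = \sum_i F_i \cdot \Delta r_i}, evaluated in nN Angstrom
#' and converted to kcal/mol (1 nN Angstrom = 14.3933 kcal/mol).
#'
#' @param field A [build_force_field()] result.
#' @param path An [align_endpoints()] result with the same atom count and
#'   order.
#' @return Work in kcal/mol.
#' @export
mechanical_work <- function(field, path) {
  stopifnot(inherits(field, "wall_force_field"),
            inherits(path, "aligned_path"))
  if (nrow(field$atom_forces) != nrow(path$displacements)) {
    stop("force field and aligned path refer to different atom counts (",
         nrow(field$atom_forces), " vs ", nrow(path$displacements), ")")
  }
  sum(field$atom_forces * path$displacements) * nn_angstrom_to_kcal_mol
}

#' Barrier change caused by mechanical work
#'
#' \eqn{\Delta E_{a,mec} = -W_{mec}}: positive work lowers the activation
#' barrier, negative work opposes the reaction progress.
#'
#' @param work Mechanical work in kcal/mol.
#' @return Barrier change in kcal/mol.
#' @export
barrier_shift <- function(work) -work

#' Midpoint grid over the unit sphere
#'
#' Cell-centered nodes with equal angular steps
#' \eqn{\Delta\theta = \Delta\phi = \pi/N}: N polar values
#' \eqn{\theta_k = (k + 1/2)\pi/N} on \eqn{(0, \pi)} and 2N azimuthal values
#' \eqn{\phi_l = (l + 1/2)\pi/N} on \eqn{(0, 2\pi)}, i.e. \eqn{2N^2}
#' directions. Midpoint placement avoids the poles (where
#' \eqn{\sin\theta = 0}) and the duplicated \eqn{\phi = 0/2\pi} seam.
#'
#' @param grid_n Polar grid size N.
#' @return List with `thetas`, `phis`, `dtheta`, `dphi`.
#' @export
spherical_grid <- function(grid_n) {
  stopifnot(grid_n >= 1)
  step <- pi / grid_n
  list(thetas = (seq_len(grid_n) - 0.5) * step,
       phis = (seq_len(2 * grid_n) - 0.5) * step,
       dtheta = step, dphi = step)
}

#' Sweep the wall-force model over all impact directions
#'
#' Aligns the endpoints once, then for each of the \eqn{2N^2} directions of
#' the midpoint grid builds the wall-force field on the centered reactant
#' and records the mechanical work and the barrier change
#' \eqn{\Delta E_{a,mec}(\theta, \phi)}, together with their spherical
#' average and extrema.
#'
#' @param endpoints A [reaction_endpoints()] pair.
#' @param config A [milling_config()].
#' @param path Optionally a precomputed [align_endpoints()] result (used by
#'   [pressure_scan()] to share one alignment across pressures).
#' @return An object of class `directional_map`: list with `grid_n`,
#'   `thetas`, `phis`, `work` and `delta_ea` (N x 2N matrices, kcal/mol,
#'   `delta_ea = -work` elementwise), `average` (the quadrature average of
#'   `delta_ea`), `extrema` (min/max with their directions), `radius`
#'   (N x 2N matrix or scalar, Angstrom), `config` and the `alignment`.
#' @export
sweep_directions <- function(endpoints, config = milling_config(),
                             path = NULL) {
  stopifnot(inherits(endpoints, "reaction_endpoints"),
            inherits(config, "milling_config"))
  if (is.null(path)) path <- align_endpoints(endpoints)
  coords <- path$reactant_centered
  n <- nrow(coords)
  delta <- delta_radii(endpoints$reactant, config)
  grid <- spherical_grid(config$grid_n)
  big_n <- config$grid_n
  th <- rep(grid$thetas, times = 2L * big_n)
  ph <- rep(grid$phis, each = big_n)
  n_hat <- rbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  proj <- coords %*% n_hat                       # r_i . n-hat
  if (config$radius_mode == "global") {
    radius <- max(sqrt(rowSums(coords^2)) + delta)
    radius_vec <- radius
  } else {
    r2 <- rowSums(coords^2)
    radius_vec <- rep(-Inf, ncol(proj))
    for (i in seq_len(n)) {
      radius_vec <- pmax(radius_vec,
                         sqrt(pmax(r2[i] - proj[i, ]^2, 0)) + delta[i])
    }
    radius <- matrix(radius_vec, nrow = big_n)
  }
  f_mec <- total_force(config$pressure, radius_vec)
  sign_i <- ifelse(proj >= 0, -1, 1)             # n-hat_i = sign_i * n-hat
  disp_proj <- path$displacements %*% n_hat      # delta-r_i . n-hat
  w <- (f_mec / n) * colSums(sign_i * disp_proj) * nn_angstrom_to_kcal_mol
  work <- matrix(w, nrow = big_n)
  delta_ea <- -work
  map <- structure(
    list(grid_n = big_n, thetas = grid$thetas, phis = grid$phis,
         dtheta = grid$dtheta, dphi = grid$dphi,
         work = work, delta_ea = delta_ea,
         radius = radius, config = config, alignment = path),
    class = "directional_map")
  map$average <- spherical_average(map)
  map$extrema <- map_extrema(map)
  map
}

map_extrema <- function(map) {
  i_min <- which.min(map$delta_ea)   # first grid index on ties
  i_max <- which.max(map$delta_ea)
  idx <- function(i) c(row = (i - 1L) %% map$grid_n + 1L,
                       col = (i - 1L) %/% map$grid_n + 1L)
  mk <- function(i) {
    ij <- idx(i)
    list(value = map$delta_ea[i], theta = map$thetas[ij["row"]],
         phi = map$phis[ij["col"]])
  }
  list(min = mk(i_min), max = mk(i_max))
}

#' Spherical (quadrature) average over the direction grid
#'
#' Discrete surface integral over the unit sphere on the midpoint grid,
#' \eqn{\langle f \rangle = \frac{1}{4\pi}\sum_{\theta,\phi}
#' f(\theta,\phi)\sin\theta\,\Delta\theta\,\Delta\phi}.
#'
#' For a `directional_map` the averaged field is `delta_ea`; a plain N x 2N
#' matrix of values on the [spherical_grid()] of matching size can be
#' averaged directly.
#'
#' @param x A `directional_map` or an N x 2N numeric matrix.
#' @param ... Unused.
#' @return The average, in the units of the field.
#' @export
spherical_average <- function(x, ...) UseMethod("spherical_average")

#' @export
spherical_average.directional_map <- function(x, ...) {
  spherical_average.matrix(x$delta_ea)
}

#' @export
spherical_average.matrix <- function(x, ...) {
  n <- nrow(x)
  if (is.null(n) || n < 1L || ncol(x) != 2L * n) {
    stop("expected an N x 2N matrix of values on the midpoint grid")
  }
  grid <- spherical_grid(n)
  sum(x * sin(grid$thetas)) * grid$dtheta * grid$dphi / (4 * pi)
}

#' Quadrature normalisation of the midpoint grid
#'
#' \eqn{\frac{1}{4\pi}\sum \sin\theta\,\Delta\theta\,\Delta\phi}; within
#' 1e-3 of unity at N = 100.
#'
#' @param grid_n Polar grid size N.
#' @return The discrete approximation of 1.
#' @export
grid_normalization <- function(grid_n) {
  spherical_average.matrix(matrix(1, grid_n, 2L * grid_n))
}

#' @export
print.directional_map <- function(x, ...) {
  cat("Directional map of the barrier change (kcal/mol)\n")
  cat(sprintf("  grid      : N = %d (%d directions)\n", x$grid_n,
              2L * x$grid_n^2))
  cat(sprintf("  <dEa,mec> : %+.4f kcal/mol at P = %g GPa\n", x$average,
              x$config$pressure))
  cat(sprintf("  min       : %+.4f at theta = %.3f, phi = %.3f rad\n",
              x$extrema$min$value, x$extrema$min$theta, x$extrema$min$phi))
  cat(sprintf("  max       : %+.4f at theta = %.3f, phi = %.3f rad\n",
              x$extrema$max$value, x$extrema$max$theta, x$extrema$max$phi))
  invisible(x)
}

#' Long-format view of a directional map
#'
#' @param x A `directional_map`.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @return data.frame with columns `theta_rad`, `phi_rad`, `work_kcal_mol`,
#'   `delta_ea_kcal_mol`, one row per grid direction.
#' @export
as.data.frame.directional_map <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(theta_rad = rep(x$thetas, times = length(x$phis)),
             phi_rad = rep(x$phis, each = length(x$thetas)),
             work_kcal_mol = as.vector(x$work),
             delta_ea_kcal_mol = as.vector(x$delta_ea))
}
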