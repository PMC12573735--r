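# Removal of overall translation and rotation between the reaction
# endpoints. The transition state is superimposed onto the minimum by a
# mass-weighted Kabsch rotation (proper rotations only), so the remaining
# per-atom displacement field carries only the intrinsic deformation of the
# reaction step.

#' Bundle reactant and transition-state geometries
#'
#' Validates that the two endpoint structures of a reaction step list the
#' same atoms in the same order, and optionally attaches the baseline
#' activation energy obtained from electronic-structure calculations.
#'
#' @param reactant [molecular_structure()] of the minimum (reactant or
#'   pre-reactive adduct).
#' @param transition [molecular_structure()] of the transition state.
#' @param baseline_barrier Optional activation energy E_a in kcal/mol in the
#'   absence of mechanical forces.
#' @return An object of class `reaction_endpoints`.
#' @export
reaction_endpoints <- function(reactant, transition,
                               baseline_barrier = NULL) {
  stopifnot(inherits(reactant, "molecular_structure"),
            inherits(transition, "molecular_structure"))
  if (n_atoms(reactant) != n_atoms(transition)) {
    stop("reactant and transition state have different atom counts (",
         n_atoms(reactant), " vs ", n_atoms(transition), ")")
  }
  if (!identical(reactant$elements, transition$elements)) {
    i <- which(reactant$elements != transition$elements)[1L]
    stop("element sequence mismatch at atom ", i, ": ",
         reactant$elements[i], " vs ", transition$elements[i],
         " (atom order must match index-by-index)")
  }
  if (!is.null(baseline_barrier)) {
    baseline_barrier <- as.numeric(baseline_barrier)
    stopifnot(length(baseline_barrier) == 1L, is.finite(baseline_barrier))
  }
  structure(list(reactant = reactant, transition = transition,
                 baseline_barrier = baseline_barrier),
            class = "reaction_endpoints")
}

#' @export
print.reaction_endpoints <- function(x, ...) {
  cat("Reaction endpoints:", n_atoms(x$reactant), "atoms\n")
  if (!is.null(x$baseline_barrier)) {
    cat("  baseline barrier:", format(x$baseline_barrier, digits = 4),
        "kcal/mol\n")
  }
  invisible(x)
}

#' Mass-weighted centroid
#'
#' @param structure A [molecular_structure()].
#' @return Length-3 numeric vector, \eqn{\sum_i m_i r_i / \sum_i m_i}
#'   (Angstrom).
#' @export
#' @examples
#' s <- molecular_structure(c("H", "H"), rbind(c(0, 0, -1), c(0, 0, 1)))
#' mass_weighted_centroid(s)  # origin
mass_weighted_centroid <- function(structure) {
  stopifnot(inherits(structure, "molecular_structure"))
  unname(drop(crossprod(structure$coordinates, structure$masses))) /
    sum(structure$masses)
}

# Optimal proper rotation mapping `moving` onto `target` (both already
# centered), minimising the mass-weighted RMSD. Returns the 3x3 rotation.
kabsch_rotation <- function(moving, target, masses) {
  a <- crossprod(moving, target * masses)   # sum_i m_i t_i r_i^T
  if (max(abs(a)) < 1e-14) {
    warning("degenerate (near-coincident) geometry: covariance is zero, ",
            "using the identity rotation")
    return(diag(3))
  }
  s <- svd(a)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

#' Superimpose the transition state on the reactant
#'
#' Centers both geometries at their mass-weighted centroids, then rotates
#' the transition state by the mass-weighted Kabsch rotation (reflections
#' excluded by a determinant correction) so that the residual displacement
#' field \eqn{\Delta r_i} carries no overall translation
#' (\eqn{\sum_i m_i \Delta r_i = 0}) and no overall rotation
#' (\eqn{\sum_i m_i r_i \times \Delta r_i = 0}) between the endpoints.
#'
#' @param endpoints A [reaction_endpoints()] pair (or two structures, in
#'   which case they are bundled first).
#' @param transition Optional second structure when `endpoints` is the
#'   reactant structure.
#' @return An object of class `aligned_path`: list with
#'   `reactant_centered` and `transition_aligned` coordinate matrices
#'   (Angstrom, mass centroids at the origin), `displacements`
#'   (`transition_aligned - reactant_centered`), `rotation` (the 3x3 Kabsch
#'   matrix), `mw_rmsd` (mass-weighted RMSD in Angstrom), and the residual
#'   momentum norms `residual_linear` / `residual_angular` used as
#'   alignment diagnostics.
#' @export
align_endpoints <- function(endpoints, transition = NULL) {
  if (!inherits(endpoints, "reaction_endpoints")) {
    endpoints <- reaction_endpoints(endpoints, transition)
  }
  m <- endpoints$reactant$masses
  rc <- sweep(endpoints$reactant$coordinates, 2L,
              mass_weighted_centroid(endpoints$reactant))
  tc <- sweep(endpoints$transition$coordinates, 2L,
              mass_weighted_centroid(endpoints$transition))
  rot <- kabsch_rotation(tc, rc, m)
  ta <- tc %*% t(rot)
  dimnames(ta) <- dimnames(rc)
  disp <- ta - rc
  mw_rmsd <- sqrt(sum(m * rowSums(disp^2)) / sum(m))
  structure(
    list(reactant_centered = rc, transition_aligned = ta,
         displacements = disp, rotation = rot, mw_rmsd = mw_rmsd,
         masses = m,
         residual_linear = sqrt(sum(colSums(m * disp)^2)),
         residual_angular = sqrt(sum(colSums(m * cross3(rc, disp))^2))),
    class = "aligned_path")
}

#' @export
print.aligned_path <- function(x, ...) {
  cat("Aligned reaction path:", nrow(x$reactant_centered), "atoms\n")
  cat("  mass-weighted RMSD:", format(x$mw_rmsd, digits = 6), "Angstrom\n")
  cat("  |net displacement| :", format(x$residual_linear, digits = 3),
      "amu Angstrom\n")
  cat("  |net rotation-like|:", format(x$residual_angular, digits = 3),
      "amu Angstrom^2\n")
  invisible(x)
}

# Row-wise cross product of two n x 3 matrices.
cross3 <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}
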