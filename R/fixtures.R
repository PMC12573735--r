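# Synthetic reactant/transition-state pairs with analytically known
# mechanical responses. These make every stage of the model testable
# without any electronic-structure data: axial compressions have a closed
# form for the work along the compression axis, isotropic contractions have
# a known sign in every direction, and rigid decoys must be removed exactly
# by the alignment. Fixtures carry geometry only -- no attempt is made to
# mimic real potential-energy surfaces.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Random proper rotation matrix
#'
#' Uniform (Haar) random rotation from the QR decomposition of a Gaussian
#' matrix, sign-corrected to determinant +1.
#'
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return 3 x 3 rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  draw <- function() {
    qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
    q <- qr.Q(qr_)
    q <- q %*% diag(sign(diag(qr.R(qr_))))
    if (det(q) < 0) q[, 1L] <- -q[, 1L]
    q
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Random centered cloud of atoms, mass-weighted centroid at the origin.
random_cloud <- function(n_atoms, spread, elements) {
  coords <- matrix(stats::runif(3 * n_atoms, -spread, spread), n_atoms, 3)
  s <- molecular_structure(elements, coords)
  s$coordinates <- sweep(s$coordinates, 2L, mass_weighted_centroid(s))
  s
}

#' Axial-compression fixture with closed-form work
#'
#' Builds a reactant whose atoms are mirror-paired across the z = 0 plane
#' and a "transition state" in which every atom has moved by `d` toward
#' that plane. For a compression along z the work has the closed form
#' \eqn{W_{mec} = F_{mec} \cdot d}: each of the N atoms is pushed toward
#' the plane with force \eqn{F_{mec}/N} and moves `d` along it, so the
#' per-atom contributions telescope. The mirror pairing keeps the centroid
#' fixed and the mass-weighted Kabsch rotation at the identity, so the
#' displacement field survives alignment unchanged.
#'
#' @param n_atoms Even atom count (atoms come in mirror pairs).
#' @param d Displacement of every atom toward the plane (Angstrom); must
#'   be smaller than the minimum |z| so no atom crosses the plane.
#' @param spread Half-width of the random cloud (Angstrom).
#' @param seed RNG seed; fixed seed gives identical output.
#' @param element Element symbol used for all atoms (one element keeps the
#'   closed form independent of masses).
#' @return A [reaction_endpoints()] pair with attribute `axial_d = d`
#'   (the closed-form work per unit force along z).
#' @export
make_axial_pair <- function(n_atoms = 8, d = 0.5, spread = 3, seed = 1,
                            element = "C") {
  if (n_atoms < 2 || n_atoms %% 2 != 0) {
    stop("axial fixtures need an even n_atoms >= 2 (mirror pairs)")
  }
  stopifnot(d >= 0)
  half <- n_atoms %/% 2L
  upper <- with_seed(seed, cbind(
    stats::runif(half, -spread, spread),
    stats::runif(half, -spread, spread),
    stats::runif(half, d + 0.5, d + 0.5 + spread)))
  coords <- rbind(upper, upper %*% diag(c(1, 1, -1)))
  reactant <- molecular_structure(rep(element, n_atoms), coords,
                                  label = "axial reactant")
  ts_coords <- coords
  ts_coords[, 3L] <- ts_coords[, 3L] - d * sign(ts_coords[, 3L])
  ts <- molecular_structure(rep(element, n_atoms), ts_coords,
                            label = "axial transition state")
  out <- reaction_endpoints(reactant, ts)
  attr(out, "axial_d") <- d
  out
}

#' Isotropic contraction/expansion fixture
#'
#' The transition state is the reactant scaled by `factor` about its mass
#' centroid. For `factor < 1` every atom moves toward every dividing
#' plane, so the compressive walls perform positive work and
#' \eqn{\Delta E_{a,mec} < 0} in all directions; `factor > 1` (expansion,
#' the model of a reverse reaction step) gives the opposite sign
#' everywhere. `factor = 1` is rejected; expansion must be requested
#' explicitly.
#'
#' @param n_atoms Atom count.
#' @param factor Scaling factor (0 < factor < 1, or > 1 with
#'   `allow_expansion = TRUE`).
#' @param allow_expansion Permit `factor > 1`.
#' @param spread,seed As in [make_axial_pair()].
#' @param elements Element symbol(s) for the atoms, recycled; mix elements
#'   to exercise mass weighting.
#' @return A [reaction_endpoints()] pair.
#' @export
make_contraction_pair <- function(n_atoms = 20, factor = 0.9,
                                  allow_expansion = FALSE, spread = 3,
                                  seed = 1, elements = "C") {
  stopifnot(n_atoms >= 1, factor > 0)
  if (factor == 1) stop("factor = 1 gives identical endpoints; ",
                        "choose factor < 1 (contraction)")
  if (factor > 1 && !allow_expansion) {
    stop("factor > 1 models an expansion (reverse step); ",
         "set allow_expansion = TRUE to request it deliberately")
  }
  elements <- rep_len(elements, n_atoms)
  reactant <- with_seed(seed, random_cloud(n_atoms, spread, elements))
  reactant$label <- "contraction reactant"
  ts <- molecular_structure(elements, factor * reactant$coordinates,
                            label = "contraction transition state")
  reaction_endpoints(reactant, ts)
}

#' Random displacement fixture
#'
#' A seeded random cloud with a seeded random Gaussian displacement field
#' of RMS size `magnitude`; no closed form, used for property tests
#' (frame invariance, grid convergence).
#'
#' @param n_atoms Atom count.
#' @param magnitude RMS per-coordinate displacement (Angstrom).
#' @param spread,seed,elements As in [make_contraction_pair()].
#' @return A [reaction_endpoints()] pair.
#' @export
make_random_pair <- function(n_atoms = 20, magnitude = 0.3, spread = 3,
                             seed = 1, elements = "C") {
  stopifnot(n_atoms >= 1, magnitude >= 0)
  elements <- rep_len(elements, n_atoms)
  with_seed(seed, {
    reactant <- random_cloud(n_atoms, spread, elements)
    reactant$label <- "random reactant"
    disp <- matrix(stats::rnorm(3 * n_atoms, sd = magnitude), n_atoms, 3)
    ts <- molecular_structure(elements, reactant$coordinates + disp,
                              label = "random transition state")
    reaction_endpoints(reactant, ts)
  })
}

#' Apply a rigid-motion decoy to the transition state
#'
#' Rotates and translates the transition-state geometry by a (seeded)
#' random rigid motion. Because the alignment removes overall translation
#' and rotation, all downstream results must match the undecoyed pair to
#' alignment tolerance; with no seed and no motion supplied the endpoints
#' are returned bitwise unchanged.
#'
#' @param endpoints A [reaction_endpoints()] pair.
#' @param rotation Optional 3 x 3 proper rotation; default drawn from
#'   `seed`, identity if `seed` is `NULL`.
#' @param translation Optional length-3 shift (Angstrom); default drawn
#'   from `seed`, zero if `seed` is `NULL`.
#' @param seed RNG seed for the random motion.
#' @return A [reaction_endpoints()] pair with the decoyed transition state.
#' @export
apply_rigid_decoy <- function(endpoints, rotation = NULL,
                              translation = NULL, seed = NULL) {
  stopifnot(inherits(endpoints, "reaction_endpoints"))
  if (!is.null(seed)) {
    moves <- with_seed(seed, list(r = random_rotation(),
                                  t = stats::runif(3, -5, 5)))
    if (is.null(rotation)) rotation <- moves$r
    if (is.null(translation)) translation <- moves$t
  }
  if (is.null(rotation) && is.null(translation)) return(endpoints)
  if (is.null(rotation)) rotation <- diag(3)
  if (is.null(translation)) translation <- c(0, 0, 0)
  ts <- endpoints$transition
  ts$coordinates <- sweep(ts$coordinates %*% t(rotation), 2L,
                          -as.numeric(translation))
  reaction_endpoints(endpoints$reactant, ts,
                     baseline_barrier = endpoints$baseline_barrier)
}

#' Write a fixture pair as XYZ files
#'
#' Emits standard XYZ files so synthetic fixtures double as end-to-end
#' inputs for the command-line interface.
#'
#' @param endpoints A [reaction_endpoints()] pair.
#' @param dir Output directory (created if needed).
#' @param basename Stem for the two file names.
#' @return Named character vector with elements `reactant` and `ts`.
#' @export
write_endpoints <- function(endpoints, dir = ".", basename = "fixture") {
  stopifnot(inherits(endpoints, "reaction_endpoints"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(reactant = file.path(dir, paste0(basename, "_reactant.xyz")),
             ts = file.path(dir, paste0(basename, "_ts.xyz")))
  write_xyz(endpoints$reactant, paths[["reactant"]])
  write_xyz(endpoints$transition, paths[["ts"]])
  paths
}
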