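# Shared helpers and independent oracles for the test suite.

# Brute-force line integral of the work: discretise the straight segment
# from reactant to transition state into `nseg` steps and accumulate
# sum_i F_i . dr_i step by step (forces constant along the path). Serves
# as the independent oracle for the closed-form dot-product work.
work_line_integral <- function(field, path, nseg = 1e4) {
  step <- path$displacements / nseg
  w_nna <- 0
  for (k in seq_len(nseg)) {
    w_nna <- w_nna + sum(field$atom_forces * step)
  }
  w_nna * nn_angstrom_to_kcal_mol
}

# Apply one rigid motion to both endpoint structures of a pair.
rotate_endpoints <- function(endpoints, rotation, translation = c(0, 0, 0)) {
  move <- function(s) {
    s$coordinates <- sweep(s$coordinates %*% t(rotation), 2L, -translation)
    s
  }
  reaction_endpoints(move(endpoints$reactant), move(endpoints$transition),
                     baseline_barrier = endpoints$baseline_barrier)
}

# Mass-weighted RMSD between centered reactant and centered transition
# state under an arbitrary rotation of the latter (used to verify that the
# Kabsch rotation is optimal by brute-force sampling).
mw_rmsd_under_rotation <- function(endpoints, rotation) {
  m <- endpoints$reactant$masses
  center <- function(s) sweep(s$coordinates, 2L, mass_weighted_centroid(s))
  rc <- center(endpoints$reactant)
  tc <- center(endpoints$transition) %*% t(rotation)
  sqrt(sum(m * rowSums((tc - rc)^2)) / sum(m))
}

# Centered copy of a structure (radius/partition operations expect the
# mass-weighted centroid at the origin).
centered <- function(structure) {
  structure$coordinates <- sweep(structure$coordinates, 2L,
                                 mass_weighted_centroid(structure))
  structure
}

# Value field on the midpoint grid: f(theta, phi) evaluated as an N x 2N
# matrix, for quadrature tests.
grid_field <- function(grid_n, f) {
  g <- spherical_grid(grid_n)
  outer(g$thetas, g$phis, f)
}

# Antipodal image of an N x 2N map: (theta, phi) -> (pi - theta, phi + pi)
# maps grid node [k, l] to [N + 1 - k, l + N (mod 2N)].
antipodal_map <- function(m) {
  n <- nrow(m)
  m[n:1, c((n + 1):(2 * n), 1:n)]
}

# Norms of the row-wise cross products F_i x n-hat (zero when every force
# is parallel or antiparallel to the impact direction).
cross_norms <- function(forces, n_hat) {
  nmat <- matrix(n_hat, nrow(forces), 3, byrow = TRUE)
  cr <- cbind(forces[, 2] * nmat[, 3] - forces[, 3] * nmat[, 2],
              forces[, 3] * nmat[, 1] - forces[, 1] * nmat[, 3],
              forces[, 1] * nmat[, 2] - forces[, 2] * nmat[, 1])
  sqrt(rowSums(cr^2))
}

write_xyz_text <- function(lines) {
  path <- tempfile(fileext = ".xyz")
  writeLines(lines, path)
  path
}
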