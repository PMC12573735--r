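test_that("direction builds the expected unit vector", {
  d <- direction(pi / 2, 0)
  expect_equal(d$unit_vector, c(1, 0, 0))
  expect_equal(sqrt(sum(direction(1.1, 2.2)$unit_vector^2)), 1,
               tolerance = 1e-12)
  expect_equal(direction(0.5, 2 * pi + 0.25)$phi, 0.25)
  expect_error(direction(-0.1, 0), "theta")
})

test_that("milling configuration validates its fields", {
  expect_error(milling_config(pressure = -1), "pressure")
  expect_error(milling_config(delta_mode = "constant"), "delta_constant")
  expect_error(milling_config(weight_scheme = "by-distance"),
               "weight scheme")
  cfg <- milling_config(delta_mode = "constant", delta_constant = 0.5)
  expect_equal(cfg$delta_constant, 0.5)
})

test_that("directional radius matches hand calculations", {
  origin <- molecular_structure("C", c(0, 0, 0))
  cfg0 <- milling_config(delta_mode = "none")
  expect_equal(directional_radius(origin, direction(0, 0), cfg0), 0)
  expect_equal(directional_radius(origin, direction(0, 0),
                                  milling_config(delta_mode = "none",
                                                 radius_mode = "global")),
               0)
  atom <- molecular_structure("C", c(3, 0, 0), vdw_radii = 1.2)
  cfg <- milling_config(delta_mode = "vdw")
  # compression along z: perpendicular distance 3 plus padding 1.2
  expect_equal(directional_radius(atom, direction(0, 0), cfg), 4.2)
  expect_equal(directional_radius(atom, direction(0, 0),
                                  milling_config(radius_mode = "global")),
               4.2)
  # compression along x: the atom sits on the axis, only padding remains
  expect_equal(directional_radius(atom, direction(pi / 2, 0), cfg), 1.2)
})

test_that("directional radius never exceeds the global radius", {
  s <- centered(make_random_pair(n_atoms = 20, seed = 12,
                                 elements = c("C", "H", "O"))$reactant)
  cfg_dir <- milling_config()
  cfg_glob <- milling_config(radius_mode = "global")
  r_glob <- directional_radius(s, direction(0, 0), cfg_glob)
  set.seed(13)
  for (i in 1:50) {
    d <- direction(runif(1, 0, pi), runif(1, 0, 2 * pi))
    expect_lte(directional_radius(s, d, cfg_dir), r_glob)
  }
})

test_that("hemisphere partition follows the sign of r . n-hat", {
  s <- molecular_structure(c("C", "C"), rbind(c(0, 0, 1), c(0, 0, -1)))
  expect_identical(partition_hemispheres(s, direction(0, 0)),
                   c("forward", "backward"))
  plane_atom <- molecular_structure("C", c(1, 0, 0))
  expect_identical(partition_hemispheres(plane_atom, direction(0, 0)),
                   "forward")  # documented tie convention
  s3 <- centered(make_random_pair(n_atoms = 15, seed = 14)$reactant)
  d <- direction(1.0, 0.7)
  labels <- partition_hemispheres(s3, d)
  flipped <- partition_hemispheres(s3, -d$unit_vector)
  on_plane <- abs(drop(s3$coordinates %*% d$unit_vector)) < 1e-14
  expect_identical(flipped[!on_plane],
                   ifelse(labels[!on_plane] == "forward", "backward",
                          "forward"))
})

test_that("total force implements P * pi * R^2 with the GPa-to-nN bridge", {
  expect_identical(total_force(0, 3.7), 0)
  expect_equal(total_force(1, 1), 0.0314159, tolerance = 1e-6)
  # about 1.4 nN for a 6.68 Angstrom molecular sphere at 1 GPa
  expect_equal(total_force(1, 6.68), 1.40, tolerance = 0.01)
  # exactly linear in P, quadratic in R
  expect_identical(total_force(4, 2.3), 4 * total_force(1, 2.3))
  expect_equal(total_force(1, 2 * 2.3), 4 * total_force(1, 2.3),
               tolerance = 1e-15)
})

test_that("force field splits the total force uniformly toward the plane", {
  s <- molecular_structure(c("C", "C"), rbind(c(0, 0, 1), c(0, 0, -1)))
  # global radius 1 with no padding; choose P so that F_mec = 1 nN
  cfg <- milling_config(pressure = 100 / pi, delta_mode = "none",
                        radius_mode = "global")
  f <- build_force_field(s, direction(0, 0), cfg)
  expect_equal(f$total_force, 1)
  expect_equal(f$atom_forces,
               rbind(c(0, 0, -0.5), c(0, 0, 0.5)))  # 0.5 nN toward plane
  expect_identical(f$hemisphere, c("forward", "backward"))
})

test_that("per-atom force magnitudes sum to the total force", {
  s <- centered(make_random_pair(n_atoms = 20, seed = 15)$reactant)
  f <- build_force_field(s, direction(0.9, 4.1), milling_config())
  expect_equal(sum(sqrt(rowSums(f$atom_forces^2))), f$total_force,
               tolerance = 1e-9)
  # every atomic force is (anti)parallel to the impact direction
  cross <- cross_norms(f$atom_forces, f$direction$unit_vector)
  expect_lt(max(cross), 1e-12)
})

test_that("net force follows the hemisphere imbalance identity", {
  for (seed in c(16, 17)) {
    s <- centered(make_random_pair(n_atoms = 13, seed = seed)$reactant)
    d <- direction(0.4 + seed / 20, seed)
    f <- build_force_field(s, d, milling_config())
    n_fwd <- sum(f$hemisphere == "forward")
    n_back <- sum(f$hemisphere == "backward")
    expect_equal(colSums(f$atom_forces),
                 ((n_back - n_fwd) / length(f$hemisphere)) *
                   f$total_force * d$unit_vector,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("the construction is antipodally symmetric off the plane", {
  s <- centered(make_random_pair(n_atoms = 17, seed = 18)$reactant)
  cfg <- milling_config()
  d <- direction(0.8, 1.3)
  anti <- direction(pi - 0.8, 1.3 + pi)
  f1 <- build_force_field(s, d, cfg)
  f2 <- build_force_field(s, anti, cfg)
  expect_equal(f2$radius, f1$radius, tolerance = 1e-12)
  expect_equal(f2$atom_forces, f1$atom_forces, tolerance = 1e-9)
})
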