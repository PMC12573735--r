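test_that("mechanical work implements the force-displacement dot product", {
  ep <- make_random_pair(n_atoms = 10, magnitude = 0, seed = 19)
  path <- align_endpoints(ep)
  s <- centered(ep$reactant)
  f <- build_force_field(s, direction(0.3, 0.4), milling_config())
  expect_equal(mechanical_work(f, path), 0)  # zero displacement

  # two-atom toy: each atom carries 0.5 nN toward the plane and moves
  # 0.5 Angstrom toward it -> W = 0.5 nN Angstrom = 7.1966 kcal/mol
  s2 <- molecular_structure(c("C", "C"), rbind(c(0, 0, 1), c(0, 0, -1)))
  ts2 <- molecular_structure(c("C", "C"),
                             rbind(c(0, 0, 0.5), c(0, 0, -0.5)))
  path2 <- align_endpoints(reaction_endpoints(s2, ts2))
  cfg <- milling_config(pressure = 100 / pi, delta_mode = "none",
                        radius_mode = "global")
  f2 <- build_force_field(s2, direction(0, 0), cfg)
  expect_equal(f2$atom_forces[1, 3], -0.5)
  w <- mechanical_work(f2, path2)
  expect_equal(w, 0.5 * 1e-19 * 6.02214076e23 / 4184)  # hand conversion
  expect_equal(w, 7.19663, tolerance = 1e-5)

  # reversed displacements (expansion) flip the sign exactly
  # F_mec = P * pi * 0.5^2 * 0.01 = 0.25 nN; both atoms move 0.5 A outward
  path_rev <- align_endpoints(reaction_endpoints(ts2, s2))
  f_rev <- build_force_field(ts2, direction(0, 0), cfg)
  expect_equal(mechanical_work(f_rev, path_rev),
               -0.25 * 0.5 * nn_angstrom_to_kcal_mol)
  expect_error(mechanical_work(f2, align_endpoints(
    make_random_pair(n_atoms = 5, seed = 1))), "atom counts")
})

test_that("barrier shift is minus the work", {
  expect_identical(barrier_shift(7.197), -7.197)
  expect_identical(barrier_shift(0), 0)
  expect_identical(barrier_shift(-2.5), 2.5)
})

test_that("work equals the brute-force line integral (oracle)", {
  fixtures <- list(
    make_axial_pair(n_atoms = 6, d = 0.4, seed = 20),
    make_contraction_pair(n_atoms = 9, factor = 0.85, seed = 21,
                          elements = c("C", "H", "O")),
    make_random_pair(n_atoms = 8, magnitude = 0.5, seed = 22))
  for (ep in fixtures) {
    path <- align_endpoints(ep)
    s <- ep$reactant
    s$coordinates <- path$reactant_centered
    for (d in list(direction(0.2, 1), direction(2.1, 4.4))) {
      f <- build_force_field(s, d, milling_config())
      w <- mechanical_work(f, path)
      w_int <- work_line_integral(f, path, nseg = 1e4)
      expect_equal(w_int, w, tolerance = 1e-9)
    }
  }
})

test_that("sweep matches the per-direction composition", {
  ep <- make_random_pair(n_atoms = 7, magnitude = 0.4, seed = 23,
                         elements = c("C", "N"))
  cfg <- milling_config(grid_n = 6)
  map <- sweep_directions(ep, cfg)
  path <- map$alignment
  s <- ep$reactant
  s$coordinates <- path$reactant_centered
  for (k in seq_along(map$thetas)) {
    for (l in seq_along(map$phis)) {
      f <- build_force_field(s, direction(map$thetas[k], map$phis[l]), cfg)
      expect_equal(map$work[k, l], mechanical_work(f, path),
                   tolerance = 1e-12)
      if (cfg$radius_mode == "directional") {
        expect_equal(map$radius[k, l], f$radius, tolerance = 1e-12)
      }
    }
  }
})

test_that("directional map satisfies its stored invariants", {
  ep <- make_contraction_pair(n_atoms = 12, factor = 0.9, seed = 24)
  map <- sweep_directions(ep, milling_config(grid_n = 30))
  expect_identical(dim(map$work), c(30L, 60L))
  expect_identical(map$delta_ea, -map$work)
  expect_equal(spherical_average(map), map$average, tolerance = 1e-12)
  expect_equal(map$extrema$min$value, min(map$delta_ea))
  expect_equal(map$extrema$max$value, max(map$delta_ea))
  df <- as.data.frame(map)
  expect_identical(names(df), c("theta_rad", "phi_rad", "work_kcal_mol",
                                "delta_ea_kcal_mol"))
  expect_identical(nrow(df), 1800L)
  expect_equal(df$delta_ea_kcal_mol, -df$work_kcal_mol)
})

test_that("identical endpoints give an identically zero map", {
  s <- make_random_pair(n_atoms = 6, seed = 25)$reactant
  map <- sweep_directions(reaction_endpoints(s, s),
                          milling_config(grid_n = 12))
  expect_lt(max(abs(map$delta_ea)), 1e-12)
  expect_lt(abs(map$average), 1e-12)
})

test_that("quadrature reproduces analytic spherical integrals", {
  n <- 100
  expect_equal(spherical_average(grid_field(n, function(th, ph) 1 + 0 * th)),
               1, tolerance = 1e-3)
  expect_equal(spherical_average(grid_field(n, function(th, ph) cos(th))),
               0, tolerance = 1e-12)
  expect_equal(spherical_average(grid_field(n, function(th, ph) cos(th)^2)),
               1 / 3, tolerance = 1e-3)
  expect_equal(grid_normalization(n), 1, tolerance = 1e-3)
  expect_error(spherical_average(matrix(1, 4, 9)), "N x 2N")
})

test_that("pressure scan shares alignment and reports per-pressure results", {
  ep <- make_contraction_pair(n_atoms = 10, factor = 0.9, seed = 26)
  cfg <- milling_config(grid_n = 15)
  scan <- pressure_scan(ep, c(0, 1, 2), cfg)
  expect_length(scan$results, 3)
  expect_identical(scan$results[[1]]$average, 0)
  df <- as.data.frame(scan)
  expect_equal(df$pressure_gpa, c(0, 1, 2))
  expect_identical(df$delta_ea_avg[3], 2 * df$delta_ea_avg[2])
  empty <- pressure_scan(ep, numeric(0), cfg)
  expect_length(empty$results, 0)
})

test_that("pathway comparison reports the mechanically favored pathway", {
  ep_strong <- make_contraction_pair(n_atoms = 10, factor = 0.85,
                                     seed = 27)
  ep_weak <- make_contraction_pair(n_atoms = 10, factor = 0.95, seed = 27)
  fit_s <- mill(ep_strong$reactant, ep_strong$transition, grid_n = 15,
                label = "strong")
  fit_w <- mill(ep_weak$reactant, ep_weak$transition, grid_n = 15,
                label = "weak")
  cmp <- compare_pathways(fit_s, fit_w)
  expect_identical(cmp$favored, "strong")
  expect_equal(cmp$difference, fit_s$average - fit_w$average)
  expect_lt(cmp$difference, 0)

  same <- compare_pathways(fit_s, fit_s, labels = c("x", "x"))
  expect_identical(same$difference, 0)
  expect_identical(same$favored, "none")

  fit_other <- mill(ep_weak$reactant, ep_weak$transition, grid_n = 20)
  expect_error(compare_pathways(fit_s, fit_other), "configurations")
})

test_that("comparison arithmetic matches the endo/exo style report", {
  # synthetic averages standing in for two cycloaddition pathways
  mk <- function(avg, label) {
    f <- mill(make_contraction_pair(n_atoms = 6, factor = 0.9,
                                    seed = 28)$reactant,
              make_contraction_pair(n_atoms = 6, factor = 0.9,
                                    seed = 28)$transition,
              grid_n = 5, label = label)
    f$average <- avg
    f
  }
  cmp <- compare_pathways(mk(-3.88, "endo"), mk(-2.90, "exo"))
  expect_equal(cmp$difference, -0.98)
  expect_identical(cmp$favored, "endo")
  cmp2 <- compare_pathways(mk(0.5, "fwd"), mk(-0.5, "rev"))
  expect_identical(cmp2$favored, "rev")
})
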