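test_that("double well and LJ pair have their analytic stationary points", {
  dw <- build_surface("double_well_1d")
  expect_equal(dw$energy(0), 0)
  expect_equal(dw$gradient(0), 0)
  expect_lt(surface_hessian(dw, 0)[1, 1], 0)        # x = 0 is a maximum
  expect_equal(dw$energy(1 / sqrt(2)), -0.25, tolerance = 1e-12)

  lj <- build_surface("lj_cluster", list(n_atoms = 2))
  x <- c(0, 0, 0, 2^(1 / 6), 0, 0)
  expect_equal(lj$energy(x), -1, tolerance = 1e-12)
  expect_equal(max(abs(lj$gradient(x))), 0, tolerance = 1e-10)
})

test_that("Muller-Brown global minimum energy matches the grid-scan value", {
  s <- build_surface("muller_brown")
  expect_equal(s$energy(MB_MINIMA$A$x), MB_MINIMA$A$E, tolerance = 1e-6)
})

test_that("analytic gradients agree with finite differences on all families", {
  surfaces <- list(
    build_surface("double_well_1d"),
    build_surface("muller_brown"),
    build_surface("lj_cluster", list(n_atoms = 5)),
    build_surface("bead_peptide"))
  set.seed(101)
  for (s in surfaces) {
    for (rep in 1:25) {
      x <- if (s$name == "bead_peptide")
        helix_configuration(s$spec) + rnorm(s$n_dof, sd = 0.3)
      else rnorm(s$n_dof, sd = 1.2)
      if (!is.finite(s$energy(x))) next
      g <- s$gradient(x)
      gn <- fd_gradient(s, x, h = 1e-6)
      expect_lt(max(abs(g - gn)) / max(1, max(abs(gn))), 1e-5)
    }
  }
})

test_that("Hessians are symmetric and match the surface's zero-mode count", {
  lj <- build_surface("lj_cluster", list(n_atoms = 4))
  set.seed(7)
  x <- local_minimize(lj, rnorm(12), rms_tol = 1e-7)$x_min
  H <- surface_hessian(lj, x)
  expect_identical(H, t(H))
  ev <- normal_mode_eigen(lj, x)
  expect_length(ev$values, 12 - 6)
  expect_true(all(ev$values > 0))
})

test_that("energy terms sum to the total and absent terms are zero", {
  lj <- build_surface("lj_cluster", list(n_atoms = 6))
  set.seed(11)
  x <- rnorm(18) * 1.3
  d <- decompose_energy(lj, x)
  expect_equal(sum(d), lj$energy(x), tolerance = 1e-10)
  expect_identical(unname(d["electrostatic"]), 0)

  bp <- build_surface("bead_peptide")
  xr <- helix_configuration(bp$spec) + rnorm(bp$n_dof, sd = 0.2)
  db <- decompose_energy(bp, xr)
  expect_equal(sum(db), bp$energy(xr), tolerance = 1e-10)

  bp0 <- build_surface("bead_peptide", list(sequence = "HPHHPHHPH"))
  x0 <- helix_configuration(bp0$spec)
  expect_identical(unname(decompose_energy(bp0, x0)["electrostatic"]), 0)

  expect_error(decompose_energy(lj, numeric(5)), "coordinates")
})

test_that("surface construction validates its inputs", {
  expect_error(build_surface("nope"), "unknown surface family")
  expect_error(build_surface("lj_cluster", list(n_atoms = 1)), "n_atoms")
  expect_error(bead_peptide_spec(sequence = "HX+"), "invalid bead types|at least 4")
  expect_error(bead_peptide_spec(sequence = "H+H"), "at least 4")
  expect_error(bead_peptide_spec(k_bond = -1), "positive")
})

test_that("extended XYZ and surface config files round-trip", {
  bp <- build_surface("bead_peptide")
  x <- helix_configuration(bp$spec)
  f <- tempfile(fileext = ".xyz")
  write_xyz(list(list(coords = x, types = bp$spec$beads, comment = "helix"),
                 list(coords = x + 1, types = bp$spec$beads)), f)
  frames <- read_xyz(f)
  expect_length(frames, 2)
  expect_equal(frames[[1]]$coords, x)
  expect_identical(frames[[1]]$types, bp$spec$beads)

  cfg <- tempfile()
  writeLines(c("# test", "surface lj_cluster", "n_atoms 5", "eps 2"), cfg)
  s <- read_surface_config(cfg)
  expect_identical(s$name, "lj_cluster")
  expect_equal(s$n_dof, 15)
  expect_equal(s$energy(c(0, 0, 0, 2^(1 / 6), 0, 0, 50, 0, 0, 0, 60, 0, 0, 0, 70)),
               -2, tolerance = 1e-3)
})

test_that("synthetic KTN generation is reproducible and connected", {
  spec <- synthetic_ktn_spec(n_funnels = 1, minima_per_funnel = 3, seed = 9)
  g <- generate_synthetic_ktn(spec)
  expect_equal(ktn_n_minima(g$db), 3)
  expect_gte(ktn_n_ts(g$db), 2)
  comp <- igraph::components(ktnet:::ktn_graph(g$db))
  expect_equal(comp$no, 1)

  g2 <- generate_synthetic_ktn(spec)
  expect_identical(ktn_edges(g$db), ktn_edges(g2$db))
  expect_identical(ktn_min_energies(g$db), ktn_min_energies(g2$db))
  expect_identical(g$K, g2$K)

  expect_error(synthetic_ktn_spec(intra_funnel_barrier = 5,
                                  inter_funnel_barrier = 2), "inter_funnel")
})

test_that("widely separated funnels give slow inter-funnel rates", {
  spec <- synthetic_ktn_spec(n_funnels = 2, minima_per_funnel = 4,
                             intra_funnel_barrier = 0.5,
                             inter_funnel_barrier = 6, seed = 4)
  g <- generate_synthetic_ktn(spec, T = 0.4)
  db <- g$db
  f1 <- which(db$funnel == 1); f2 <- which(db$funnel == 2)
  inter <- graph_transform_rates(db, A_set = db$bottoms[2],
                                 B_set = db$bottoms[1], T = 0.4)
  intra <- graph_transform_rates(db, A_set = f1[2], B_set = f1[1], T = 0.4)
  expect_lt(inter$k_AB * 1e3, intra$k_AB)
  # exact master-equation oracle agrees
  gen <- ktn_generator(db, 0.4)
  ex <- exact_rate_oracle(gen$K, match(db$bottoms[2], gen$ids),
                          match(db$bottoms[1], gen$ids))
  expect_equal(inter$k_AB, ex$k_AB, tolerance = 1e-10)
})
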