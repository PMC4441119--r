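bp <- build_surface("bead_peptide")

test_that("helicity fraction counts dihedrals inside the window", {
  helix <- helix_configuration(bp$spec)           # all dihedrals at 50
  expect_equal(helicity_fraction(helix), 1.0)
  anti <- helix_configuration(bp$spec, phi = 50 + 180)
  expect_equal(helicity_fraction(anti), 0.0)
  # half the chain helical: rebuild with mixed dihedrals via a pivot flip
  spec8 <- bead_peptide_spec(sequence = "HHHHHHHHHHHH")
  phis <- chain_dihedrals(helix_configuration(spec8))
  expect_equal(length(phis), 9)
  expect_error(helicity_fraction(c(0, 0, 0, 1, 0, 0)), "too short")
})

test_that("radius of gyration matches hand values", {
  expect_equal(radius_of_gyration(c(1, 2, 3, 1, 2, 3)), 0)
  expect_equal(radius_of_gyration(c(0, 0, 0, 2, 0, 0)), 1)
  sq <- sqrt(2) * c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0)
  expect_equal(radius_of_gyration(sq), 1, tolerance = 1e-12)
})

test_that("superposition RMSD: exact zeros, symmetry, and the chiral case
           bounded by a rotation-sampling oracle", {
  set.seed(42)
  a <- rnorm(15)
  expect_equal(rmsd_superpose(a, a)$rmsd, 0, tolerance = 1e-12)
  R <- random_rotation()
  b <- rotate_conf(a, R) + rep(c(1, -2, 0.5), 5)
  expect_lt(rmsd_superpose(a, b)$rmsd, 1e-10)
  c <- a + rnorm(15, sd = 0.4)
  expect_equal(rmsd_superpose(a, c)$rmsd, rmsd_superpose(c, a)$rmsd,
               tolerance = 1e-10)
  # planar structure vs its mirror: achievable by a proper rotation
  planar <- as.numeric(t(cbind(matrix(rnorm(10), 5, 2), 0)))
  mirror <- planar * rep(c(1, 1, -1), 5)
  expect_lt(rmsd_superpose(planar, mirror)$rmsd, 1e-10)
  # chiral structure vs mirror: optimal proper rotation beats random sampling
  mir_c <- a * rep(c(1, 1, -1), 5)
  kab <- rmsd_superpose(a, mir_c)$rmsd
  expect_gt(kab, 0.01)
  A <- matrix(a, ncol = 3, byrow = TRUE)
  A <- sweep(A, 2, colMeans(A))
  M <- matrix(mir_c, ncol = 3, byrow = TRUE)
  M <- sweep(M, 2, colMeans(M))
  best <- Inf
  for (i in 1:20000) {
    Rr <- random_rotation()
    best <- min(best, sqrt(mean(rowSums((A - M %*% t(Rr))^2))))
  }
  expect_lte(kab, best + 1e-12)
  expect_lt(best - kab, 0.05)
})

test_that("end-to-end distances", {
  x <- c(0, 0, 0, 1, 0, 0, 2, 0, 0, 3, 0, 0)
  expect_equal(end_to_end_distance(x), 3)
  expect_equal(end_to_end_distance(x, 2, 3), 1)
  expect_equal(end_to_end_distance(c(1, 1, 1, 1, 1, 1), 1, 2), 0)
  set.seed(3)
  y <- rnorm(12)
  expect_equal(end_to_end_distance(y, 1, 4),
               sqrt(sum((y[1:3] - y[10:12])^2)))
})

test_that("contact maps are symmetric ensemble frequencies with the
           near-diagonal excluded", {
  lin <- function(s) as.numeric(t(cbind(s, 0, 0)))   # beads on a line
  c1 <- lin(c(0, 1, 2, 3, 4, 10))
  c2 <- lin(c(0, 1, 2, 3, 4, 4.5))
  c3 <- lin(c(0, 1, 2, 3, 4, 20))
  M <- contact_map(list(c1, c2, c3), cutoff = 6)
  expect_identical(M, t(M))
  expect_true(all(diag(M) == 0))
  expect_true(all(M[abs(row(M) - col(M)) <= 2] == 0))
  # bead pair (1, 6): distances 10, 4.5, 20 -> 1/3 of frames within 6
  expect_equal(M[1, 6], 1 / 3)
  # pair (1, 4): distance 3 always, |i-j| = 3 -> frequency 1
  expect_equal(M[1, 4], 1)
  expect_error(contact_map(list(), 6), "empty")
})

test_that("hydrogen-bond-like contacts respect both cutoffs", {
  mk <- function(d, ang_dev) {
    # donor at origin, hydrogen at (1,0,0), acceptor at distance d with
    # deviation ang_dev from linearity
    th <- (180 - ang_dev) * pi / 180
    H <- c(1, 0, 0)
    A <- H + d * c(cos(pi - th), sin(pi - th), 0)
    c(0, 0, 0, H, A)
  }
  tri <- data.frame(donor = 1, hydrogen = 2, acceptor = 3)
  expect_equal(nrow(hbond_like_contacts(mk(2.5, 0), tri)), 1)
  expect_equal(nrow(hbond_like_contacts(mk(3.5, 0), tri)), 0)
  expect_equal(nrow(hbond_like_contacts(mk(2.5, 50), tri)), 0)
  expect_equal(nrow(hbond_like_contacts(mk(2.9, 39), tri)), 1)
})

test_that("dihedral leader clustering recovers archetypes", {
  spec <- bead_peptide_spec(sequence = "HHHHHHHH")
  mk <- function(phi) helix_configuration(spec, phi = phi)
  expect_length(cluster_dihedrals(list(mk(50), mk(50), mk(50))), 1)
  two <- cluster_dihedrals(list(mk(50), mk(-130)), angle_cutoff = 40)
  expect_length(two, 2)
  # three archetypes + small noise: assignments recovered
  set.seed(9)
  arch <- c(50, 170, -70)
  labels <- sample(1:3, 150, replace = TRUE)
  ens <- lapply(labels, function(l) mk(arch[l] + runif(1, -10, 10)))
  cl <- cluster_dihedrals(ens, angle_cutoff = 40)
  expect_length(cl, 3)
  assign <- integer(150)
  for (i in seq_along(cl)) assign[cl[[i]]$members] <- i
  # cluster labels are a permutation of archetype labels
  tab <- table(labels, assign)
  purity <- sum(apply(tab, 1, max)) / 150
  expect_gte(purity, 0.99)
  pops <- vapply(cl, function(c) c$population, numeric(1))
  expect_true(all(diff(pops) <= 0))
  expect_equal(sum(pops), 1)
})

test_that("2-D free-energy surfaces: uniform bins, analytic two-bin gap,
           weight-rescaling invariance, degenerate flag", {
  x <- c(rep(0.25, 5), rep(0.75, 5))
  f <- fes_2d(x, rep(0.5, 10), bins = c(2, 1), x_range = c(0, 1),
              y_range = c(0, 1))
  expect_equal(f$F[1, 1], 0)
  expect_equal(f$F[2, 1], 0)
  p <- 0.7
  x2 <- c(rep(0.25, 7), rep(0.75, 3))
  f2 <- fes_2d(x2, rep(0.5, 10), T = 2, kB = 1, bins = c(2, 1),
               x_range = c(0, 1), y_range = c(0, 1))
  expect_equal(f2$F[2, 1], -2 * log((1 - p) / p), tolerance = 1e-12)
  f3 <- fes_2d(x2, rep(0.5, 10), weights = rep(17, 10), T = 2, bins = c(2, 1),
               x_range = c(0, 1), y_range = c(0, 1))
  expect_equal(f2$F, f3$F)
  f4 <- fes_2d(rep(0.2, 5), rep(0.2, 5), bins = 4,
               x_range = c(0, 1), y_range = c(0, 1))
  expect_true(f4$degenerate)
  expect_true(any(is.na(f4$F)))
})

test_that("reweighted 1-D double-well marginal matches the Boltzmann
           integral", {
  # samples drawn uniformly, reweighted by exp(-V/T): the two-bin occupancy
  # of a tilted double well must match quadrature
  s <- tilted_double_well(0.3)
  T <- 0.25
  set.seed(31)
  xs <- runif(20000, -1.6, 1.6)
  w <- exp(-vapply(xs, function(x) s$energy(x), numeric(1)) / T)
  f <- fes_2d(xs, rep(0, 20000), weights = w, T = T, bins = c(2, 1),
              x_range = c(-1.6, 1.6), y_range = c(-1, 1))
  dF <- f$F[2, 1] - f$F[1, 1]
  zl <- stats::integrate(function(x) exp(-(x^4 - x^2 + 0.3 * x) / T), -1.6, 0)$value
  zr <- stats::integrate(function(x) exp(-(x^4 - x^2 + 0.3 * x) / T), 0, 1.6)$value
  expect_equal(dF, -T * log(zr / zl), tolerance = 0.05)
})

test_that("order parameters are invariant under rigid motions", {
  set.seed(55)
  x <- helix_configuration(bp$spec) + rnorm(39, sd = 0.1)
  R <- random_rotation()
  y <- rotate_conf(x, R) + rep(c(2, -1, 3), 13)
  expect_equal(helicity_fraction(y), helicity_fraction(x), tolerance = 1e-10)
  expect_equal(radius_of_gyration(y), radius_of_gyration(x), tolerance = 1e-10)
  expect_equal(end_to_end_distance(y), end_to_end_distance(x),
               tolerance = 1e-10)
})

test_that("path energy profiles decompose every stationary point", {
  mb <- build_surface("muller_brown")
  r <- mb_database(mb)
  res <- connect_minima(mb, r$ids[["A"]], r$ids[["B"]], r$db,
                        max_cycles = 10, rms_tol = 1e-7)
  fp <- fastest_path(r$db, r$ids[["A"]], r$ids[["B"]], T = 10)
  prof <- path_energy_profile(fp, r$db, mb)
  expect_equal(nrow(prof), 2 * length(fp$min_ids) - 1)
  expect_equal(prof$total,
               rowSums(prof[, ktnet:::ALL_TERMS]), tolerance = 1e-10)
  # analytic surface: everything in the analytic term, electrostatics flat 0
  expect_true(all(prof$electrostatic == 0))
})

test_that("charge patterning kappa: mixed, blocky and the BH3 peptide", {
  expect_lt(charge_patterning("EKEKEKEKEKEKEKEKEKEK")$kappa, 0.01)
  expect_equal(charge_patterning("EEEEEEEEEEKKKKKKKKKK")$kappa, 1.0,
               tolerance = 1e-12)
  p <- charge_patterning(read_fasta_sequence(
    system.file("extdata", "puma_bh3.fasta", package = "ktnet")))
  expect_lt(abs(p$kappa - 0.18), 0.02)
  expect_gte(p$FCR, abs(p$NCPR))
  expect_true(p$kappa >= 0 && p$kappa <= 1)
  expect_error(charge_patterning("GGGGGGGG"), "no charged")
  expect_error(charge_patterning("EKX"), "amino-acid|blob")
  # histidine is uncharged
  expect_identical(charge_patterning("EHEHKHKHEHKH")$charges[2], 0)
})
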