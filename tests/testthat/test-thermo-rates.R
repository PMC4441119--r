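test_that("harmonic-superposition occupations match the closed forms", {
  db <- ktn_new(); ktn_put_minimum(db, 0, 0); ktn_put_minimum(db, 0, 0)
  expect_equal(unname(hsa_free_energies(db, 1)$occupations), c(0.5, 0.5),
               tolerance = 1e-12)
  db2 <- ktn_new(); ktn_put_minimum(db2, 0, 0)
  ktn_put_minimum(db2, log(2), 0)        # dE = kB T ln 2 at T = 1
  expect_equal(unname(hsa_free_energies(db2, 1)$occupations), c(2, 1) / 3,
               tolerance = 1e-12)
  db3 <- ktn_new(); ktn_put_minimum(db3, 0, 0)
  ktn_put_minimum(db3, 0, log(2))        # frequency-product ratio 2, equal E
  expect_equal(unname(hsa_free_energies(db3, 1)$occupations), c(2, 1) / 3,
               tolerance = 1e-12)
  expect_equal(sum(hsa_free_energies(db3, 0.37)$occupations), 1,
               tolerance = 1e-12)
  expect_error(hsa_free_energies(db3, -1), "positive")
})

test_that("heat capacity: single minimum is the vibrational baseline; the
           two-state peak and the finite-difference identity hold", {
  db1 <- ktn_new(); db1$n_modes <- 5; ktn_put_minimum(db1, 0, 0)
  cv <- hsa_heat_capacity(db1, c(0.5, 1, 2))
  expect_equal(cv$Cv, rep(5, 3), tolerance = 1e-12)

  # two-state system: closed-form Cv peak near dE / (kB T ln-ratio)
  db2 <- ktn_new(); db2$n_modes <- 1
  ktn_put_minimum(db2, 0, 0); ktn_put_minimum(db2, 2, -3)  # gap 2, entropy ln ratio 3
  Ts <- seq(0.05, 3, length.out = 400)
  cv2 <- hsa_heat_capacity(db2, Ts)
  peak <- attr(cv2, "peak")
  # closed-form two-state: maximise dE^2 p(1-p)/T^2 with p = 1/(1+exp(3-2/T))
  f <- function(T) { p <- 1 / (1 + exp(3 - 2 / T)); 4 * p * (1 - p) / T^2 }
  oracle <- Ts[which.max(f(Ts))]
  expect_equal(peak, oracle, tolerance = 0.05)

  # Cv equals the finite-difference second derivative of the partition sum
  spec <- synthetic_ktn_spec(n_funnels = 2, minima_per_funnel = 4, seed = 3)
  g <- generate_synthetic_ktn(spec)
  Ts2 <- seq(0.3, 2.5, length.out = 25)
  cv3 <- hsa_heat_capacity(g$db, Ts2)
  h <- 1e-4
  lnZ <- function(T) hsa_free_energies(g$db, T)$log_Z
  EofT <- function(T) T^2 * (lnZ(T + h) - lnZ(T - h)) / (2 * h)
  cv_fd <- vapply(Ts2, function(T) (EofT(T + h) - EofT(T - h)) / (2 * h),
                  numeric(1))
  expect_equal(cv3$Cv, cv_fd, tolerance = 1e-6)
})

test_that("harmonic TST rates: prefactor identity, Boltzmann factor,
           detailed balance", {
  db <- ktn_new()
  nu <- 0.8
  m1 <- ktn_put_minimum(db, 0, 3 * log(nu))
  m2 <- ktn_put_minimum(db, 0, 3 * log(nu))
  t1 <- ktn_put_ts(db, 0, m1, m2, 2 * log(nu))   # dE = 0, equal frequencies
  expect_equal(tst_rate(ktn_ts(db, t1), ktn_minimum(db, m1), T = 1), nu,
               tolerance = 1e-12)
  db$ts[["1"]]$energy <- 1                        # dE = kB T at T = 1
  expect_equal(tst_rate(ktn_ts(db, t1), ktn_minimum(db, m1), T = 1),
               nu * exp(-1), tolerance = 1e-12)
  expect_error(tst_rate(ktn_ts(db, t1), list(id = 99, energy = 0,
                                             log_product_frequencies = 0), 1),
               "does not connect")
  db$ts[["1"]]$energy <- -1                       # below the minimum
  expect_error(tst_rate(ktn_ts(db, t1), ktn_minimum(db, m1), 1), "corrupt")

  # k(b<-a) p_a == k(a<-b) p_b under HSA weights on a random network
  dbr <- random_ktn(8, seed = 31)
  st <- hsa_free_energies(dbr, 0.9)
  for (t in dbr$ts) {
    if (t$min_minus == t$min_plus) next
    ka <- tst_rate(t, ktn_minimum(dbr, t$min_minus), 0.9)
    kb <- tst_rate(t, ktn_minimum(dbr, t$min_plus), 0.9)
    pa <- st$occupations[as.character(t$min_minus)]
    pb <- st$occupations[as.character(t$min_plus)]
    expect_equal(unname(ka * pa), unname(kb * pb), tolerance = 1e-12)
  }
})

test_that("free-energy regrouping: threshold 0 identity, analytic two-state
           merge, idempotence, merge-order independence", {
  db <- random_ktn(10, seed = 17)
  rg0 <- regroup_free_energy(db, 1, 0)
  expect_length(rg0$groups, 10)

  db2 <- ktn_new(); ktn_put_minimum(db2, 0, 0); ktn_put_minimum(db2, 0.5, 0)
  ktn_put_ts(db2, 2.5, 1, 2)              # barrier 2 < threshold 3
  rg2 <- regroup_free_energy(db2, 1, 3)
  expect_length(rg2$groups, 1)
  F1 <- ktnet:::stationary_free_energy(0, 0, 0, 1, 1)
  F2 <- ktnet:::stationary_free_energy(0.5, 0, 0, 1, 1)
  expect_equal(unname(rg2$group_free_energies[1]),
               -log(exp(-F1) + exp(-F2)), tolerance = 1e-12)

  # idempotent and enumeration-order independent: exhaustive random-order
  # pairwise merging reaches the same partition
  for (seed in c(17, 23, 29)) {
    db3 <- random_ktn(10, seed = seed)
    thr <- 1.2
    rg <- regroup_free_energy(db3, 1, thr)
    rg_again <- regroup_free_energy(db3, 1, thr)
    expect_identical(rg$membership, rg_again$membership)
    part_ref <- unname(sort(vapply(rg$groups, function(g)
      paste(sort(g), collapse = ","), character(1)), method = "radix"))
    for (rep in 1:5) {
      part <- random_order_regroup(db3, 1, thr, seed = seed * 100 + rep)
      expect_identical(part, part_ref)
    }
  }
})

test_that("graph transformation matches symmetry, the single-intermediate
           closed form, and the exact oracle", {
  # symmetric double well: k_AB == k_BA
  db <- ktn_new(); ktn_put_minimum(db, 0, 0); ktn_put_minimum(db, 0, 0)
  ktn_put_ts(db, 1, 1, 2)
  r <- graph_transform_rates(db, 1, 2, T = 0.7)
  expect_equal(r$k_AB, r$k_BA, tolerance = 1e-12)

  # single intermediate with k(a<-i)=3, k(b<-i)=1, k(i<-b)=2
  K <- matrix(0, 3, 3)
  K[2, 3] <- 2; K[1, 2] <- 3; K[3, 2] <- 1; K[2, 1] <- 1e-6
  ex <- exact_rate_oracle(K, 1, 3)
  expect_equal(ex$k_AB, 1.5, tolerance = 1e-9)

  # random networks: GT vs oracle and detailed balance
  set.seed(404)
  for (trial in 1:30) {
    n <- sample(4:12, 1)
    dbr <- random_ktn(n, seed = 5000 + trial, extra_edges = sample(0:4, 1))
    T <- runif(1, 0.5, 2)
    picks <- sample(seq_len(n), sample(2:4, 1))
    A <- picks[1]; B <- picks[-1]
    gt <- graph_transform_rates(dbr, A, B, T)
    gen <- ktn_generator(dbr, T)
    orc <- exact_rate_oracle(gen$K, match(A, gen$ids), match(B, gen$ids))
    expect_equal(gt$k_AB, orc$k_AB, tolerance = 1e-8)
    expect_equal(gt$k_BA, orc$k_BA, tolerance = 1e-8)
    expect_equal(gt$k_AB * gt$p_B, gt$k_BA * gt$p_A,
                 tolerance = 1e-10 * gt$k_AB * gt$p_B)
  }
  expect_error(graph_transform_rates(db, 1, 1, T = 1), "disjoint")
})

test_that("group-level rates after regrouping keep detailed balance", {
  db <- random_ktn(12, seed = 61, extra_edges = 4L)
  rg <- regroup_free_energy(db, 0.8, 0.8)
  gids <- seq_along(rg$groups)
  if (length(gids) >= 3) {
    reps <- vapply(rg$groups, `[`, integer(1), 1)
    r <- graph_transform_rates(rg, A_set = reps[1], B_set = reps[2], T = 0.8)
    expect_equal(r$k_AB * r$p_B, r$k_BA * r$p_A,
                 tolerance = 1e-10 * r$k_AB * r$p_B)
  }
})

test_that("the rate table reproduces fold/unfold asymmetry of a high narrow
           funnel and obeys detailed balance", {
  db <- ktn_new(); db$n_modes <- 1
  helix <- ktn_put_minimum(db, 5, 0)
  glob <- ktn_put_minimum(db, 0, 0)
  set.seed(8)
  for (i in 1:4) {
    m <- ktn_put_minimum(db, runif(1, 0.2, 1.5), runif(1, -0.2, 0.2))
    ktn_put_ts(db, 2 + runif(1), glob, m)
  }
  ktn_put_ts(db, 9, helix, glob)
  tab <- rate_table(db, reference_min = helix, targets = glob, T = 0.5)
  expect_gt(tab$k_unfold / tab$k_fold, 1e3)
  expect_equal(tab$k_unfold / tab$k_fold, tab$p_eq / tab$p_ref,
               tolerance = 1e-8)
  expect_error(rate_table(db, helix, c(glob, helix), T = 0.5), "disjoint")
})
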