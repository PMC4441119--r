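mb <- build_surface("muller_brown")

test_that("minimum insertion is idempotent and rotation-invariant", {
  lj <- build_surface("lj_cluster", list(n_atoms = 7))
  set.seed(5)
  m <- local_minimize(lj, rnorm(21) * 1.1, rms_tol = 1e-6)
  db <- ktn_new("lj7")
  r1 <- add_minimum(db, m, lj)
  expect_true(r1$is_new)
  r2 <- add_minimum(db, m, lj)
  expect_false(r2$is_new)
  expect_identical(r2$id, r1$id)
  expect_equal(ktn_n_minima(db), 1)
  # rigid rotation of the same minimum is identified as the same record
  mrot <- m
  mrot$x_min <- rotate_conf(m$x_min, random_rotation())
  r3 <- add_minimum(db, mrot, lj)
  expect_false(r3$is_new)
  expect_equal(ktn_n_minima(db), 1)
  # unconverged candidates are rejected
  bad <- m; bad$converged <- FALSE
  expect_error(add_minimum(db, bad, lj), "not converged")
})

test_that("the three Muller-Brown minima give three records, and TS insertion
           mirrors the identity rule", {
  r <- mb_database(mb)
  expect_equal(ktn_n_minima(r$db), 3)
  ts <- refine_transition_state(mb, c(0.2, 0.3), rms_tol = 1e-8)
  tri <- descend_to_minima(mb, ts)
  i1 <- add_transition_state(r$db, ts, tri, mb)
  expect_true(i1$is_new)
  i2 <- add_transition_state(r$db, ts, tri, mb)
  expect_false(i2$is_new)
  expect_equal(ktn_n_ts(r$db), 1)
  ed <- ktn_edges(r$db)
  expect_setequal(c(ed$m1, ed$m2), c(r$ids[["B"]], r$ids[["C"]]))
})

test_that("databases round-trip losslessly through the text format", {
  empty <- ktn_new("nothing")
  p0 <- tempfile()
  write_db(empty, p0)
  back0 <- read_db(p0)
  expect_equal(ktn_n_minima(back0), 0)
  expect_equal(ktn_n_ts(back0), 0)

  r <- mb_database(mb)
  ts <- refine_transition_state(mb, c(0.2, 0.3), rms_tol = 1e-8)
  add_transition_state(r$db, ts, descend_to_minima(mb, ts), mb)
  p1 <- tempfile()
  write_db(r$db, p1)
  back <- read_db(p1)
  expect_identical(ktn_min_energies(back), ktn_min_energies(r$db))
  for (id in ktn_min_ids(r$db)) {
    expect_identical(ktn_minimum(back, id)$coords, ktn_minimum(r$db, id)$coords)
    expect_identical(ktn_minimum(back, id)$log_product_frequencies,
                     ktn_minimum(r$db, id)$log_product_frequencies)
  }
  expect_identical(ktn_edges(back), ktn_edges(r$db))

  # fuzzed database of 100 random records
  set.seed(99)
  fz <- ktn_new("fuzz")
  for (i in 1:60) ktn_put_minimum(fz, rnorm(1) * 10^runif(1, -3, 3),
                                  rnorm(1), coords = rnorm(6))
  for (i in 1:40) {
    ij <- sample(1:60, 2)
    ktn_put_ts(fz, abs(rnorm(1)) * 10^runif(1, -2, 2), ij[1], ij[2],
               rnorm(1), coords = rnorm(6))
  }
  p2 <- tempfile()
  write_db(fz, p2)
  back2 <- read_db(p2)
  expect_identical(ktn_min_energies(back2), ktn_min_energies(fz))
  expect_identical(ktn_edges(back2), ktn_edges(fz))
  expect_identical(ktn_ts(back2, 17)$coords, ktn_ts(fz, 17)$coords)

  # malformed file reports the problem
  writeLines(c("1.0 2.0"), file.path(p2, "ts.data"))
  expect_error(read_db(p2), "malformed|fields|records")
})

test_that("order parameters survive persistence", {
  db <- ktn_new("op")
  ktn_put_minimum(db, 0, 0, coords = rnorm(6),
                  order_parameters = list(helicity = 0.4))
  p <- tempfile()
  write_db(db, p)
  back <- read_db(p)
  expect_equal(ktn_minimum(back, 1)$order_parameters$helicity, 0.4)
})

test_that("fastest paths: single exit, brute-force enumeration, rerouting", {
  # two minima, one TS: unique path with weight 0
  db <- ktn_new()
  ktn_put_minimum(db, 0, 0); ktn_put_minimum(db, 0.5, 0)
  ktn_put_ts(db, 1.5, 1, 2)
  fp <- fastest_path(db, 1, 2, T = 1)
  expect_identical(fp$min_ids, c(1L, 2L))
  expect_equal(fp$weight, 0)

  # 4-minimum network vs exhaustive simple-path enumeration
  set.seed(12)
  db4 <- ktn_new()
  for (i in 1:4) ktn_put_minimum(db4, runif(1, 0, 1), runif(1, -0.5, 0.5))
  ktn_put_ts(db4, 2.0, 1, 2); ktn_put_ts(db4, 2.5, 2, 4)
  ktn_put_ts(db4, 1.8, 1, 3); ktn_put_ts(db4, 3.2, 3, 4)
  ktn_put_ts(db4, 3.0, 1, 4)
  T <- 0.7
  rm <- ktnet:::ktn_rate_matrix(db4, T, 1)
  paths <- list(c(1, 4), c(1, 2, 4), c(1, 3, 4))
  ws <- vapply(paths, function(p) {
    s <- 0
    for (k in seq_len(length(p) - 1)) s <- s - log(rm$P[p[k + 1], p[k]])
    s
  }, numeric(1))
  fp4 <- fastest_path(db4, 1, 4, T)
  expect_equal(fp4$weight, min(ws), tolerance = 1e-12)
  expect_identical(fp4$min_ids, as.integer(paths[[which.min(ws)]]))

  # raising a TS energy on the best path increases its weight and reroutes
  best_path <- fp4$min_ids
  raise_id <- fp4$ts_ids[1]
  db4$ts[[as.character(raise_id)]]$energy <-
    db4$ts[[as.character(raise_id)]]$energy + 3
  db4$ts_energies[as.character(raise_id)] <-
    db4$ts_energies[as.character(raise_id)] + 3
  fp5 <- fastest_path(db4, 1, 4, T)
  expect_gt(fp5$weight, 0)
  expect_false(identical(fp5$min_ids, best_path))

  # disconnected sets produce an informative error
  iso <- ktn_put_minimum(db4, 0.2, 0)
  expect_error(fastest_path(db4, 1, iso, T), "disconnected")
})

test_that("a fast direct transition state captures the fastest path", {
  # adding a transition state reshuffles branching probabilities (escape
  # routes compete), but a sufficiently fast direct channel always wins
  db <- random_ktn(8, seed = 21, extra_edges = 0L)
  w0 <- fastest_path(db, 1, 8, T = 1)$weight
  emax <- max(ktn_minimum(db, 1)$energy, ktn_minimum(db, 8)$energy)
  ktn_put_ts(db, emax + 0.05, 1, 8)     # low direct barrier
  fp <- fastest_path(db, 1, 8, T = 1)
  expect_identical(fp$min_ids, c(1L, 8L))
  expect_lt(fp$weight, w0)
})

test_that("referential integrity and dedup idempotence of whole databases", {
  r <- mb_database(mb)
  ts <- refine_transition_state(mb, c(0.2, 0.3), rms_tol = 1e-8)
  add_transition_state(r$db, ts, descend_to_minima(mb, ts), mb)
  ed <- ktn_edges(r$db)
  expect_true(all(c(ed$m1, ed$m2) %in% ktn_min_ids(r$db)))
  expect_error(ktn_put_ts(r$db, 5, 1, 99), "endpoints must exist")
  # re-inserting every stored minimum changes nothing
  n0 <- ktn_n_minima(r$db)
  for (id in ktn_min_ids(r$db)) {
    m <- ktn_minimum(r$db, id)
    cand <- list(x_min = m$coords, energy = m$energy, converged = TRUE,
                 rms_gradient = 0, n_iterations = 0)
    class(cand) <- "minimize_result"
    res <- add_minimum(r$db, cand, mb)
    expect_false(res$is_new)
  }
  expect_equal(ktn_n_minima(r$db), n0)
})
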