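# shared fixtures: closure surfaces and small databases built in code

# d-dimensional harmonic well V = 0.5 k |x|^2
harmonic_surface <- function(d = 2L, k = 1) {
  potential_surface(paste0("harmonic", d), d,
                    energy = function(x) 0.5 * k * sum(x^2),
                    gradient = function(x) k * x,
                    dim = as.integer(d), scale = 1)
}

# four-well 2-D surface: minima near (+-1, +-1); saddles near (0, +-1) with
# energies ~1 (top channel) and ~1.8 (bottom channel), and (+-1, 0) ~0.5
four_well_surface <- function() {
  potential_surface("four_well", 2L,
    energy = function(x) {
      (x[1]^2 - 1)^2 * (1 + 0.2 * (x[2] - 1)^2) + 0.5 * (x[2]^2 - 1)^2
    },
    gradient = function(x) {
      gx <- 4 * x[1] * (x[1]^2 - 1) * (1 + 0.2 * (x[2] - 1)^2)
      gy <- (x[1]^2 - 1)^2 * 0.4 * (x[2] - 1) + 2 * x[2] * (x[2]^2 - 1)
      c(gx, gy)
    },
    dim = 2L, scale = 1)
}

# tilted 1-D double well with closed quadrature oracle
tilted_double_well <- function(tilt = 0.3) {
  potential_surface("tilted_dw", 1L,
                    energy = function(x) x[1]^4 - x[1]^2 + tilt * x[1],
                    gradient = function(x) 4 * x[1]^3 - 2 * x[1] + tilt,
                    dim = 1L, scale = 1)
}

# Muller-Brown reference stationary points (tight grid-scan + descent values)
MB_MINIMA <- list(A = list(x = c(-0.5582236, 1.4417258), E = -146.69952),
                  B = list(x = c(0.6234994, 0.0280378), E = -108.16672),
                  C = list(x = c(-0.0500108, 0.4666941), E = -80.76746))
MB_SADDLES <- list(AC = list(x = c(-0.8220016, 0.6243128), E = -40.664843),
                   CB = list(x = c(0.2124866, 0.2929883), E = -72.248940))

# database of the three Muller-Brown minima
mb_database <- function(surface, rms_tol = 1e-7) {
  db <- ktn_new("muller_brown")
  ids <- vapply(MB_MINIMA, function(m)
    add_minimum(db, local_minimize(surface, m$x, rms_tol = rms_tol),
                surface)$id, integer(1))
  list(db = db, ids = ids)
}

# random reversible ktn with spanning-tree connectivity
random_ktn <- function(n, seed, extra_edges = 3L) {
  set.seed(seed)
  db <- ktn_new("random")
  for (i in seq_len(n)) ktn_put_minimum(db, runif(1, 0, 3), runif(1, -1, 1))
  for (i in seq_len(n)[-1]) {
    j <- sample(seq_len(i - 1), 1)
    emax <- max(ktn_minimum(db, i)$energy, ktn_minimum(db, j)$energy)
    ktn_put_ts(db, emax + runif(1, 0.3, 2), i, j, runif(1, -1, 1))
  }
  for (k in seq_len(extra_edges)) {
    ij <- sample(seq_len(n), 2)
    emax <- max(ktn_minimum(db, ij[1])$energy, ktn_minimum(db, ij[2])$energy)
    ktn_put_ts(db, emax + runif(1, 0.3, 2), ij[1], ij[2], runif(1, -1, 1))
  }
  db
}

# generator matrix of a ktn's TST rates
ktn_generator <- function(db, T, kB = 1) {
  rm <- ktnet:::ktn_rate_matrix(db, T, kB)
  K <- rm$K
  diag(K) <- -colSums(K)
  list(K = K, ids = rm$ids)
}

fd_gradient <- function(surface, x, h = 1e-6) {
  vapply(seq_along(x), function(k) {
    xp <- x; xm <- x
    xp[k] <- xp[k] + h; xm[k] <- xm[k] - h
    (surface$energy(xp) - surface$energy(xm)) / (2 * h)
  }, numeric(1))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rotate_conf <- function(x, R) as.numeric(t(matrix(x, ncol = 3, byrow = TRUE) %*% t(R)))

# oracle for merge-order independence: relabel the minima by a random
# permutation (a different enumeration/merge order), regroup, and map the
# partition back to the original ids
random_order_regroup <- function(db, T, threshold, seed, kB = 1) {
  set.seed(seed)
  ids <- ktn_min_ids(db)
  perm <- sample(ids)                 # original id -> position in new db
  newid <- setNames(seq_along(ids), perm)
  db2 <- ktn_new("perm")
  for (old in perm) {
    m <- ktn_minimum(db, old)
    ktn_put_minimum(db2, m$energy, m$log_product_frequencies)
  }
  for (t in db$ts)
    ktn_put_ts(db2, t$energy, newid[as.character(t$min_minus)],
               newid[as.character(t$min_plus)], t$log_product_frequencies)
  rg <- regroup_free_energy(db2, T, threshold, kB = kB)
  back <- setNames(perm, seq_along(ids))   # new id -> original id
  unname(sort(vapply(rg$groups, function(g)
    paste(sort(back[as.character(g)]), collapse = ","), character(1)),
    method = "radix"))
}
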