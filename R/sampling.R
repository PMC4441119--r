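# Parallel-tempering Monte Carlo and MBAR multistate reweighting: the
# equilibrium-sampling stage feeding the 2-D free-energy surfaces, dihedral
# clustering and heat-capacity curves.

#' Parallel-tempering Monte Carlo run
#'
#' Within-replica single-coordinate Metropolis moves; every
#' `exchange_interval` sweeps, neighbouring replicas attempt a configuration
#' swap accepted with `min(1, exp((beta_i - beta_j)(E_i - E_j)))`. Fully
#' deterministic for a fixed seed.
#'
#' @param surface A `potential_surface`.
#' @param ladder Strictly increasing temperature ladder (a geometric ladder
#'   is conventional). See [geometric_ladder()].
#' @param n_sweeps Number of sweeps (one sweep = `n_dof` single-coordinate
#'   move attempts per replica).
#' @param x0 Starting configuration (shared by all replicas).
#' @param exchange_interval Sweeps between exchange attempts.
#' @param step Maximum single-coordinate displacement.
#' @param seed RNG seed.
#' @param kB Boltzmann constant.
#' @param discard_fraction Initial fraction of sweeps dropped as
#'   equilibration (default 0.2).
#' @return A `replica_run`: `ladder`, `energies` (list per replica, sweeps x
#'   1 after discard), `configs` (list of matrices, sweeps x n_dof),
#'   `exchange_acceptance` (per neighbour pair), `exchange_log`, `seed`.
#' @export
pt_mc_run <- function(surface, ladder, n_sweeps, x0,
                      exchange_interval = 10L, step = 0.5 * surface$scale,
                      seed = 1L, kB = 1, discard_fraction = 0.2) {
  if (is.unsorted(ladder, strictly = TRUE) && length(ladder) > 1)
    stop("ladder must be strictly increasing")
  if (n_sweeps < 1 || exchange_interval < 1) stop("positive intervals required")
  set.seed(seed)
  R <- length(ladder)
  beta <- 1 / (kB * ladder)
  n <- surface$n_dof
  X <- matrix(rep(as.numeric(x0), R), nrow = R, byrow = TRUE)
  E <- apply(X, 1, surface$energy)
  keep_from <- floor(discard_fraction * n_sweeps) + 1L
  energies <- matrix(NA_real_, n_sweeps, R)
  configs <- array(NA_real_, c(n_sweeps, R, n))
  att <- acc <- rep(0L, max(R - 1, 1))
  exlog <- list()
  for (sw in seq_len(n_sweeps)) {
    for (r in seq_len(R)) {
      for (mv in seq_len(n)) {
        k <- if (n == 1) 1L else sample.int(n, 1)
        xt <- X[r, ]
        xt[k] <- xt[k] + runif(1, -step, step)
        et <- surface$energy(xt)
        if (is.finite(et) && (et <= E[r] || runif(1) < exp(-beta[r] * (et - E[r])))) {
          X[r, ] <- xt; E[r] <- et
        }
      }
    }
    if (R > 1 && sw %% exchange_interval == 0) {
      parity <- (sw %/% exchange_interval) %% 2
      for (i in seq_len(R - 1)) {
        if (i %% 2 != parity) next
        att[i] <- att[i] + 1L
        dln <- (beta[i] - beta[i + 1]) * (E[i] - E[i + 1])
        ok <- dln >= 0 || runif(1) < exp(dln)
        if (ok) {
          tmp <- X[i, ]; X[i, ] <- X[i + 1, ]; X[i + 1, ] <- tmp
          e <- E[i]; E[i] <- E[i + 1]; E[i + 1] <- e
          acc[i] <- acc[i] + 1L
        }
        exlog[[length(exlog) + 1]] <- list(sweep = sw, pair = i, accepted = ok)
      }
    }
    energies[sw, ] <- E
    configs[sw, , ] <- X
  }
  sel <- keep_from:n_sweeps
  run <- list(ladder = ladder,
              energies = lapply(seq_len(R), function(r) energies[sel, r]),
              configs = lapply(seq_len(R), function(r)
                configs[sel, r, , drop = TRUE]),
              exchange_acceptance = ifelse(att > 0, acc / att, NA_real_),
              exchange_log = exlog, seed = seed, kB = kB,
              discarded_sweeps = keep_from - 1L)
  class(run) <- "replica_run"
  run
}

#' Geometric temperature ladder
#' @param T_min,T_max Endpoint temperatures.
#' @param n Number of replicas.
#' @return Strictly increasing numeric vector.
#' @export
geometric_ladder <- function(T_min, T_max, n) {
  exp(seq(log(T_min), log(T_max), length.out = n))
}

#' MBAR multistate reweighting
#'
#' Self-consistent solution of the MBAR equations over the replica states
#' (binless WHAM): dimensionless free energies `f_k` with `f_1 = 0`, and
#' normalised per-sample weights at any target temperature.
#'
#' @param run A `replica_run` (or a list with `energies`, `ladder`, `kB`).
#' @param tol Convergence threshold on `max |delta f|`.
#' @param max_iter Iteration budget.
#' @param n_bootstrap If positive, bootstrap standard errors on `f`
#'   (resampling within states, free energies refit each time).
#' @return A `reweight_model`: `f` (per state), `f_se` (if bootstrapped),
#'   `E` (pooled energies), `log_denominator`, `betas`, plus
#'   `weights_at(T)` giving normalised sample weights.
#' @export
mbar_free_energies <- function(run, tol = 1e-10, max_iter = 10000L,
                               n_bootstrap = 0L) {
  betas <- 1 / (run$kB * run$ladder)
  N <- vapply(run$energies, length, integer(1))
  if (!any(N >= 2)) stop("need at least one state with two samples")
  E <- unlist(run$energies)
  fit <- mbar_solve(E, betas, N, tol, max_iter)
  f <- fit$f
  se <- NULL
  if (n_bootstrap > 0) {
    fb <- replicate(n_bootstrap, {
      Eb <- unlist(lapply(run$energies, function(e)
        e[sample.int(length(e), replace = TRUE)]))
      mbar_solve(Eb, betas, N, tol, max_iter)$f
    })
    se <- apply(fb, 1, stats::sd)
  }
  model <- list(f = f, f_se = se, E = E, N = N, betas = betas, kB = run$kB,
                log_denominator = fit$log_den, converged = fit$converged)
  model$weights_at <- function(T) {
    lw <- -E / (run$kB * T) - model$log_denominator
    lw <- lw - max(lw)
    w <- exp(lw)
    w / sum(w)
  }
  class(model) <- "reweight_model"
  model
}

# core MBAR self-consistent iteration (energies only: states differ by beta)
mbar_solve <- function(E, betas, N, tol, max_iter) {
  K <- length(betas)
  U <- outer(betas, E)              # K x Ntot reduced energies
  f <- numeric(K)
  logN <- log(N)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # log denominator per sample: log sum_l N_l exp(f_l - u_l(x_n))
    A <- f + logN - U               # K x Ntot
    M <- apply(A, 2, max)
    log_den <- M + log(colSums(exp(sweep(A, 2, M))))
    B <- -U - rep(log_den, each = K)
    Mb <- apply(B, 1, max)
    fn <- -(Mb + log(rowSums(exp(B - Mb))))
    fn <- fn - fn[1]
    if (max(abs(fn - f)) < tol) { f <- fn; converged <- TRUE; break }
    f <- fn
  }
  A <- f + logN - U
  M <- apply(A, 2, max)
  log_den <- M + log(colSums(exp(sweep(A, 2, M))))
  list(f = f, log_den = log_den, converged = converged)
}

#' Reweighted heat-capacity curve
#'
#' `Cv(T) = (<E^2>_T - <E>_T^2) / (kB T^2)` with MBAR weights; the peak
#' location is reported with a bootstrap error.
#'
#' @param run A `replica_run`.
#' @param model A `reweight_model` from [mbar_free_energies()].
#' @param T_grid Temperatures to evaluate.
#' @param n_bootstrap Bootstrap resamples for the peak uncertainty.
#' @param seed Bootstrap seed.
#' @return data.frame `T`, `Cv`; attributes `peak`, `peak_se`.
#' @export
heat_capacity_curve <- function(run, model, T_grid, n_bootstrap = 100L,
                                seed = 1L) {
  cv_of <- function(E, log_den, T) {
    lw <- -E / (model$kB * T) - log_den
    lw <- lw - max(lw)
    w <- exp(lw); w <- w / sum(w)
    (sum(w * E^2) - sum(w * E)^2) / (model$kB * T^2)
  }
  cv <- vapply(T_grid, function(T) cv_of(model$E, model$log_denominator, T),
               numeric(1))
  out <- data.frame(T = T_grid, Cv = cv)
  attr(out, "peak") <- T_grid[which.max(cv)]
  if (n_bootstrap > 0) {
    set.seed(seed)
    peaks <- replicate(n_bootstrap, {
      idx <- sample.int(length(model$E), replace = TRUE)
      cvb <- vapply(T_grid, function(T)
        cv_of(model$E[idx], model$log_denominator[idx], T), numeric(1))
      T_grid[which.max(cvb)]
    })
    attr(out, "peak_se") <- stats::sd(peaks)
  }
  out
}
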