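#' Local minimisation by L-BFGS
#'
#' Minimises the potential energy to a root-mean-square gradient tolerance.
#' Built-in surface families run a compiled L-BFGS; closure surfaces fall back
#' to [stats::optim()]'s L-BFGS-B with RMS-gradient verification and restarts.
#'
#' @param surface A `potential_surface`.
#' @param x0 Starting configuration.
#' @param rms_tol Convergence threshold on the RMS gradient (default `1e-4`,
#'   kcal/mol/A for the bead peptide, reduced units otherwise).
#' @param max_iter Iteration budget.
#' @return A `minimize_result`: list with `x_min`, `energy`, `rms_gradient`,
#'   `n_iterations`, `converged`.
#' @export
local_minimize <- function(surface, x0, rms_tol = 1e-4, max_iter = 10000L) {
  x0 <- as.numeric(x0)
  if (length(x0) != surface$n_dof)
    stop("x0 has ", length(x0), " coordinates; surface needs ", surface$n_dof)
  if (!all(is.finite(x0))) stop("x0 must be finite")
  if (rms_tol <= 0) stop("rms_tol must be positive")
  e0 <- surface$energy(x0)
  if (!is.finite(e0))
    stop("energy not finite at x0 (overlapping beads?)")
  if (!is.na(surface$family)) {
    r <- cpp_lbfgs(surface$family, surface$params, x0, rms_tol, max_iter,
                   max_step = 0.5 * surface$scale)
    res <- list(x_min = as.numeric(r$x), energy = r$energy,
                rms_gradient = r$rms_grad, n_iterations = r$n_iter,
                converged = isTRUE(r$converged))
  } else {
    x <- x0; it_total <- 0L; converged <- FALSE
    for (round in 1:6) {
      o <- stats::optim(x, fn = surface$energy, gr = surface$gradient,
                        method = "L-BFGS-B",
                        control = list(maxit = max_iter, factr = 1,
                                       pgtol = rms_tol / 10))
      x <- o$par
      it_total <- it_total + o$counts[["function"]]
      rms <- sqrt(mean(surface$gradient(x)^2))
      if (rms <= rms_tol) { converged <- TRUE; break }
      if (it_total >= max_iter) break
    }
    res <- list(x_min = x, energy = surface$energy(x),
                rms_gradient = sqrt(mean(surface$gradient(x)^2)),
                n_iterations = it_total, converged = converged)
  }
  if (!is.finite(res$energy))
    stop("energy diverged during minimisation (overlapping beads?)")
  class(res) <- "minimize_result"
  res
}

#' @export
print.minimize_result <- function(x, ...) {
  cat("<minimize_result> E =", format(x$energy, digits = 10),
      " rms|g| =", format(x$rms_gradient, digits = 3),
      " converged:", x$converged, "\n")
  invisible(x)
}

# ---------------------------------------------------------------- move set

apply_move <- function(surface, x, move, rng_scale) {
  if (move == "cartesian") {
    s <- rng_scale$cartesian
    x + runif(length(x), -s, s)
  } else if (move == "pivot") {
    if (!isTRUE(surface$chain)) stop("pivot move requires a chain system")
    X <- coords_matrix(x)
    n <- nrow(X)
    j <- sample(2:(n - 2), 1)           # rotate about bond axis j -> j+1
    ang <- runif(1, -rng_scale$pivot, rng_scale$pivot) * pi / 180
    axis <- X[j + 1, ] - X[j, ]
    axis <- axis / sqrt(sum(axis^2))
    R <- rotation_matrix(axis, ang)
    # rotate the shorter arm about the pivot point
    if (j <= n - j) {
      idx <- seq_len(j - 1)
      pivot <- X[j, ]
    } else {
      idx <- (j + 2):n
      pivot <- X[j + 1, ]
    }
    X[idx, ] <- sweep(sweep(X[idx, , drop = FALSE], 2, pivot) %*% t(R), 2,
                      pivot, `+`)
    as.numeric(t(X))
  } else stop("unknown move type: ", move)
}

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle); C <- 1 - c
  matrix(c(a[1]^2 * C + c, a[1] * a[2] * C - a[3] * s, a[1] * a[3] * C + a[2] * s,
           a[2] * a[1] * C + a[3] * s, a[2]^2 * C + c, a[2] * a[3] * C - a[1] * s,
           a[3] * a[1] * C - a[2] * s, a[3] * a[2] * C + a[1] * s, a[3]^2 * C + c),
         3, 3, byrow = TRUE)
}

#' Basin-hopping global optimisation
#'
#' Random structural perturbations, each followed by local minimisation, with
#' Metropolis acceptance on the minimised energies: downhill steps are always
#' accepted, uphill with probability `exp(-dE/temperature_param)`. Distinct
#' minima encountered are collected (deduplicated by the database identity
#' rule: energies within 1e-6 and superposition RMSD below 1e-3).
#'
#' @param surface A `potential_surface`.
#' @param x0 Starting configuration.
#' @param n_steps Number of basin-hopping steps.
#' @param moves Character vector from `{"cartesian", "pivot"}`.
#' @param temperature_param Acceptance temperature in energy units.
#' @param seed Integer RNG seed (run is fully reproducible).
#' @param step_size Cartesian displacement half-width (default
#'   `0.4 * surface$scale`).
#' @param pivot_angle Pivot rotation half-width, degrees.
#' @param rms_tol Minimisation tolerance.
#' @param target_energy Optional early-stop: the run returns as soon as the
#'   best minimum is within `target_tol` of this energy.
#' @param target_tol Match tolerance for `target_energy`.
#' @return A `basin_hop_run`: list with `best`, `visited_minima`,
#'   `acceptance_fraction`, `move_log`, `seed`, `temperature_param`,
#'   `n_steps_done`.
#' @export
basin_hop <- function(surface, x0, n_steps, moves = "cartesian",
                      temperature_param = 1.0, seed = 1L,
                      step_size = 0.4 * surface$scale, pivot_angle = 60,
                      rms_tol = 1e-4, target_energy = NULL,
                      target_tol = 1e-6) {
  stopifnot(length(moves) >= 1)
  if ("pivot" %in% moves && !isTRUE(surface$chain))
    stop("pivot move requires a chain system")
  set.seed(seed)
  rng_scale <- list(cartesian = step_size, pivot = pivot_angle)
  cur <- local_minimize(surface, x0, rms_tol = rms_tol)
  visited <- list(cur)
  visited_e <- cur$energy
  best <- cur
  n_acc <- 0L
  n_valid <- 0L
  move_log <- data.frame(step = integer(), move = character(),
                         accepted = logical(), energy = numeric())
  log_move <- vector("list", n_steps)
  steps_done <- 0L
  for (k in seq_len(n_steps)) {
    mv <- if (length(moves) == 1) moves else sample(moves, 1)
    xt <- apply_move(surface, cur$x_min, mv, rng_scale)
    cand <- tryCatch(local_minimize(surface, xt, rms_tol = rms_tol),
                     error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(cand) && cand$converged) {
      n_valid <- n_valid + 1L
      dE <- cand$energy - cur$energy
      accepted <- dE <= 0 || runif(1) < exp(-dE / temperature_param)
      # record genuinely new minima
      hit <- which(abs(visited_e - cand$energy) < 1e-6)
      is_new <- TRUE
      for (i in hit) {
        if (config_distance(surface, visited[[i]]$x_min, cand$x_min) < 1e-3) {
          is_new <- FALSE; break
        }
      }
      if (is_new) {
        visited[[length(visited) + 1]] <- cand
        visited_e <- c(visited_e, cand$energy)
        if (cand$energy < best$energy) best <- cand
      }
      if (accepted) { cur <- cand; n_acc <- n_acc + 1L }
    }
    log_move[[k]] <- list(step = k, move = mv, accepted = accepted,
                          energy = if (is.null(cand)) NA_real_ else cand$energy)
    steps_done <- k
    if (!is.null(target_energy) &&
        best$energy <= target_energy + target_tol) break
  }
  log_move <- log_move[seq_len(steps_done)]
  run <- list(best = best, visited_minima = visited,
              acceptance_fraction = if (n_valid > 0) n_acc / n_valid else NA_real_,
              move_log = do.call(rbind, lapply(log_move, as.data.frame)),
              seed = seed, temperature_param = temperature_param,
              n_steps_done = steps_done)
  class(run) <- "basin_hop_run"
  run
}

#' @export
print.basin_hop_run <- function(x, ...) {
  cat("<basin_hop_run>", x$n_steps_done, "steps,",
      length(x$visited_minima), "distinct minima, best E =",
      format(x$best$energy, digits = 10),
      sprintf("(acceptance %.2f)\n", x$acceptance_fraction))
  invisible(x)
}
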