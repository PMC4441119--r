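# Double-ended (DNEB) and single-ended (eigenvector-following) transition
# state searches, and the connection driver that grows the database.

# L-BFGS driven purely by a force field (no consistent scalar objective):
# used for band relaxation, where the doubly-nudged force is not the gradient
# of any energy. Displacements are trust-limited instead of line-searched.
force_lbfgs <- function(x0, force_fn, max_iter = 1000L, rms_tol = 1e-3,
                        max_disp = 0.1, memory = 8L) {
  x <- x0
  n <- length(x)
  S <- Y <- matrix(0, n, memory)
  rho <- numeric(memory)
  stored <- 0L
  f <- force_fn(x)
  for (k in seq_len(max_iter)) {
    rms <- sqrt(mean(f^2))
    if (rms <= rms_tol) break
    q <- -f
    navail <- min(stored, memory)
    alpha <- numeric(memory)
    if (navail > 0) {
      for (i in seq(stored, stored - navail + 1)) {
        ci <- ((i - 1) %% memory) + 1
        alpha[ci] <- rho[ci] * sum(S[, ci] * q)
        q <- q - alpha[ci] * Y[, ci]
      }
      last <- ((stored - 1) %% memory) + 1
      q <- q * sum(S[, last] * Y[, last]) / sum(Y[, last]^2)
      for (i in seq(stored - navail + 1, stored)) {
        ci <- ((i - 1) %% memory) + 1
        beta <- rho[ci] * sum(Y[, ci] * q)
        q <- q + (alpha[ci] - beta) * S[, ci]
      }
    } else {
      q <- q / max(1, sqrt(sum(q^2)))
    }
    d <- -q
    if (sum(d * (-f)) > 0) d <- f / max(1, sqrt(sum(f^2)))  # ensure along force
    dn <- sqrt(sum(d^2))
    if (dn > max_disp) d <- d * (max_disp / dn)
    xn <- x + d
    fn <- force_fn(xn)
    sv <- xn - x
    yv <- -(fn - f)   # y = grad difference = -(force difference)
    sy <- sum(sv * yv)
    if (sy > 1e-12) {
      stored <- stored + 1L
      ci <- ((stored - 1) %% memory) + 1
      S[, ci] <- sv; Y[, ci] <- yv; rho[ci] <- 1 / sy
    }
    x <- xn; f <- fn
  }
  list(x = x, force = f, rms = sqrt(mean(f^2)), n_iter = k)
}

# FIRE (fast inertial relaxation engine): robust first-order relaxation for
# force fields without a consistent scalar objective; the workhorse for band
# relaxation.
fire_relax <- function(x0, force_fn, max_iter = 1000L, rms_tol = 1e-3,
                       max_disp = 0.1, dt0 = 0.02) {
  x <- x0
  v <- numeric(length(x))
  dt <- dt0
  dt_max <- 10 * dt0
  alpha <- 0.1
  n_pos <- 0L
  f <- force_fn(x)
  for (k in seq_len(max_iter)) {
    rms <- sqrt(mean(f^2))
    if (rms <= rms_tol) break
    P <- sum(f * v)
    if (P > 0) {
      n_pos <- n_pos + 1L
      fn <- sqrt(sum(f^2))
      vn <- sqrt(sum(v^2))
      v <- (1 - alpha) * v + alpha * (vn / max(fn, 1e-30)) * f
      if (n_pos > 5L) {
        dt <- min(dt * 1.1, dt_max)
        alpha <- alpha * 0.99
      }
    } else {
      v <- v * 0
      dt <- dt * 0.5
      alpha <- 0.1
      n_pos <- 0L
    }
    v <- v + dt * f
    step <- dt * v
    sn <- sqrt(sum(step^2))
    if (sn > max_disp) step <- step * (max_disp / sn)
    x <- x + step
    f <- force_fn(x)
  }
  list(x = x, force = f, rms = sqrt(mean(f^2)), n_iter = k)
}

#' Doubly-nudged elastic band transition-state candidates
#'
#' Relaxes a chain of images between two minima under the doubly-nudged
#' force (perpendicular true gradient + parallel spring force + the retained
#' perpendicular spring component) and returns interior images that are local
#' energy maxima along the band.
#'
#' @param surface A `potential_surface`.
#' @param x_a,x_b Converged endpoint minima (must be distinct under the
#'   database identity rule).
#' @param n_images Number of interior images (default 11).
#' @param spring_constant Band spring constant.
#' @param max_iter Band relaxation iteration budget.
#' @param rms_tol Convergence threshold on the RMS band force.
#' @return List of candidate configurations (possibly empty on a monotone
#'   band), highest-energy candidate first, with attributes `energies` and
#'   `band` (the relaxed image matrix).
#' @export
dneb_candidates <- function(surface, x_a, x_b, n_images = 11L,
                            spring_constant = 10, max_iter = 1000L,
                            rms_tol = 1e-3) {
  if (n_images < 1) stop("need at least one interior image")
  if (config_distance(surface, x_a, x_b) < RMSD_ID_TOL)
    stop("degenerate endpoints")
  n <- surface$n_dof
  m <- n_images
  # linear interpolation, tiny transverse jitter to break exact symmetry
  lam <- seq(0, 1, length.out = m + 2)
  band <- vapply(lam, function(l) (1 - l) * x_a + l * x_b, numeric(n))
  band <- if (n == 1) matrix(band, ncol = 1) else t(band)
  band_force <- function(flat) {
    B <- matrix(flat, nrow = m, byrow = TRUE)
    Y <- rbind(matrix(x_a, 1), B, matrix(x_b, 1))
    E <- apply(Y, 1, surface$energy)
    Fout <- matrix(0, m, n)
    for (i in 2:(m + 1)) {
      # Henkelman improved tangent
      dp <- Y[i + 1, ] - Y[i, ]
      dm <- Y[i, ] - Y[i - 1, ]
      if (E[i + 1] > E[i] && E[i] > E[i - 1]) tau <- dp
      else if (E[i + 1] < E[i] && E[i] < E[i - 1]) tau <- dm
      else {
        dEmax <- max(abs(E[i + 1] - E[i]), abs(E[i - 1] - E[i]))
        dEmin <- min(abs(E[i + 1] - E[i]), abs(E[i - 1] - E[i]))
        tau <- if (E[i + 1] > E[i - 1]) dp * dEmax + dm * dEmin
               else dp * dEmin + dm * dEmax
      }
      tau <- tau / sqrt(sum(tau^2))
      g <- surface$gradient(Y[i, ])
      gperp <- g - sum(g * tau) * tau
      fspring_par <- spring_constant * (sqrt(sum(dp^2)) - sqrt(sum(dm^2))) * tau
      fs <- spring_constant * (dp - dm)
      fsperp <- fs - sum(fs * tau) * tau
      gph <- gperp / max(sqrt(sum(gperp^2)), 1e-12)
      fdneb <- fsperp - sum(fsperp * gph) * gph   # doubly-nudged retention
      Fout[i - 1, ] <- -gperp + fspring_par + fdneb
    }
    as.numeric(t(Fout))
  }
  rel <- fire_relax(as.numeric(t(band[2:(m + 1), , drop = FALSE])),
                    band_force, max_iter = max_iter, rms_tol = rms_tol,
                    max_disp = 0.1 * surface$scale,
                    dt0 = 0.02 * surface$scale)
  B <- matrix(rel$x, nrow = m, byrow = TRUE)
  Y <- rbind(matrix(x_a, 1), B, matrix(x_b, 1))
  E <- apply(Y, 1, surface$energy)
  cand_idx <- which(vapply(2:(m + 1), function(i)
    E[i] > E[i - 1] && E[i] > E[i + 1], logical(1))) + 1L
  cand_idx <- cand_idx[order(E[cand_idx], decreasing = TRUE)]
  out <- lapply(cand_idx, function(i) Y[i, ])
  attr(out, "energies") <- E[cand_idx]
  attr(out, "band") <- Y
  attr(out, "band_energies") <- E
  out
}

#' Refine a transition-state candidate (hybrid eigenvector-following)
#'
#' Steps uphill along the lowest non-zero Hessian eigenvector under a trust
#' radius while minimising the energy in the orthogonal subspace, until the
#' RMS gradient drops below `rms_tol` at an index-1 stationary point.
#'
#' @param surface A `potential_surface`.
#' @param x0 Starting configuration.
#' @param rms_tol Gradient convergence threshold.
#' @param max_iter Outer iteration budget.
#' @param trust0 Initial trust radius (units of the coordinates).
#' @return A `transition_state_result`: `x_ts`, `energy`,
#'   `negative_eigenvalue`, `eigenvector`, `rms_gradient`, `converged`,
#'   `hessian_index`.
#' @export
refine_transition_state <- function(surface, x0, rms_tol = 1e-5,
                                    max_iter = 300L, trust0 = 0.1) {
  x <- as.numeric(x0)
  if (!all(is.finite(x))) stop("x0 must be finite")
  trust <- trust0 * surface$scale
  trust_min <- 1e-5 * surface$scale
  trust_max <- 0.5 * surface$scale
  for (it in seq_len(max_iter)) {
    ev <- normal_mode_eigen(surface, x)
    lam <- ev$values[1]
    v <- ev$vectors[, 1]
    g <- surface$gradient(x)
    rms <- sqrt(mean(g^2))
    idx <- hessian_index(ev$values)
    if (rms <= rms_tol) {
      res <- list(x_ts = x, energy = surface$energy(x),
                  negative_eigenvalue = lam, eigenvector = v,
                  rms_gradient = rms, converged = idx == 1,
                  hessian_index = idx)
      class(res) <- "transition_state_result"
      return(res)
    }
    e_here <- surface$energy(x)
    gpar <- sum(g * v)
    if (lam < 0) {
      s1 <- -gpar / lam            # Newton step along the soft mode
      if (abs(s1) > trust) s1 <- sign(s1) * trust
    } else {
      s1 <- (if (gpar >= 0) 1 else -1) * trust   # push uphill
    }
    step <- s1 * v
    pred <- gpar * s1 + 0.5 * lam * s1^2
    xt <- x + step
    # minimise in the subspace orthogonal to v
    sub <- force_lbfgs(xt, function(y) {
      gy <- surface$gradient(y)
      -(gy - sum(gy * v) * v)
    }, max_iter = 30L, rms_tol = rms_tol / 2, max_disp = 0.2 * surface$scale)
    xt <- sub$x
    act <- surface$energy(x + step) - e_here
    ratio <- if (abs(pred) > 1e-14) act / pred else 1
    if (is.finite(ratio)) {
      if (ratio > 0.75 && ratio < 1.25) trust <- min(trust * 2, trust_max)
      else if (ratio < 0.25 || ratio > 4) trust <- max(trust / 2, trust_min)
    }
    x <- xt
  }
  ev <- normal_mode_eigen(surface, x)
  g <- surface$gradient(x)
  res <- list(x_ts = x, energy = surface$energy(x),
              negative_eigenvalue = ev$values[1],
              eigenvector = ev$vectors[, 1],
              rms_gradient = sqrt(mean(g^2)), converged = FALSE,
              hessian_index = hessian_index(ev$values))
  class(res) <- "transition_state_result"
  res
}

#' @export
print.transition_state_result <- function(x, ...) {
  cat("<transition_state_result> E =", format(x$energy, digits = 10),
      " lambda- =", format(x$negative_eigenvalue, digits = 4),
      " index:", x$hessian_index, " converged:", x$converged, "\n")
  invisible(x)
}

#' Steepest-descent connection of a transition state to its two minima
#'
#' Displaces off the saddle by `displacement` along +/- the negative-mode
#' eigenvector and minimises both sides.
#'
#' @param surface A `potential_surface`.
#' @param ts A converged `transition_state_result`.
#' @param displacement Push-off magnitude (default 0.01 x surface scale).
#' @param rms_tol Minimisation tolerance.
#' @return A `min_ts_min_triple`: `minus_minimum`, `ts`, `plus_minimum`,
#'   `degenerate` (both descents reached the same minimum).
#' @export
descend_to_minima <- function(surface, ts, displacement = 0.01 * surface$scale,
                              rms_tol = 1e-5) {
  if (!isTRUE(ts$converged)) stop("transition state must be converged")
  if (displacement <= 0) stop("displacement must be positive (no descent direction)")
  v <- ts$eigenvector
  mm <- local_minimize(surface, ts$x_ts - displacement * v, rms_tol = rms_tol)
  mp <- local_minimize(surface, ts$x_ts + displacement * v, rms_tol = rms_tol)
  if (ts$energy < max(mm$energy, mp$energy) - 1e-8)
    stop("TS energy below a connected minimum: descent left the channel")
  tri <- list(minus_minimum = mm, ts = ts, plus_minimum = mp,
              degenerate = config_distance(surface, mm$x_min, mp$x_min) <
                RMSD_ID_TOL)
  class(tri) <- "min_ts_min_triple"
  tri
}

# one full DNEB -> refine -> descend -> insert attempt between two
# configurations; returns number of new TSs inserted
attempt_connection <- function(db, surface, xa, xb, n_images = 11L,
                               rms_tol = 1e-5, band_tol = 1e-3) {
  cands <- tryCatch(
    dneb_candidates(surface, xa, xb, n_images = n_images, rms_tol = band_tol),
    error = function(e) list())
  n_new <- 0L
  for (cand in cands) {
    ts <- tryCatch(refine_transition_state(surface, cand, rms_tol = rms_tol),
                   error = function(e) NULL)
    if (is.null(ts) || !ts$converged) next
    tri <- tryCatch(descend_to_minima(surface, ts, rms_tol = rms_tol),
                    error = function(e) NULL)
    if (is.null(tri) || !tri$minus_minimum$converged ||
        !tri$plus_minimum$converged) next
    ins <- tryCatch({
      add_minimum(db, tri$minus_minimum, surface)
      add_minimum(db, tri$plus_minimum, surface)
      add_transition_state(db, ts, tri, surface)
    }, error = function(e) NULL)
    if (!is.null(ins) && ins$is_new) n_new <- n_new + 1L
  }
  n_new
}

#' Grow the database until two minima are connected
#'
#' Repeatedly selects the most promising unconnected gap on the current best
#' incomplete path (Dijkstra on a mixed graph where existing transition-state
#' edges cost nothing and missing edges cost squared distance) and attempts a
#' DNEB / eigenvector-following / descent cycle across it, inserting every
#' converged stationary point found.
#'
#' @param surface A `potential_surface`.
#' @param m_a,m_b Ids of minima already in `db`.
#' @param db A `ktn`.
#' @param max_cycles Connection cycle budget.
#' @param n_images Interior DNEB images for the first attempt at a gap
#'   (subsequent attempts at the same gap use more).
#' @param rms_tol Stationary-point convergence tolerance.
#' @param attempt_even_if_connected Attempt a direct DNEB between `m_a` and
#'   `m_b` even when a path already exists (used by the refinement drivers).
#' @return List with `db`, `status` (`"connected"` or `"unconnected"`),
#'   `cycles` used.
#' @export
connect_minima <- function(surface, m_a, m_b, db, max_cycles = 20L,
                           n_images = 11L, rms_tol = 1e-5,
                           attempt_even_if_connected = FALSE) {
  if (is.null(ktn_minimum(db, m_a)) || is.null(ktn_minimum(db, m_b)))
    stop("both endpoints must already be in the database")
  if (is.null(db$connect_attempts))
    db$connect_attempts <- new.env(parent = emptyenv())
  if (attempt_even_if_connected) {
    attempt_connection(db, surface, ktn_minimum(db, m_a)$coords,
                       ktn_minimum(db, m_b)$coords,
                       n_images = n_images, rms_tol = rms_tol)
    status <- if (ktn_connected(db, m_a, m_b)) "connected" else "unconnected"
    return(list(db = db, status = status, cycles = 1L))
  }
  for (cyc in seq_len(max_cycles)) {
    if (ktn_connected(db, m_a, m_b))
      return(list(db = db, status = "connected", cycles = cyc - 1L))
    gaps <- best_gap_pairs(db, surface, m_a, m_b)
    if (!nrow(gaps)) break
    progressed <- FALSE
    for (r in seq_len(nrow(gaps))) {
      key <- paste0(gaps$i[r], "-", gaps$j[r])
      tries <- db$connect_attempts[[key]] %||% 0L
      if (tries >= 3L) next
      db$connect_attempts[[key]] <- tries + 1L
      ni <- n_images + 10L * tries
      n_new <- attempt_connection(db, surface,
                                  ktn_minimum(db, gaps$i[r])$coords,
                                  ktn_minimum(db, gaps$j[r])$coords,
                                  n_images = ni, rms_tol = rms_tol)
      progressed <- TRUE
      break
    }
    if (!progressed) break
  }
  status <- if (ktn_connected(db, m_a, m_b)) "connected" else "unconnected"
  list(db = db, status = status, cycles = max_cycles)
}

# Dijkstra on the mixed graph: existing TS edges weight ~0, missing pairs
# squared distance; returns the missing pairs on the best path, nearest gaps
# first.
best_gap_pairs <- function(db, surface, m_a, m_b) {
  ids <- ktn_min_ids(db)
  n <- length(ids)
  pos <- lapply(ids, function(i) ktn_minimum(db, i)$coords)
  idx_of <- setNames(seq_len(n), ids)
  W <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    W[i, j] <- W[j, i] <- config_distance(surface, pos[[i]], pos[[j]])^2
  }
  ed <- ktn_edges(db)
  eps <- 1e-9
  for (r in seq_len(nrow(ed))) {
    i <- idx_of[as.character(ed$m1[r])]; j <- idx_of[as.character(ed$m2[r])]
    W[i, j] <- W[j, i] <- eps
  }
  g <- igraph::graph_from_adjacency_matrix(ifelse(is.finite(W), W, 0),
                                           mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  sp <- igraph::shortest_paths(g, from = idx_of[as.character(m_a)],
                               to = idx_of[as.character(m_b)],
                               weights = igraph::E(g)$weight)$vpath[[1]]
  v <- as.integer(sp)
  if (length(v) < 2) return(data.frame(i = integer(), j = integer()))
  out <- data.frame(i = integer(), j = integer(), w = numeric())
  for (k in seq_len(length(v) - 1)) {
    if (W[v[k], v[k + 1]] > eps * 2)
      out <- rbind(out, data.frame(i = ids[v[k]], j = ids[v[k + 1]],
                                   w = W[v[k], v[k + 1]]))
  }
  out[order(out$w), , drop = FALSE]
}
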