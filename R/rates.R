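# Phenomenological two-state rate constants: graph-transformation node
# elimination, and an exact linear-algebra oracle on the master-equation
# generator. Both compute the committor-weighted equilibrium escape flux
#   k_AB = sum_{b in B} (p_b / p_B) P_{A<-b} / tau_b ,
# where P_{A<-b} is the probability that the walk from b reaches A before
# any B state and tau_b is the waiting time in b. This flux definition obeys
# detailed balance exactly: k_AB p_B = k_BA p_A.

# jump-chain ingredients for either a ktn (HSA/TST rates) or a regrouped
# network (group-level HSA-TST rates)
transition_ingredients <- function(x, T, kB) {
  if (inherits(x, "regrouped_network")) {
    db <- x$db
    beta <- 1 / (kB * x$temperature)
    if (abs(x$temperature - T) > 1e-12)
      warning("using the regrouping temperature ", x$temperature)
    member <- x$membership
    # group weights and inter-group TS weight sums
    wmin <- exp(-beta * db$min_energies[names(member)] -
      vapply(names(member), function(i)
        ktn_minimum(db, i)$log_product_frequencies, numeric(1)))
    wg <- vapply(split(wmin, member), sum, numeric(1))
    G <- length(x$groups)
    K <- matrix(0, G, G, dimnames = list(seq_len(G), seq_len(G)))
    for (t in db$ts) {
      if (t$min_minus == t$min_plus) next
      ga <- member[as.character(t$min_minus)]
      gb <- member[as.character(t$min_plus)]
      if (ga == gb) next
      wts <- exp(-beta * t$energy - t$log_product_frequencies)
      K[gb, ga] <- K[gb, ga] + wts / wg[as.character(ga)]
      K[ga, gb] <- K[ga, gb] + wts / wg[as.character(gb)]
    }
    p <- wg / sum(wg)
    list(ids = as.integer(names(wg)), K = K, p = unname(p),
         map = function(min_ids) unique(unname(member[as.character(min_ids)])))
  } else {
    rm <- ktn_rate_matrix(x, T, kB)
    st <- hsa_free_energies(x, T, kB = kB)
    list(ids = rm$ids, K = rm$K, p = unname(st$occupations[as.character(rm$ids)]),
         map = function(min_ids) min_ids)
  }
}

# GT node elimination on jump probabilities; returns renormalised P and both
# waiting-time vectors over the surviving nodes
gt_eliminate <- function(P, tau, keep) {
  nodes <- seq_len(nrow(P))
  tau_orig <- tau
  interior <- setdiff(nodes, keep)
  alive <- rep(TRUE, length(nodes))
  while (length(interior)) {
    deg <- vapply(interior, function(x)
      sum(P[, x] > 0 & alive & seq_along(alive) != x), numeric(1))
    x <- interior[order(deg, interior)][1]
    px <- P[x, x]
    denom <- 1 - px
    if (denom < 1e-14) denom <- sum(P[alive & nodes != x, x])  # renormalise
    nb_in <- which(P[x, ] > 0 & alive & nodes != x)    # u with u -> x
    nb_out <- which(P[, x] > 0 & alive & nodes != x)   # v with x -> v
    for (u in nb_in) {
      pux <- P[x, u]
      P[nb_out, u] <- P[nb_out, u] + P[nb_out, x] * pux / denom
      tau[u] <- tau[u] + pux * tau[x] / denom
      P[x, u] <- 0
    }
    P[, x] <- 0
    alive[x] <- FALSE
    interior <- setdiff(interior, x)
  }
  list(P = P, tau = tau, tau_orig = tau_orig, alive = alive)
}

#' Graph-transformation phenomenological two-state rates
#'
#' Eliminates all intermediate minima (minimum-degree order, ties by id) by
#' the graph-transformation update
#' `P'_uv = P_uv + P_ux P_xv / (1 - P_xx)`,
#' `tau'_u = tau_u + P_ux tau_x / (1 - P_xx)`, then assembles
#' `k_AB = sum_b (p_b/p_B) P_{A<-b}/tau_b` (and symmetrically `k_BA`).
#' Waiting-time renormalised (mean-first-passage) rates are reported
#' alongside as `k_AB_mfpt` / `k_BA_mfpt`.
#'
#' @param x A `ktn` or a `regrouped_network`.
#' @param A_set,B_set Disjoint non-empty sets of minima ids (mapped to their
#'   groups for a regrouped network).
#' @param T Temperature.
#' @param kB Boltzmann constant.
#' @return A `phenomenological_rates` list: `k_AB`, `k_BA`, `k_AB_mfpt`,
#'   `k_BA_mfpt`, `p_A`, `p_B`, `A_set`, `B_set`, `temperature`.
#' @export
graph_transform_rates <- function(x, A_set, B_set, T, kB = 1) {
  ing <- transition_ingredients(x, T, kB)
  A <- match(ing$map(A_set), ing$ids)
  B <- match(ing$map(B_set), ing$ids)
  if (!length(A) || !length(B)) stop("A and B must be non-empty")
  if (any(is.na(A)) || any(is.na(B))) stop("unknown minima in A or B")
  if (length(intersect(A, B))) stop("A and B must be disjoint")
  esc <- colSums(ing$K)
  if (any(esc[c(A, B)] <= 0)) stop("A/B states must have outgoing transitions")
  tau <- 1 / esc
  tau[!is.finite(tau)] <- 0
  P <- sweep(ing$K, 2, ifelse(esc > 0, esc, 1), "/")
  gt <- gt_eliminate(P, tau, keep = c(A, B))
  one_dir <- function(Aset, Bset) {
    pB <- sum(ing$p[Bset])
    kk <- 0; kk_m <- 0
    for (b in Bset) {
      PAb <- sum(gt$P[Aset, b])
      kk <- kk + unname(ing$p[b] / pB * PAb / gt$tau_orig[b])
      kk_m <- kk_m + unname(ing$p[b] / pB * PAb / gt$tau[b])
    }
    c(ss = kk, mfpt = kk_m)
  }
  ab <- one_dir(A, B)
  ba <- one_dir(B, A)
  out <- list(k_AB = unname(ab["ss"]), k_BA = unname(ba["ss"]),
              k_AB_mfpt = unname(ab["mfpt"]), k_BA_mfpt = unname(ba["mfpt"]),
              p_A = sum(ing$p[A]), p_B = sum(ing$p[B]),
              A_set = A_set, B_set = B_set, temperature = T)
  class(out) <- "phenomenological_rates"
  out
}

#' @export
print.phenomenological_rates <- function(x, ...) {
  cat("<phenomenological_rates> k_AB =", format(x$k_AB, digits = 6),
      " k_BA =", format(x$k_BA, digits = 6),
      " (p_A =", format(x$p_A, digits = 4),
      ", p_B =", format(x$p_B, digits = 4), ")\n")
  invisible(x)
}

#' Exact master-equation rate oracle
#'
#' Independent linear-algebra route to the same phenomenological rates as
#' [graph_transform_rates()]: the stationary distribution comes from the
#' generator's null space and the committor (probability of reaching A
#' before B) from a direct linear solve over the intermediate states.
#'
#' @param K Generator matrix: `K[v, u]` is the `u -> v` rate for `v != u`;
#'   columns sum to zero (the diagonal is ignored and rebuilt).
#' @param A_set,B_set Disjoint non-empty index sets (into the rows of `K`).
#' @return A `phenomenological_rates` list (same fields as
#'   [graph_transform_rates()]).
#' @export
exact_rate_oracle <- function(K, A_set, B_set) {
  n <- nrow(K)
  off <- K; diag(off) <- 0
  esc <- colSums(off)
  gen <- off; diag(gen) <- -esc
  # stationary distribution: null space of gen
  ns <- svd(gen)
  pi_eq <- abs(ns$v[, n])
  pi_eq <- pi_eq / sum(pi_eq)
  tau <- 1 / esc
  P <- sweep(off, 2, esc, "/")
  committor_flux <- function(A, B) {
    I <- setdiff(seq_len(n), c(A, B))
    # h_x = P(reach A before B | start x), for intermediates
    if (length(I)) {
      M <- diag(length(I)) - t(P[I, I, drop = FALSE])
      rhs <- vapply(I, function(x) sum(P[A, x]), numeric(1))
      h <- solve(M, rhs)
    } else h <- numeric(0)
    pB <- sum(pi_eq[B])
    kk <- 0
    for (b in B) {
      PAb <- sum(P[A, b]) + if (length(I)) sum(P[I, b] * h) else 0
      kk <- kk + unname(pi_eq[b] / pB * PAb / tau[b])
    }
    kk
  }
  out <- list(k_AB = committor_flux(A_set, B_set),
              k_BA = committor_flux(B_set, A_set),
              p_A = sum(pi_eq[A_set]), p_B = sum(pi_eq[B_set]),
              A_set = A_set, B_set = B_set, temperature = NA_real_)
  class(out) <- "phenomenological_rates"
  out
}

#' Rate table against a reference minimum
#'
#' For each target, graph-transformation rates both ways between the
#' reference and the target (all other minima acting as intermediates) and
#' harmonic-superposition populations. `k_fold` is the rate into the
#' reference from the target, `k_unfold` the reverse.
#'
#' @param db A `ktn`.
#' @param reference_min Reference minimum id (e.g. the helix funnel bottom).
#' @param targets Ids of target minima.
#' @param T Temperature.
#' @param kB Boltzmann constant.
#' @return data.frame with `target`, `k_fold`, `k_unfold`, `p_eq` (target
#'   occupation) and `p_ref`.
#' @export
rate_table <- function(db, reference_min, targets, T, kB = 1) {
  if (reference_min %in% targets)
    stop("reference and target sets must be disjoint")
  st <- hsa_free_energies(db, T, kB = kB)
  rows <- lapply(targets, function(tg) {
    r <- graph_transform_rates(db, A_set = tg, B_set = reference_min,
                               T = T, kB = kB)
    data.frame(target = tg, k_fold = r$k_BA, k_unfold = r$k_AB,
               p_eq = unname(st$occupations[as.character(tg)]),
               p_ref = unname(st$occupations[as.character(reference_min)]))
  })
  do.call(rbind, rows)
}
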