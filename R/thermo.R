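# Harmonic superposition thermodynamics and transition-state-theory rates.
# Classical harmonic oscillators, unit masses, h = 1; the per-minimum
# statistical weight at inverse temperature beta is
#   w_i = exp(-beta E_i - logprod_i),
# where logprod_i is the sum of ln(nu) over positive normal modes. Mode-count
# dependent factors (kappa ln beta) are common to all minima of a surface and
# cancel in occupation probabilities; they are included in free energies.

# statistical weight exponent (log w)
hsa_log_weight <- function(energy, logprod, T, kB) {
  -energy / (kB * T) - logprod
}

#' Harmonic superposition free energies and occupations
#'
#' Per-minimum free energies and equilibrium occupation probabilities from
#' the harmonic superposition approximation over the database.
#'
#' @param db A `ktn` whose minima carry frequencies.
#' @param T Temperature (K, or reduced).
#' @param kB Boltzmann constant in the database's energy units
#'   (1 for reduced units; `0.0019872041` kcal/mol/K for the bead peptide).
#' @param n_modes Vibrational mode count per minimum (defaults to the value
#'   recorded by the generator, else 0; only shifts all free energies by a
#'   common constant).
#' @return A `thermo_state`: `temperature`, `free_energies` (named by id),
#'   `occupations`, `log_Z`, `kB`, `n_modes`.
#' @export
hsa_free_energies <- function(db, T, kB = 1, n_modes = NULL) {
  if (T <= 0) stop("T must be positive")
  ids <- ktn_min_ids(db)
  if (!length(ids)) stop("empty database")
  lp <- vapply(ids, function(i) {
    v <- ktn_minimum(db, i)$log_product_frequencies
    if (is.null(v)) stop("minimum ", i, " has no frequencies")
    v
  }, numeric(1))
  E <- unname(db$min_energies[as.character(ids)])
  kappa <- n_modes %||% db$n_modes %||% 0
  beta <- 1 / (kB * T)
  lw <- hsa_log_weight(E, lp, T, kB) - kappa * log(beta)
  M <- max(lw)
  lZ <- M + log(sum(exp(lw - M)))
  p <- exp(lw - lZ)
  st <- list(temperature = T,
             free_energies = setNames(-kB * T * lw, ids),
             occupations = setNames(p, ids),
             log_Z = lZ, kB = kB, n_modes = kappa)
  class(st) <- "thermo_state"
  st
}

#' Harmonic superposition heat capacity curve
#'
#' `Cv(T) = kappa kB + Var_occ(E) / (kB T^2)`: the vibrational baseline plus
#' the configurational contribution from energy fluctuations across minima.
#'
#' @param db A `ktn`.
#' @param T_grid Temperatures to evaluate.
#' @inheritParams hsa_free_energies
#' @return data.frame with `T`, `Cv`; attribute `peak` holds the grid
#'   temperature of the maximum.
#' @export
hsa_heat_capacity <- function(db, T_grid, kB = 1, n_modes = NULL) {
  ids <- ktn_min_ids(db)
  E <- unname(db$min_energies[as.character(ids)])
  kappa <- n_modes %||% db$n_modes %||% 0
  cv <- vapply(T_grid, function(T) {
    st <- hsa_free_energies(db, T, kB = kB, n_modes = kappa)
    p <- st$occupations
    varE <- sum(p * E^2) - sum(p * E)^2
    kappa * kB + varE / (kB * T^2)
  }, numeric(1))
  out <- data.frame(T = T_grid, Cv = cv)
  attr(out, "peak") <- T_grid[which.max(cv)]
  out
}

#' Harmonic transition-state-theory rate constant
#'
#' `k = (prod nu_min / prod nu_ts) exp(-(E_ts - E_min)/kB T)`, frequency
#' products over positive modes (the transition state has one fewer).
#'
#' @param ts A transition-state record (from the database).
#' @param from_min The minimum the transition leaves.
#' @param T Temperature.
#' @param kB Boltzmann constant in energy units.
#' @return Rate in reciprocal reduced time.
#' @export
tst_rate <- function(ts, from_min, T, kB = 1) {
  if (T <= 0) stop("T must be positive")
  if (!from_min$id %in% c(ts$min_minus, ts$min_plus))
    stop("transition state does not connect the given minimum")
  if (ts$energy < from_min$energy - 1e-9)
    stop("TS energy below its minimum: corrupt database")
  exp(from_min$log_product_frequencies - ts$log_product_frequencies -
        (ts$energy - from_min$energy) / (kB * T))
}

# full rate table between adjacent minima: list with matrix K (K[v,u] = rate
# u->v summed over connecting TSs), waiting times tau, jump probabilities P
ktn_rate_matrix <- function(db, T, kB = 1) {
  ids <- ktn_min_ids(db)
  n <- length(ids)
  idx <- setNames(seq_len(n), ids)
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  for (t in db$ts) {
    if (t$min_minus == t$min_plus) next
    i <- idx[as.character(t$min_minus)]
    j <- idx[as.character(t$min_plus)]
    K[j, i] <- K[j, i] + tst_rate(t, ktn_minimum(db, t$min_minus), T, kB)
    K[i, j] <- K[i, j] + tst_rate(t, ktn_minimum(db, t$min_plus), T, kB)
  }
  esc <- colSums(K)
  list(ids = ids, K = K, escape = esc, tau = ifelse(esc > 0, 1 / esc, Inf),
       P = sweep(K, 2, ifelse(esc > 0, esc, 1), "/"))
}

# free energies of minima and transition states (for regrouping):
# F = E + kB T (logprod + kappa ln beta); kappa differs by one between
# minima and saddles, so the convention matters only via a uniform offset.
stationary_free_energy <- function(energy, logprod, n_modes, T, kB) {
  beta <- 1 / (kB * T)
  energy + kB * T * (logprod + n_modes * log(beta))
}

#' Self-consistent free-energy regrouping
#'
#' Iteratively merges groups of minima separated by free-energy barriers
#' below `threshold` (the lowest connecting transition-state free energy
#' minus the higher group free energy), recomputing group free energies
#' `F_G = -kB T ln sum_i exp(-F_i/kB T)` after every pass, until
#' self-consistency. All qualifying pairs merge simultaneously in each pass,
#' so the result is independent of enumeration order.
#'
#' @param db A `ktn`.
#' @param T Temperature.
#' @param threshold Free-energy barrier threshold (energy units; the
#'   disordered-peptide analyses in the field typically use ~3 kcal/mol).
#' @param kB Boltzmann constant.
#' @param n_modes Vibrational mode count of minima (see
#'   [hsa_free_energies()]).
#' @return A `regrouped_network`: `groups` (list of minima-id vectors),
#'   `group_free_energies`, `inter_group_ts` (data.frame of lowest TS free
#'   energies between groups), `threshold`, `temperature`, `kB`.
#' @export
regroup_free_energy <- function(db, T, threshold, kB = 1, n_modes = NULL) {
  if (threshold < 0) stop("threshold must be >= 0")
  ids <- ktn_min_ids(db)
  kappa <- n_modes %||% db$n_modes %||% 0
  Fmin <- setNames(vapply(ids, function(i) {
    m <- ktn_minimum(db, i)
    stationary_free_energy(m$energy, m$log_product_frequencies, kappa, T, kB)
  }, numeric(1)), ids)
  Fts <- vapply(db$ts, function(t)
    stationary_free_energy(t$energy, t$log_product_frequencies,
                           max(kappa - 1, 0), T, kB), numeric(1))
  ed <- ktn_edges(db)
  ed$F <- if (nrow(ed)) unname(Fts[as.character(ed$ts_id)]) else numeric(0)
  # group bookkeeping: membership vector over minima
  member <- setNames(seq_along(ids), ids)
  group_F <- function(member) {
    vapply(split(Fmin, member), function(f) {
      M <- max(-f / (kB * T))
      -kB * T * (M + log(sum(exp(-f / (kB * T) - M))))
    }, numeric(1))
  }
  repeat {
    gF <- group_F(member)
    g1 <- member[as.character(ed$m1)]
    g2 <- member[as.character(ed$m2)]
    keep <- g1 != g2
    if (!any(keep)) break
    # free-energy barriers are reported non-negative: the harmonic prefactor
    # convention can push a TS free energy below a minimum's, which is not a
    # physical barrier; clamping also makes threshold 0 the exact identity
    bar <- pmax(0, ed$F[keep] - pmax(gF[as.character(g1[keep])],
                                     gF[as.character(g2[keep])]))
    mergers <- which(bar < threshold)
    if (!length(mergers)) break
    pairs <- cbind(g1[keep][mergers], g2[keep][mergers])
    # union-find over group labels
    parent <- setNames(unique(member), unique(member))
    find <- function(x) { while (parent[as.character(x)] != x)
      x <- parent[as.character(x)]; x }
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[as.character(max(ra, rb))] <- min(ra, rb)
    }
    member <- setNames(vapply(member, find, numeric(1)), names(member))
  }
  # relabel groups 1..G in order of appearance of their lowest minimum id
  labs <- unique(member)
  relab <- setNames(seq_along(labs), labs)
  member <- setNames(relab[as.character(member)], names(member))
  groups <- split(as.integer(names(member)), member)
  gF <- group_F(member)
  inter <- data.frame(g1 = integer(), g2 = integer(), ts_F = numeric())
  if (nrow(ed)) {
    ga <- pmin(member[as.character(ed$m1)], member[as.character(ed$m2)])
    gb <- pmax(member[as.character(ed$m1)], member[as.character(ed$m2)])
    sel <- ga != gb
    if (any(sel)) {
      agg <- stats::aggregate(ed$F[sel], list(g1 = ga[sel], g2 = gb[sel]), min)
      inter <- data.frame(g1 = agg$g1, g2 = agg$g2, ts_F = agg$x)
    }
  }
  out <- list(groups = groups,
              group_free_energies = setNames(as.numeric(gF), names(gF)),
              membership = member,
              inter_group_ts = inter, threshold = threshold,
              temperature = T, kB = kB, db = db, n_modes = kappa)
  class(out) <- "regrouped_network"
  out
}

#' @export
print.regrouped_network <- function(x, ...) {
  cat("<regrouped_network>", length(x$groups), "groups from",
      length(x$membership), "minima at threshold", x$threshold, "\n")
  invisible(x)
}
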