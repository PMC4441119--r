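# Fastest discrete paths (Dijkstra over -ln branching probabilities) and the
# database refinement drivers.

#' Fastest discrete path between two sets of minima
#'
#' Minimises `sum -ln P` over discrete paths, where
#' `P(v <- u) = k(v <- u) / sum_w k(w <- u)` is the branching probability at
#' temperature `T` with harmonic TST rates. Ties are broken deterministically:
#' fewer edges first, then the lexicographically smallest id sequence.
#'
#' @param db A `ktn`.
#' @param reactant_set,product_set Disjoint non-empty id sets; the path runs
#'   from a reactant to a product minimum.
#' @param T Temperature.
#' @param kB Boltzmann constant.
#' @return A `discrete_path`: `min_ids`, `ts_ids` (highest-rate transition
#'   state of each step), `branching_probabilities`, `weight`.
#' @export
fastest_path <- function(db, reactant_set, product_set, T, kB = 1) {
  if (!length(reactant_set) || !length(product_set))
    stop("reactant and product sets must be non-empty")
  if (length(intersect(reactant_set, product_set)))
    stop("reactant and product sets must be disjoint")
  rm <- ktn_rate_matrix(db, T, kB)
  ids <- rm$ids
  idx <- setNames(seq_along(ids), ids)
  n <- length(ids)
  W <- matrix(Inf, n, n)
  pos <- rm$K > 0
  W[pos] <- -log(rm$P[pos])     # W[v, u]: cost of step u -> v
  src <- idx[as.character(reactant_set)]
  dst <- idx[as.character(product_set)]
  if (any(is.na(src)) || any(is.na(dst))) stop("unknown minima ids")
  # Dijkstra with (weight, n_edges, lexicographic path) ordering
  dist <- rep(Inf, n); nedge <- rep(Inf, n)
  prev <- rep(NA_integer_, n)
  dist[src] <- 0; nedge[src] <- 0
  done <- rep(FALSE, n)
  path_key <- function(v) {       # id sequence back to source
    out <- integer(0)
    while (!is.na(v)) { out <- c(ids[v], out); v <- prev[v] }
    out
  }
  lex_less <- function(a, b) {
    for (k in seq_len(min(length(a), length(b)))) {
      if (a[k] < b[k]) return(TRUE)
      if (a[k] > b[k]) return(FALSE)
    }
    length(a) < length(b)
  }
  for (rep_i in seq_len(n)) {
    u <- NA_integer_
    for (v in which(!done)) {
      if (!is.finite(dist[v])) next
      if (is.na(u) || dist[v] < dist[u] - 1e-15 ||
          (abs(dist[v] - dist[u]) <= 1e-15 && nedge[v] < nedge[u]))
        u <- v
    }
    if (is.na(u)) break
    done[u] <- TRUE
    for (v in which(is.finite(W[, u]))) {
      if (done[v]) next
      nd <- dist[u] + W[v, u]
      better <- nd < dist[v] - 1e-15 ||
        (abs(nd - dist[v]) <= 1e-15 &&
           (nedge[u] + 1 < nedge[v] ||
              (nedge[u] + 1 == nedge[v] && !is.na(prev[v]) &&
                 lex_less(c(path_key(u), ids[v]), path_key(v)))))
      if (better) { dist[v] <- nd; nedge[v] <- nedge[u] + 1; prev[v] <- u }
    }
  }
  reach <- dst[is.finite(dist[dst])]
  if (!length(reach)) {
    comp <- igraph::components(ktn_graph(db))$membership
    stop("disconnected: reactant component(s) {",
         paste(unique(comp[as.character(reactant_set)]), collapse = ","),
         "} vs product component(s) {",
         paste(unique(comp[as.character(product_set)]), collapse = ","), "}")
  }
  end <- reach[which.min(dist[reach])]
  vpath <- rev(unlist(local({
    out <- list(); v <- end
    while (!is.na(v)) { out[[length(out) + 1]] <- v; v <- prev[v] }
    out
  })))
  min_ids <- ids[vpath]
  ed <- ktn_edges(db)
  ts_ids <- integer(0); probs <- numeric(0)
  for (k in seq_len(length(vpath) - 1)) {
    u <- vpath[k]; v <- vpath[k + 1]
    probs <- c(probs, rm$P[v, u])
    cand <- ed[(ed$m1 == ids[u] & ed$m2 == ids[v]) |
                 (ed$m2 == ids[u] & ed$m1 == ids[v]), , drop = FALSE]
    ts_ids <- c(ts_ids, cand$ts_id[which.min(cand$energy)])
  }
  out <- list(min_ids = unname(min_ids), ts_ids = ts_ids,
              branching_probabilities = probs, weight = sum(-log(probs)),
              temperature = T)
  class(out) <- "discrete_path"
  out
}

#' @export
print.discrete_path <- function(x, ...) {
  cat("<discrete_path>", paste(x$min_ids, collapse = " -> "),
      " weight =", format(x$weight, digits = 6), "\n")
  invisible(x)
}

#' SHORTCUT BARRIER database refinement
#'
#' Repeatedly takes the current fastest path, finds its highest potential
#' energy transition state, and launches a fresh connection attempt between
#' the two minima flanking that barrier, until successive graph-transformation
#' rate estimates agree within a factor of 10 or the budget is exhausted.
#'
#' @param db A `ktn` with a connected reactant-product fastest path.
#' @param surface The underlying `potential_surface`.
#' @param reactant_set,product_set Minima id sets.
#' @param T Temperature.
#' @param budget Maximum refinement cycles (0 = no-op).
#' @param kB Boltzmann constant.
#' @param convergence_factor Successive-rate ratio regarded as converged.
#' @return List with `db`, `status` (`"converged"`/`"unconverged"`/`"no-op"`),
#'   `rate_history` (k_AB after each stage).
#' @export
shortcut_barrier_refine <- function(db, surface, reactant_set, product_set,
                                    T, budget = 5L, kB = 1,
                                    convergence_factor = 10) {
  if (budget <= 0) return(list(db = db, status = "no-op",
                               rate_history = numeric(0)))
  rate <- function() graph_transform_rates(db, A_set = product_set,
                                           B_set = reactant_set,
                                           T = T, kB = kB)$k_AB
  history <- rate()
  status <- "unconverged"
  for (cyc in seq_len(budget)) {
    path <- fastest_path(db, reactant_set, product_set, T, kB)
    ts_e <- vapply(path$ts_ids, function(i) ktn_ts(db, i)$energy, numeric(1))
    hi <- which.max(ts_e)
    # leapfrog the barrier region: take the minima one step beyond the
    # immediate flanking pair where the path allows, so the attempt can
    # discover a direct lower saddle bypassing the barrier
    lo_i <- max(1L, hi - 1L)
    hi_i <- min(length(path$min_ids), hi + 2L)
    pair <- path$min_ids[c(lo_i, hi_i)]
    connect_minima(surface, pair[1], pair[2], db,
                   attempt_even_if_connected = TRUE)
    history <- c(history, rate())
    m <- length(history)
    if (history[m] > 0 && history[m - 1] > 0 &&
        abs(log10(history[m] / history[m - 1])) < log10(convergence_factor)) {
      status <- "converged"
      break
    }
  }
  list(db = db, status = status, rate_history = history)
}

# minimax barrier from every minimum to a target set: lowest achievable
# highest-TS energy along any path (widest-path Dijkstra variant)
minimax_barriers <- function(db, target_set) {
  ids <- ktn_min_ids(db)
  idx <- setNames(seq_along(ids), ids)
  n <- length(ids)
  ed <- ktn_edges(db)
  ed <- ed[ed$m1 != ed$m2, , drop = FALSE]
  best <- rep(Inf, n)
  best[idx[as.character(target_set)]] <- -Inf
  done <- rep(FALSE, n)
  repeat {
    cand <- which(!done & best < Inf)
    if (!length(cand)) break
    u <- cand[which.min(best[cand])]
    done[u] <- TRUE
    rows <- which(ed$m1 == ids[u] | ed$m2 == ids[u])
    for (r in rows) {
      v <- idx[as.character(if (ed$m1[r] == ids[u]) ed$m2[r] else ed$m1[r])]
      if (done[v]) next
      nb <- max(best[u], ed$energy[r])
      if (nb < best[v]) best[v] <- nb
    }
  }
  setNames(best, ids)
}

#' UNTRAP database refinement
#'
#' Ranks minima by the ratio (potential-energy barrier towards the product
#' set) / (energy above the product set) and attempts a fresh connection from
#' the top-ranked trapped minimum to the product-set minimum nearest in
#' configuration space, repeating up to `budget` times.
#'
#' @param db A `ktn`.
#' @param surface The underlying `potential_surface`.
#' @param product_set Minima ids forming the product group.
#' @param T Temperature (recorded; the ranking is energy-based).
#' @param budget Attempt budget.
#' @param kB Boltzmann constant.
#' @param barrier_threshold Minima whose barrier towards the product set is
#'   below this are not considered trapped.
#' @return List with `db`, `attempts` (data.frame of chosen pairs and whether
#'   a new TS appeared).
#' @export
untrap_refine <- function(db, surface, product_set, T, budget = 3L, kB = 1,
                          barrier_threshold = 0) {
  attempts <- data.frame(from = integer(), to = integer(), new_ts = logical())
  e_prod <- min(db$min_energies[as.character(product_set)])
  for (cyc in seq_len(max(budget, 0L))) {
    bar <- minimax_barriers(db, product_set)
    ids <- as.integer(names(bar))
    cand <- setdiff(ids, product_set)
    height <- bar[as.character(cand)] - db$min_energies[as.character(cand)]
    # disconnected minima have infinite barrier: maximally trapped; minima
    # level with (or below) the product set rank by barrier alone
    above <- pmax(db$min_energies[as.character(cand)] - e_prod, 1e-12)
    ok <- !is.na(height) & height > barrier_threshold
    if (!any(ok)) break
    score <- height[ok] / above[ok]
    pick <- cand[ok][order(-score, cand[ok])][1]
    dists <- vapply(product_set, function(pm)
      config_distance(surface, ktn_minimum(db, pick)$coords,
                      ktn_minimum(db, pm)$coords), numeric(1))
    tgt <- product_set[which.min(dists)]
    n_ts0 <- ktn_n_ts(db)
    connect_minima(surface, pick, tgt, db, attempt_even_if_connected = TRUE)
    attempts <- rbind(attempts, data.frame(from = pick, to = tgt,
                                           new_ts = ktn_n_ts(db) > n_ts0))
  }
  list(db = db, attempts = attempts)
}
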