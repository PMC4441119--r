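#' Create an empty kinetic transition network (stationary-point database)
#'
#' A `ktn` is an environment holding id-indexed minima and transition states.
#' Minima carry energy, coordinates, the log-product of their positive
#' normal-mode frequencies, and cached order parameters; transition states
#' additionally reference the two minima they connect. Adjacency is derived
#' from transition-state connectivity and is always symmetric.
#'
#' @param surface_name Optional label of the surface the database belongs to.
#' @return An empty `ktn` object.
#' @export
ktn_new <- function(surface_name = NA_character_) {
  db <- new.env(parent = emptyenv())
  db$minima <- list()
  db$ts <- list()
  db$min_energies <- numeric(0)    # names = ids
  db$ts_energies <- numeric(0)
  db$next_min_id <- 1L
  db$next_ts_id <- 1L
  db$surface_name <- surface_name
  class(db) <- "ktn"
  db
}

#' @export
print.ktn <- function(x, ...) {
  cat("<ktn>", ktn_n_minima(x), "minima,", ktn_n_ts(x), "transition states\n")
  invisible(x)
}

#' Number of minima / transition states in a database
#' @param db A `ktn`.
#' @return Integer count.
#' @export
ktn_n_minima <- function(db) length(db$minima)

#' @rdname ktn_n_minima
#' @export
ktn_n_ts <- function(db) length(db$ts)

#' Minimum and transition-state records
#' @param db A `ktn`.
#' @param id Record id.
#' @return The stored record (list).
#' @export
ktn_minimum <- function(db, id) db$minima[[as.character(id)]]

#' @rdname ktn_minimum
#' @export
ktn_ts <- function(db, id) db$ts[[as.character(id)]]

#' All minima ids / energies
#' @param db A `ktn`.
#' @return Integer vector of ids, or named numeric vector of energies.
#' @export
ktn_min_ids <- function(db) as.integer(names(db$min_energies))

#' @rdname ktn_min_ids
#' @export
ktn_min_energies <- function(db) db$min_energies

#' Transition-state edge table
#'
#' @param db A `ktn`.
#' @return data.frame with `ts_id`, `m1`, `m2`, `energy`, `degenerate`.
#' @export
ktn_edges <- function(db) {
  if (!length(db$ts))
    return(data.frame(ts_id = integer(), m1 = integer(), m2 = integer(),
                      energy = numeric(), degenerate = logical()))
  do.call(rbind, lapply(db$ts, function(t)
    data.frame(ts_id = t$id, m1 = t$min_minus, m2 = t$min_plus,
               energy = t$energy, degenerate = isTRUE(t$degenerate))))
}

# ------------------------------------------------------------------ identity

ENERGY_ID_TOL <- 1e-6
RMSD_ID_TOL <- 1e-3

find_matching_minimum <- function(db, surface, x, energy) {
  cand <- which(abs(db$min_energies - energy) < ENERGY_ID_TOL)
  for (i in cand) {
    rec <- db$minima[[i]]
    if (is.null(surface) || is.null(rec$coords)) return(rec$id)
    if (config_distance(surface, rec$coords, x) < RMSD_ID_TOL) return(rec$id)
  }
  NA_integer_
}

find_matching_ts <- function(db, surface, x, energy) {
  cand <- which(abs(db$ts_energies - energy) < ENERGY_ID_TOL)
  for (i in cand) {
    rec <- db$ts[[i]]
    if (is.null(surface) || is.null(rec$coords)) return(rec$id)
    if (config_distance(surface, rec$coords, x) < RMSD_ID_TOL) return(rec$id)
  }
  NA_integer_
}

# ------------------------------------------------------------------ insertion

#' Insert a converged minimum into the database
#'
#' Applies the identity rule (energies within 1e-6 and superposition RMSD
#' below 1e-3 identify the same minimum); normal-mode frequencies are
#' computed and stored on first insertion.
#'
#' @param db A `ktn` (modified in place and returned).
#' @param candidate A converged `minimize_result` (from [local_minimize()]).
#' @param surface The surface the candidate lives on.
#' @param order_parameters Optional named list cached on the record.
#' @return List with `db`, `id`, `is_new`.
#' @export
add_minimum <- function(db, candidate, surface, order_parameters = NULL) {
  if (!isTRUE(candidate$converged)) stop("candidate minimum is not converged")
  x <- candidate$x_min
  match_id <- find_matching_minimum(db, surface, x, candidate$energy)
  if (!is.na(match_id))
    return(list(db = db, id = match_id, is_new = FALSE))
  ev <- normal_mode_eigen(surface, x)
  if (hessian_index(ev$values) > 0)
    stop("candidate has negative Hessian eigenvalues; not a minimum")
  id <- db$next_min_id
  db$next_min_id <- id + 1L
  rec <- list(id = id, energy = candidate$energy, coords = x,
              log_product_frequencies = log_product_frequencies(ev$values),
              order_parameters = order_parameters %||% list())
  db$minima[[as.character(id)]] <- rec
  db$min_energies <- c(db$min_energies, setNames(candidate$energy, id))
  list(db = db, id = id, is_new = TRUE)
}

#' Insert a converged transition state into the database
#'
#' @param db A `ktn`.
#' @param ts A converged `transition_state_result`
#'   (from [refine_transition_state()]).
#' @param triple A `min_ts_min_triple` (from [descend_to_minima()]) whose
#'   endpoint minima are already in the database.
#' @param surface The surface.
#' @return List with `db`, `id`, `is_new`.
#' @export
add_transition_state <- function(db, ts, triple, surface) {
  if (!isTRUE(ts$converged)) stop("transition state is not converged")
  ida <- find_matching_minimum(db, surface, triple$minus_minimum$x_min,
                               triple$minus_minimum$energy)
  idb <- find_matching_minimum(db, surface, triple$plus_minimum$x_min,
                               triple$plus_minimum$energy)
  if (is.na(ida) || is.na(idb))
    stop("triple endpoints must be inserted before the transition state")
  match_id <- find_matching_ts(db, surface, ts$x_ts, ts$energy)
  if (!is.na(match_id))
    return(list(db = db, id = match_id, is_new = FALSE))
  ev <- normal_mode_eigen(surface, ts$x_ts)
  if (hessian_index(ev$values) != 1)
    stop("stored TS must have exactly one negative non-zero eigenvalue")
  id <- db$next_ts_id
  db$next_ts_id <- id + 1L
  rec <- list(id = id, energy = ts$energy, coords = ts$x_ts,
              log_product_frequencies =
                log_product_frequencies(ev$values),
              min_minus = ida, min_plus = idb,
              degenerate = ida == idb)
  db$ts[[as.character(id)]] <- rec
  db$ts_energies <- c(db$ts_energies, setNames(ts$energy, id))
  list(db = db, id = id, is_new = TRUE)
}

# low-level record insertion (synthetic networks, hand-built examples)

#' Insert raw records (synthetic or hand-built networks)
#'
#' Low-level constructors that bypass geometry: used by the synthetic KTN
#' generator and by hand-built examples where energies and frequency products
#' are prescribed rather than computed from a surface.
#'
#' @param db A `ktn`.
#' @param energy Stationary-point energy.
#' @param log_product_frequencies Sum of ln of positive normal-mode
#'   frequencies.
#' @param coords Optional coordinates.
#' @param order_parameters Optional named list.
#' @param m1,m2 Minima ids a TS connects.
#' @return The new record id.
#' @export
ktn_put_minimum <- function(db, energy, log_product_frequencies = 0,
                            coords = NULL, order_parameters = NULL) {
  id <- db$next_min_id
  db$next_min_id <- id + 1L
  db$minima[[as.character(id)]] <-
    list(id = id, energy = energy, coords = coords,
         log_product_frequencies = log_product_frequencies,
         order_parameters = order_parameters %||% list())
  db$min_energies <- c(db$min_energies, setNames(energy, id))
  id
}

#' @rdname ktn_put_minimum
#' @export
ktn_put_ts <- function(db, energy, m1, m2, log_product_frequencies = 0,
                       coords = NULL) {
  if (is.null(db$minima[[as.character(m1)]]) ||
      is.null(db$minima[[as.character(m2)]]))
    stop("TS endpoints must exist")
  id <- db$next_ts_id
  db$next_ts_id <- id + 1L
  db$ts[[as.character(id)]] <-
    list(id = id, energy = energy, coords = coords,
         log_product_frequencies = log_product_frequencies,
         min_minus = m1, min_plus = m2, degenerate = m1 == m2)
  db$ts_energies <- c(db$ts_energies, setNames(energy, id))
  id
}

# ---------------------------------------------------------------- components

# igraph over the minima; multi-edges collapse for connectivity purposes
ktn_graph <- function(db, ts_energy_below = Inf) {
  ids <- ktn_min_ids(db)
  ed <- ktn_edges(db)
  ed <- ed[ed$energy < ts_energy_below & ed$m1 != ed$m2, , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  igraph::V(g)$name <- as.character(ids)
  if (nrow(ed))
    g <- igraph::add_edges(g, rbind(as.character(ed$m1), as.character(ed$m2)))
  g
}

#' Are two minima connected in the network?
#' @param db A `ktn`.
#' @param a,b Minima ids.
#' @return Logical.
#' @export
ktn_connected <- function(db, a, b) {
  g <- ktn_graph(db)
  comp <- igraph::components(g)$membership
  comp[as.character(a)] == comp[as.character(b)]
}

# ------------------------------------------------------------------- export

#' Export the network as a GraphML or TSV edge list
#'
#' @param db A `ktn`.
#' @param path Output file.
#' @param format `"graphml"` or `"tsv"`.
#' @export
ktn_export <- function(db, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  ed <- ktn_edges(db)
  if (format == "tsv") {
    utils::write.table(ed, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    g <- ktn_graph(db)
    igraph::V(g)$energy <- unname(db$min_energies[igraph::V(g)$name])
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
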