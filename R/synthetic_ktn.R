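# Generator for synthetic multifunnel kinetic transition networks with a
# known exact master-equation generator: every downstream stage (fastest
# paths, regrouping, graph transformation, disconnectivity) is testable
# against ground truth.

#' Specify a synthetic multifunnel network
#'
#' @param n_funnels Number of funnels.
#' @param minima_per_funnel Minima per funnel (single count, or one
#'   per funnel: a small count against a deep competitor makes a narrow,
#'   weakly populated funnel).
#' @param intra_funnel_barrier Barrier height (energy above the higher of the
#'   two minima) for transition states inside a funnel.
#' @param inter_funnel_barrier Barrier height for the single transition state
#'   joining adjacent funnel bottoms; must exceed the intra-funnel barrier.
#' @param funnel_bottom_energies Energies of the funnel-bottom minima
#'   (length `n_funnels`; default `0, 1, 2, ...`).
#' @param energy_spread Energy gap between successive minima climbing away
#'   from a funnel bottom.
#' @param logprod_spread Half-width of the uniform jitter on the per-minimum
#'   log frequency products (entropic diversity).
#' @param seed Integer seed; the draw is bitwise reproducible.
#' @return A `synthetic_ktn_spec` list.
#' @export
synthetic_ktn_spec <- function(n_funnels = 3L, minima_per_funnel = 5L,
                               intra_funnel_barrier = 1.0,
                               inter_funnel_barrier = 5.0,
                               funnel_bottom_energies = NULL,
                               energy_spread = 0.5,
                               logprod_spread = 0.2,
                               seed = 1L) {
  if (inter_funnel_barrier <= intra_funnel_barrier || intra_funnel_barrier <= 0)
    stop("need inter_funnel_barrier > intra_funnel_barrier > 0")
  if (n_funnels < 1 || any(minima_per_funnel < 1))
    stop("counts must be positive")
  minima_per_funnel <- rep_len(as.integer(minima_per_funnel), n_funnels)
  fb <- funnel_bottom_energies %||% (seq_len(n_funnels) - 1)
  if (length(fb) != n_funnels)
    stop("funnel_bottom_energies must have n_funnels entries")
  spec <- list(n_funnels = as.integer(n_funnels),
               minima_per_funnel = minima_per_funnel,
               intra_funnel_barrier = intra_funnel_barrier,
               inter_funnel_barrier = inter_funnel_barrier,
               funnel_bottom_energies = fb,
               energy_spread = energy_spread,
               logprod_spread = logprod_spread,
               seed = as.integer(seed))
  class(spec) <- "synthetic_ktn_spec"
  spec
}

#' Generate a synthetic KTN with its exact rate generator
#'
#' Each funnel is a chain of minima climbing away from its bottom, joined by
#' intra-funnel transition states; adjacent funnel bottoms are joined by one
#' high inter-funnel transition state. Per-minimum frequency products get a
#' seeded jitter. The returned generator matrix holds the exact harmonic
#' TST master-equation rates implied by the network at temperature `T`.
#'
#' @param spec A [synthetic_ktn_spec()].
#' @param T Temperature at which the exact generator is evaluated.
#' @param kB Boltzmann constant.
#' @return List with `db` (a `ktn`; `db$funnel` maps minima ids to funnels),
#'   `K` (generator matrix, `K[v,u]` = rate u -> v), `spec`.
#' @export
generate_synthetic_ktn <- function(spec, T = 1, kB = 1) {
  set.seed(spec$seed)
  db <- ktn_new(surface_name = "synthetic")
  db$n_modes <- 1
  funnel_of <- integer(0)
  bottoms <- integer(spec$n_funnels)
  for (f in seq_len(spec$n_funnels)) {
    prev <- NA_integer_
    for (j in seq_len(spec$minima_per_funnel[f])) {
      e <- spec$funnel_bottom_energies[f] + (j - 1) * spec$energy_spread +
        if (j > 1) runif(1, 0, 0.1 * spec$energy_spread) else 0
      lp <- runif(1, -spec$logprod_spread, spec$logprod_spread)
      id <- ktn_put_minimum(db, e, log_product_frequencies = lp)
      funnel_of[id] <- f
      if (j == 1) bottoms[f] <- id
      if (!is.na(prev)) {
        e_ts <- max(e, ktn_minimum(db, prev)$energy) + spec$intra_funnel_barrier
        ktn_put_ts(db, e_ts, prev, id,
                   log_product_frequencies =
                     runif(1, -spec$logprod_spread, spec$logprod_spread))
      }
      prev <- id
    }
  }
  if (spec$n_funnels > 1) for (f in seq_len(spec$n_funnels - 1)) {
    ea <- ktn_minimum(db, bottoms[f])$energy
    eb <- ktn_minimum(db, bottoms[f + 1])$energy
    ktn_put_ts(db, max(ea, eb) + spec$inter_funnel_barrier,
               bottoms[f], bottoms[f + 1],
               log_product_frequencies =
                 runif(1, -spec$logprod_spread, spec$logprod_spread))
  }
  db$funnel <- funnel_of
  db$bottoms <- bottoms
  rm <- ktn_rate_matrix(db, T, kB)
  K <- rm$K
  diag(K) <- -colSums(K)
  list(db = db, K = K, spec = spec)
}
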