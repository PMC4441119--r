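#' @useDynLib ktnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim rnorm runif setNames var
#' @importFrom utils head tail
NULL

FAMILY_ID <- c(double_well_1d = 1L, muller_brown = 2L, lj_cluster = 3L,
               bead_peptide = 4L)

ALL_TERMS <- c("bonded", "angular", "torsional", "van_der_waals",
               "electrostatic", "analytic")

#' Build a potential-energy surface
#'
#' Constructs one of the built-in surface families with a consistent
#' energy / gradient / Hessian interface and per-term energy decomposition.
#'
#' Families:
#' \describe{
#'   \item{`double_well_1d`}{\eqn{V(x) = x^4 - x^2}; reduced units.}
#'   \item{`muller_brown`}{The standard four-Gaussian 2-D surface with its
#'     three minima and two index-1 saddles; reduced units.}
#'   \item{`lj_cluster`}{Pairwise Lennard-Jones
#'     \eqn{4\epsilon[(\sigma/r)^{12}-(\sigma/r)^6]} in reduced units;
#'     `params` needs `n_atoms` (and optionally `eps`, `sigma`).}
#'   \item{`bead_peptide`}{A coarse-grained charged bead chain (one bead per
#'     residue, types `H` hydrophobic / `P` polar / `+` / `-`) with bond
#'     springs, angle bending, helically biased torsions, Lennard-Jones
#'     non-bonded terms and Debye-screened Coulomb electrostatics; units
#'     kcal/mol and Angstrom. See [bead_peptide_spec()].}
#' }
#'
#' @param name Family name, one of `"double_well_1d"`, `"muller_brown"`,
#'   `"lj_cluster"`, `"bead_peptide"`.
#' @param params Named list of family parameters (see Details); for
#'   `bead_peptide` either a parameter list or a [bead_peptide_spec()].
#' @return A `potential_surface` object: list with `name`, `n_dof`,
#'   `energy_terms`, `n_zero_modes`, `units`, plus closures `energy(x)`,
#'   `gradient(x)`, `terms(x)`.
#' @examples
#' s <- build_surface("muller_brown")
#' s$energy(c(-0.558, 1.442))
#' @export
build_surface <- function(name, params = list()) {
  if (!name %in% names(FAMILY_ID))
    stop("unknown surface family: ", name)
  switch(name,
    double_well_1d = new_family_surface(name, 1L, "analytic", 0L, "reduced",
                                        list(), chain = FALSE, dim = 1L),
    muller_brown = new_family_surface(name, 2L, "analytic", 0L, "reduced",
                                      list(), chain = FALSE, dim = 2L),
    lj_cluster = {
      n <- params$n_atoms
      if (is.null(n) || n < 2) stop("lj_cluster needs params$n_atoms >= 2")
      p <- list(n_atoms = as.integer(n),
                eps = params$eps %||% 1.0, sigma = params$sigma %||% 1.0)
      if (p$eps <= 0 || p$sigma <= 0) stop("eps and sigma must be positive")
      new_family_surface(name, 3L * p$n_atoms, "van_der_waals", 6L, "reduced",
                         p, chain = FALSE, dim = 3L, scale = p$sigma)
    },
    bead_peptide = {
      spec <- if (inherits(params, "bead_peptide_spec")) params
              else do.call(bead_peptide_spec, params)
      p <- bead_peptide_cpp_params(spec)
      s <- new_family_surface(name, 3L * spec$n_beads,
                              c("bonded", "angular", "torsional",
                                "van_der_waals", "electrostatic"),
                              6L, "kcal/mol,A,K", p, chain = TRUE, dim = 3L,
                              scale = spec$r0)
      s$spec <- spec
      s
    })
}

new_family_surface <- function(name, n_dof, terms, n_zero_modes, units,
                               params, chain, dim, scale = 1.0) {
  fam <- FAMILY_ID[[name]]
  s <- list(
    name = name, n_dof = n_dof, energy_terms = terms,
    n_zero_modes = n_zero_modes, units = units,
    family = fam, params = params, chain = chain, dim = dim, scale = scale,
    energy = function(x) cpp_energy(fam, params, as.numeric(x)),
    gradient = function(x) as.numeric(cpp_gradient(fam, params, as.numeric(x))),
    terms = function(x) cpp_energy_terms(fam, params, as.numeric(x)))
  class(s) <- "potential_surface"
  s
}

#' Construct a surface from R closures
#'
#' Generic constructor for custom (test or research) surfaces given plain R
#' energy/gradient functions. Used internally for oracles; the built-in
#' families come from [build_surface()].
#'
#' @param name Label.
#' @param n_dof Number of coordinates.
#' @param energy,gradient Functions of a numeric vector.
#' @param terms Optional function returning the named per-term decomposition;
#'   defaults to putting everything in `analytic`.
#' @param n_zero_modes Zero Hessian eigenvalues at stationary points.
#' @param units Unit system label.
#' @param dim Spatial dimension per particle (1, 2 or 3).
#' @param chain Whether the coordinates form a chain of beads.
#' @param scale Geometric scale (sets default move/displacement sizes).
#' @return A `potential_surface`.
#' @export
potential_surface <- function(name, n_dof, energy, gradient, terms = NULL,
                              n_zero_modes = 0L, units = "reduced",
                              dim = 1L, chain = FALSE, scale = 1.0) {
  if (is.null(terms)) {
    terms <- function(x) setNames(c(0, 0, 0, 0, 0, energy(x)), ALL_TERMS)
  }
  s <- list(name = name, n_dof = as.integer(n_dof),
            energy_terms = "analytic", n_zero_modes = as.integer(n_zero_modes),
            units = units, family = NA_integer_, params = NULL,
            chain = chain, dim = as.integer(dim), scale = scale,
            energy = energy, gradient = gradient, terms = terms)
  class(s) <- "potential_surface"
  s
}

#' @export
print.potential_surface <- function(x, ...) {
  cat("<potential_surface>", x$name, "\n",
      " n_dof:", x$n_dof, " zero modes:", x$n_zero_modes,
      " units:", x$units, "\n",
      " terms:", paste(x$energy_terms, collapse = ", "), "\n")
  invisible(x)
}

#' Per-term energy decomposition
#'
#' Splits the total potential energy at a configuration into its contributing
#' terms (bonded, angular, torsional, van der Waals, electrostatic, analytic).
#' Terms absent from the surface are reported as exactly 0; the terms always
#' sum to the total energy.
#'
#' @param surface A `potential_surface`.
#' @param x Configuration vector of length `surface$n_dof`.
#' @return Named numeric vector over all term labels.
#' @export
decompose_energy <- function(surface, x) {
  if (length(x) != surface$n_dof)
    stop("configuration has ", length(x), " coordinates; surface needs ",
         surface$n_dof)
  tv <- surface$terms(as.numeric(x))
  out <- setNames(numeric(length(ALL_TERMS)), ALL_TERMS)
  out[names(tv)] <- tv
  out
}

#' Finite-difference Hessian of a surface
#'
#' Central differences of the analytic gradient (step `h`), symmetrised so the
#' matrix is exactly equal to its transpose.
#'
#' @param surface A `potential_surface`.
#' @param x Configuration.
#' @param h Step size (same units as the coordinates).
#' @return `n_dof` x `n_dof` symmetric matrix.
#' @export
surface_hessian <- function(surface, x, h = 1e-4) {
  n <- surface$n_dof
  x <- as.numeric(x)
  H <- matrix(0, n, n)
  for (k in seq_len(n)) {
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    H[, k] <- (surface$gradient(xp) - surface$gradient(xm)) / (2 * h)
  }
  (H + t(H)) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
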