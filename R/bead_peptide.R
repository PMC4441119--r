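#' Coarse-grained charged bead-peptide specification
#'
#' One bead per residue over the alphabet `H` (hydrophobic), `P` (polar),
#' `+`, `-` (unit charges). The chain carries bond springs, angle bending, a
#' helically biased torsion at every backbone dihedral, Lennard-Jones
#' non-bonded interactions (deeper for H-H pairs) and Debye-screened Coulomb
#' electrostatics. The default 13-bead sequence mixes hydrophobic and charged
#' beads so that a biased helix competes with electrostatically collapsed
#' globules: a multifunnel landscape in miniature.
#'
#' Units: kcal/mol, Angstrom, Kelvin (Boltzmann constant
#' 0.0019872041 kcal/mol/K).
#'
#' @param sequence Bead string over `{H, P, +, -}`; default
#'   `"H+HH-HH+H-HPH"`.
#' @param k_bond Bond spring constant, kcal/mol/A^2.
#' @param r0 Equilibrium bond length, A (Calpha virtual bond 3.8).
#' @param k_angle Angle bending constant, kcal/mol/rad^2.
#' @param theta0 Equilibrium bend angle, degrees.
#' @param k_tor Torsional bias strength, kcal/mol.
#' @param phi0 Helical reference dihedral, degrees.
#' @param eps_hh LJ well depth for hydrophobic pairs, kcal/mol.
#' @param eps_bb LJ well depth for all other pairs, kcal/mol.
#' @param sigma LJ diameter, A.
#' @param debye_length Electrostatic screening length, A.
#' @param dielectric_scale Dimensionless prefactor on the Coulomb term
#'   (1/effective relative permittivity).
#' @return A `bead_peptide_spec` list.
#' @export
bead_peptide_spec <- function(sequence = "H+HH-HH+H-HPH",
                              k_bond = 100, r0 = 3.8,
                              k_angle = 10, theta0 = 95,
                              k_tor = 1.0, phi0 = 50,
                              eps_hh = 1.0, eps_bb = 0.2, sigma = 4.5,
                              debye_length = 10, dielectric_scale = 1.0) {
  beads <- strsplit(sequence, "")[[1]]
  if (length(beads) < 4) stop("bead peptide needs at least 4 beads")
  bad <- setdiff(beads, c("H", "P", "+", "-"))
  if (length(bad)) stop("invalid bead types: ", paste(bad, collapse = ", "))
  for (v in c(k_bond, r0, k_angle, theta0, k_tor, eps_hh, eps_bb, sigma,
              debye_length, dielectric_scale))
    if (!is.finite(v) || v <= 0) stop("interaction parameters must be positive")
  spec <- list(sequence = sequence, beads = beads, n_beads = length(beads),
               charges = ifelse(beads == "+", 1, ifelse(beads == "-", -1, 0)),
               hydrophobic = as.integer(beads == "H"),
               k_bond = k_bond, r0 = r0, k_angle = k_angle, theta0 = theta0,
               k_tor = k_tor, phi0 = phi0, eps_hh = eps_hh, eps_bb = eps_bb,
               sigma = sigma, debye_length = debye_length,
               dielectric_scale = dielectric_scale)
  class(spec) <- "bead_peptide_spec"
  spec
}

# Boltzmann constant, kcal/mol/K
KB_KCAL <- 0.0019872041
# Coulomb constant, kcal A / mol / e^2
COULOMB_KCAL <- 332.0637

bead_peptide_cpp_params <- function(spec) {
  list(charges = as.numeric(spec$charges),
       hydrophobic = as.integer(spec$hydrophobic),
       k_bond = spec$k_bond, r0 = spec$r0,
       k_angle = spec$k_angle, theta0 = spec$theta0 * pi / 180,
       k_tor = spec$k_tor, phi0 = spec$phi0 * pi / 180,
       eps_hh = spec$eps_hh, eps_bb = spec$eps_bb, sigma = spec$sigma,
       coulomb = COULOMB_KCAL * spec$dielectric_scale,
       debye = spec$debye_length)
}

#' Ideal-geometry chain configurations
#'
#' Builds a bead chain with the given bond length, bend angle and a constant
#' backbone dihedral; with the spec's `theta0`/`phi0` defaults this is the
#' ideal biased helix used as the folded reference state.
#'
#' @param spec A [bead_peptide_spec()].
#' @param phi Constant dihedral in degrees (default: the spec's helical
#'   reference `phi0`).
#' @return Numeric vector of 3 x n_beads coordinates.
#' @export
helix_configuration <- function(spec, phi = spec$phi0) {
  chain_configuration(spec$n_beads, spec$r0, spec$theta0, phi)
}

# place beads sequentially with fixed internal coordinates (NeRF construction)
chain_configuration <- function(n, r0, theta_deg, phi_deg) {
  th <- theta_deg * pi / 180
  ph <- phi_deg * pi / 180
  X <- matrix(0, n, 3)
  X[1, ] <- c(0, 0, 0)
  X[2, ] <- c(r0, 0, 0)
  if (n >= 3)
    X[3, ] <- X[2, ] + r0 * c(-cos(th), sin(th), 0)
  if (n >= 4) for (i in 4:n) {
    a <- X[i - 3, ]; b <- X[i - 2, ]; cc <- X[i - 1, ]
    bc <- cc - b; bc <- bc / sqrt(sum(bc^2))
    ab <- b - a
    nrm <- pracma_cross(ab, bc); nrm <- nrm / sqrt(sum(nrm^2))
    m <- pracma_cross(nrm, bc)
    d2 <- c(-r0 * cos(th), r0 * sin(th) * cos(ph), r0 * sin(th) * sin(ph))
    X[i, ] <- cc + d2[1] * bc + d2[2] * m + d2[3] * nrm
  }
  as.numeric(t(X))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Backbone dihedral angles of a chain configuration
#'
#' @param x Flat coordinate vector (3 per bead).
#' @return Vector of `n_beads - 3` dihedrals in degrees, in (-180, 180].
#' @export
chain_dihedrals <- function(x) {
  X <- coords_matrix(x)
  n <- nrow(X)
  if (n < 4) stop("chain too short for dihedrals")
  out <- numeric(n - 3)
  for (i in seq_len(n - 3)) {
    b1 <- X[i + 1, ] - X[i, ]
    b2 <- X[i + 2, ] - X[i + 1, ]
    b3 <- X[i + 3, ] - X[i + 2, ]
    n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
    out[i] <- atan2(sum(pracma_cross(n1, n2) * b2) / sqrt(sum(b2^2)),
                    sum(n1 * n2)) * 180 / pi
  }
  out
}

coords_matrix <- function(x, dim = 3L) {
  matrix(as.numeric(x), ncol = dim, byrow = TRUE)
}
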