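# Conformational order parameters, ensemble analyses and sequence charge
# patterning.

#' Helicity fraction of a bead chain
#'
#' Fraction of backbone dihedrals within `window` of the helical reference
#' dihedral: the bead-model proxy for per-residue secondary structure
#' assignment.
#'
#' @param conf Flat coordinate vector (3 per bead) of a chain of >= 4 beads.
#' @param reference_dihedral Helical reference, degrees.
#' @param window Acceptance half-width, degrees.
#' @return Fraction in `[0, 1]`.
#' @export
helicity_fraction <- function(conf, reference_dihedral = 50, window = 30) {
  phi <- chain_dihedrals(conf)
  dev <- abs(((phi - reference_dihedral + 180) %% 360) - 180)
  mean(dev <= window)
}

#' Radius of gyration
#' @param conf Flat coordinates (3 per bead), unit masses.
#' @return Root-mean-square distance to the centroid.
#' @export
radius_of_gyration <- function(conf) {
  X <- coords_matrix(conf)
  Xc <- sweep(X, 2, colMeans(X))
  sqrt(mean(rowSums(Xc^2)))
}

#' End-to-end (or any inter-bead) distance
#' @param conf Flat coordinates.
#' @param i,j Bead indices (1-based; default first and last).
#' @return Euclidean distance.
#' @export
end_to_end_distance <- function(conf, i = 1L, j = NULL) {
  X <- coords_matrix(conf)
  j <- j %||% nrow(X)
  sqrt(sum((X[i, ] - X[j, ])^2))
}

#' Ensemble contact-frequency map
#'
#' Symmetric matrix of the fraction of conformations in which beads `i` and
#' `j` lie within `cutoff`; near-diagonal pairs (`|i-j| <= 2`) are excluded.
#'
#' @param ensemble List of flat coordinate vectors.
#' @param cutoff Contact distance.
#' @return n x n matrix with entries in `[0, 1]`.
#' @export
contact_map <- function(ensemble, cutoff) {
  if (!length(ensemble)) stop("empty ensemble")
  if (cutoff <= 0) stop("cutoff must be positive")
  n <- length(ensemble[[1]]) / 3
  M <- matrix(0, n, n)
  for (conf in ensemble) {
    X <- coords_matrix(conf)
    D <- as.matrix(stats::dist(X))
    M <- M + (D <= cutoff)
  }
  M <- M / length(ensemble)
  band <- abs(row(M) - col(M)) <= 2
  M[band] <- 0
  M
}

#' Hydrogen-bond-like contacts
#'
#' Reports donor-hydrogen-acceptor triples satisfying
#' `distance(H, A) <= d_cut` and a deviation from linearity of the D-H-A
#' angle of at most `angle_dev_cut` (defaults 3 A and 40 degrees).
#'
#' @param conf Flat coordinates.
#' @param triples data.frame/matrix with columns `donor`, `hydrogen`,
#'   `acceptor` (bead indices) to test.
#' @param d_cut Distance cutoff.
#' @param angle_dev_cut Maximum deviation from 180 degrees.
#' @return The subset of `triples` forming bonds, with `distance` and
#'   `angle_deviation` columns.
#' @export
hbond_like_contacts <- function(conf, triples, d_cut = 3, angle_dev_cut = 40) {
  X <- coords_matrix(conf)
  triples <- as.data.frame(triples)
  res <- triples
  res$distance <- NA_real_
  res$angle_deviation <- NA_real_
  keep <- logical(nrow(triples))
  for (r in seq_len(nrow(triples))) {
    D <- X[triples$donor[r], ]; H <- X[triples$hydrogen[r], ]
    A <- X[triples$acceptor[r], ]
    d <- sqrt(sum((H - A)^2))
    v1 <- D - H; v2 <- A - H
    ang <- acos(max(-1, min(1, sum(v1 * v2) /
                              sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    res$distance[r] <- d
    res$angle_deviation[r] <- abs(180 - ang)
    keep[r] <- d <= d_cut && abs(180 - ang) <= angle_dev_cut
  }
  res[keep, , drop = FALSE]
}

# RMS circular distance between two dihedral vectors (degrees)
dihedral_distance <- function(a, b) {
  d <- ((a - b + 180) %% 360) - 180
  sqrt(mean(d^2))
}

#' Leader clustering on backbone dihedral angles
#'
#' Deterministic first-fit leader clustering under the RMS minimum-image
#' dihedral distance: each conformation joins the first cluster whose leader
#' is within `angle_cutoff`, else founds a new cluster. Clusters are returned
#' ordered by population.
#'
#' @param ensemble List of flat coordinate vectors (chains).
#' @param angle_cutoff Cluster radius in degrees (the field's trajectory
#'   clustering commonly uses 40).
#' @return List of clusters: each with `leader` (index into the ensemble),
#'   `members`, `population`.
#' @export
cluster_dihedrals <- function(ensemble, angle_cutoff = 40) {
  if (!length(ensemble)) stop("empty ensemble")
  if (angle_cutoff <= 0 || angle_cutoff >= 180)
    stop("angle_cutoff must be in (0, 180)")
  dihs <- lapply(ensemble, chain_dihedrals)
  leaders <- integer(0)
  members <- list()
  for (i in seq_along(dihs)) {
    placed <- FALSE
    for (c in seq_along(leaders)) {
      if (dihedral_distance(dihs[[i]], dihs[[leaders[c]]]) <= angle_cutoff) {
        members[[c]] <- c(members[[c]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      leaders <- c(leaders, i)
      members[[length(leaders)]] <- i
    }
  }
  ord <- order(-vapply(members, length, integer(1)), leaders)
  lapply(ord, function(c)
    list(leader = leaders[c], members = members[[c]],
         population = length(members[[c]]) / length(ensemble)))
}

#' 2-D free-energy surface over two order parameters
#'
#' `F(bin) = -kB T ln(p_bin / max p_bin)`, so the most occupied bin sits at
#' zero; empty bins are `NA` (flagged, not zero).
#'
#' @param x,y Order-parameter samples (e.g. helicity fraction and radius of
#'   gyration).
#' @param weights Sample weights (normalised internally; uniform rescaling
#'   leaves the surface unchanged).
#' @param T Temperature.
#' @param kB Boltzmann constant.
#' @param bins Bin count per axis (single number or length-2).
#' @param x_range,y_range Optional axis ranges.
#' @return List with `F` (matrix, x-bins by y-bins), `x_mid`, `y_mid`,
#'   `degenerate` flag (all samples in one bin).
#' @export
fes_2d <- function(x, y, weights = NULL, T = 1, kB = 1, bins = 30,
                   x_range = range(x), y_range = range(y)) {
  w <- weights %||% rep(1, length(x))
  if (any(w < 0) || sum(w) <= 0) stop("weights must be normalisable")
  w <- w / sum(w)
  bins <- rep_len(bins, 2)
  bx <- seq(x_range[1], x_range[2], length.out = bins[1] + 1)
  by <- seq(y_range[1], y_range[2], length.out = bins[2] + 1)
  ix <- pmin(pmax(findInterval(x, bx, all.inside = TRUE), 1), bins[1])
  iy <- pmin(pmax(findInterval(y, by, all.inside = TRUE), 1), bins[2])
  P <- matrix(0, bins[1], bins[2])
  for (k in seq_along(x)) P[ix[k], iy[k]] <- P[ix[k], iy[k]] + w[k]
  FF <- matrix(NA_real_, bins[1], bins[2])
  occ <- P > 0
  FF[occ] <- -kB * T * log(P[occ] / max(P))
  list(F = FF, x_mid = (bx[-1] + bx[-length(bx)]) / 2,
       y_mid = (by[-1] + by[-length(by)]) / 2,
       degenerate = sum(occ) == 1)
}

#' Per-term energy profile along a discrete path
#'
#' Ordered total and per-term energies for every stationary point
#' (minimum / transition state / minimum / ...) of a discrete path; the route
#' to the downhill-relaxation decomposition plots of folding/unfolding paths.
#'
#' @param path A `discrete_path` (see [fastest_path()]).
#' @param db The `ktn` holding the path's stationary points (with
#'   coordinates).
#' @param surface The `potential_surface`.
#' @return data.frame: `kind` (`min`/`ts`), `id`, `total`, one column per
#'   energy term.
#' @export
path_energy_profile <- function(path, db, surface) {
  seq_kind <- character(0); seq_id <- integer(0); coords <- list()
  for (k in seq_along(path$min_ids)) {
    seq_kind <- c(seq_kind, "min"); seq_id <- c(seq_id, path$min_ids[k])
    coords[[length(coords) + 1]] <- ktn_minimum(db, path$min_ids[k])$coords
    if (k <= length(path$ts_ids)) {
      seq_kind <- c(seq_kind, "ts"); seq_id <- c(seq_id, path$ts_ids[k])
      coords[[length(coords) + 1]] <- ktn_ts(db, path$ts_ids[k])$coords
    }
  }
  rows <- lapply(seq_along(coords), function(i) {
    if (is.null(coords[[i]])) stop("stationary point ", seq_id[i],
                                   " carries no coordinates")
    tv <- decompose_energy(surface, coords[[i]])
    cbind(data.frame(kind = seq_kind[i], id = seq_id[i],
                     total = sum(tv)), as.data.frame(as.list(tv)))
  })
  do.call(rbind, rows)
}

# ------------------------------------------------------------------ kappa

AA_CHARGE <- c(K = 1, R = 1, D = -1, E = -1)

aa_charges <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  valid <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bad <- setdiff(aa, valid)
  if (length(bad)) stop("not an amino-acid sequence: ", paste(bad, collapse = ""))
  unname(ifelse(aa %in% names(AA_CHARGE), AA_CHARGE[aa], 0))
}

sigma_of <- function(q) {
  fp <- mean(q > 0); fm <- mean(q < 0)
  if (fp + fm == 0) return(0)
  (fp - fm)^2 / (fp + fm)
}

delta_of <- function(q, g) {
  s_all <- sigma_of(q)
  n <- length(q)
  mean(vapply(seq_len(n - g + 1), function(i)
    (sigma_of(q[i:(i + g - 1)]) - s_all)^2, numeric(1)))
}

#' Sequence charge-patterning parameter kappa
#'
#' Das-Pappu charge patterning for an amino-acid sequence: per blob size `g`,
#' `delta_g` is the mean squared deviation of the windowed charge asymmetry
#' `sigma = (f+ - f-)^2/(f+ + f-)` from the whole-sequence value; kappa is
#' `mean(delta_g)` normalised by the same quantity for the maximally
#' segregated permutation of the identical composition (all negatives, then
#' neutrals, then positives). Kappa near 0 means well-mixed charges, 1 means
#' fully segregated blocks. Histidine and the termini are treated as
#' uncharged; K/R count +1 and D/E -1.
#'
#' @param sequence One-letter amino-acid string (length >= max blob size).
#' @param blob_sizes Window sizes (default 5 and 6).
#' @return A `sequence_charge_profile`: `sequence`, `charges`, `FCR`, `NCPR`,
#'   `kappa`, `delta` (per blob size), `delta_max`.
#' @export
charge_patterning <- function(sequence, blob_sizes = c(5L, 6L)) {
  q <- aa_charges(sequence)
  if (length(q) < max(blob_sizes))
    stop("sequence shorter than the largest blob size")
  if (!any(q != 0))
    stop("kappa undefined: sequence has no charged residues")
  fp <- mean(q > 0); fm <- mean(q < 0)
  qmax <- c(rep(-1, sum(q < 0)), rep(0, sum(q == 0)), rep(1, sum(q > 0)))
  d <- vapply(blob_sizes, function(g) delta_of(q, g), numeric(1))
  dmax <- vapply(blob_sizes, function(g) delta_of(qmax, g), numeric(1))
  out <- list(sequence = toupper(sequence), charges = q,
              FCR = fp + fm, NCPR = fp - fm,
              kappa = mean(d) / mean(dmax),
              delta = setNames(d, blob_sizes),
              delta_max = setNames(dmax, blob_sizes))
  class(out) <- "sequence_charge_profile"
  out
}

#' @export
print.sequence_charge_profile <- function(x, ...) {
  cat("<sequence_charge_profile>", nchar(x$sequence), "aa  FCR =",
      format(x$FCR, digits = 3), " NCPR =", format(x$NCPR, digits = 3),
      " kappa =", format(x$kappa, digits = 4), "\n")
  invisible(x)
}

#' Read the first sequence from a FASTA file
#' @param path FASTA file.
#' @return Character string (uppercase, gaps stripped).
#' @export
read_fasta_sequence <- function(path) {
  lines <- readLines(path)
  seq_lines <- lines[!startsWith(lines, ">")]
  gsub("[^A-Za-z]", "", toupper(paste(seq_lines, collapse = "")))
}
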