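# Rigid-body superposition and structural distances.

#' Optimal-superposition RMSD (Kabsch)
#'
#' Least-squares RMSD between two equal-length conformations after centroid
#' removal and optimal proper rotation (no permutations, no reflections).
#'
#' @param a,b Flat coordinate vectors or n x dim matrices.
#' @param dim Spatial dimension if flat vectors are given.
#' @return List with `rmsd` and the `rotation` matrix (b onto a).
#' @export
rmsd_superpose <- function(a, b, dim = 3L) {
  A <- if (is.matrix(a)) a else coords_matrix(a, dim)
  B <- if (is.matrix(b)) b else coords_matrix(b, dim)
  if (!all(dim(A) == dim(B))) stop("conformations differ in size")
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(rep(1, ncol(A) - 1), d))
  R <- sv$v %*% D %*% t(sv$u)
  Brot <- B %*% t(R)
  list(rmsd = sqrt(mean(rowSums((A - Brot)^2))), rotation = R)
}

# identity-rule distance between two configurations of a surface:
# superposition RMSD for 3-D systems (rigid-body degeneracy), plain
# per-particle RMSD otherwise.
config_distance <- function(surface, xa, xb) {
  if (surface$dim == 3L && surface$n_zero_modes >= 6L) {
    rmsd_superpose(xa, xb, dim = 3L)$rmsd
  } else {
    sqrt(mean((as.numeric(xa) - as.numeric(xb))^2))
  }
}
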