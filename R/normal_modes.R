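# Normal-mode analysis at stationary points (unit masses).

# orthonormal basis of rigid-body zero modes (3 translations + 3 rotations)
rigid_body_modes <- function(x) {
  X <- coords_matrix(x)
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  basis <- matrix(0, 3 * n, 6)
  for (k in 1:3) basis[seq(k, 3 * n, by = 3), k] <- 1
  axes <- diag(3)
  for (k in 1:3) {
    v <- t(apply(Xc, 1, function(r) pracma_cross(axes[k, ], r)))
    basis[, 3 + k] <- as.numeric(t(v))
  }
  qr.Q(qr(basis))[, seq_len(qr(basis)$rank), drop = FALSE]
}

#' Normal-mode eigenvalues at a configuration
#'
#' Hessian eigenvalues with the surface's zero modes projected out
#' (translations and rotations for 3-D systems). At a minimum all returned
#' eigenvalues are positive; at an index-1 saddle exactly one is negative.
#'
#' @param surface A `potential_surface`.
#' @param x Configuration (should be a stationary point).
#' @return List with `values` (sorted ascending, zero modes removed) and
#'   `vectors` (matching columns).
#' @export
normal_mode_eigen <- function(surface, x) {
  H <- surface_hessian(surface, x)
  nz <- surface$n_zero_modes
  if (nz > 0 && surface$dim == 3L) {
    Q <- rigid_body_modes(x)
    P <- diag(nrow(H)) - Q %*% t(Q)
    H <- P %*% H %*% P
    H <- (H + t(H)) / 2
  }
  e <- eigen(H, symmetric = TRUE)
  ord <- order(e$values)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  if (nz > 0) {
    drop_idx <- order(abs(vals))[seq_len(nz)]
    keep <- setdiff(seq_along(vals), drop_idx)
    vals <- vals[keep]
    vecs <- vecs[, keep, drop = FALSE]
  }
  list(values = vals, vectors = vecs)
}

# sum of ln(nu) over positive modes; nu = sqrt(lambda)/(2 pi), unit masses.
log_product_frequencies <- function(eigenvalues) {
  pos <- eigenvalues[eigenvalues > 0]
  sum(0.5 * log(pos) - log(2 * pi))
}

# Hessian index (number of negative non-zero eigenvalues), with a relative
# threshold so that numerically tiny negatives do not count.
hessian_index <- function(eigenvalues, tol = 1e-8) {
  scale <- max(abs(eigenvalues), 1e-12)
  sum(eigenvalues < -tol * scale)
}
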