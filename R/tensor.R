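#' Build a diffusion tensor from an eigensystem
#'
#' Constructs the symmetric 3x3 diffusion tensor with the given eigenvalues,
#' the largest aligned with `principal_axis`. The two remaining eigenvectors
#' are completed deterministically: the second is the canonical basis vector
#' least aligned with the axis (ties broken in x, y, z order), orthogonalised
#' against the axis; the third is their cross product. For a z-axis fiber with
#' eigenvalues (l1, l2, l3) this yields Dzz = l1, Dxx = l2, Dyy = l3, which is
#' the convention used by the fiber phantoms.
#'
#' @param eigenvalues Numeric length 3, sorted descending, non-negative,
#'   in mm^2/s.
#' @param principal_axis Unit 3-vector (renormalised if within 1e-6 of unit
#'   norm; a zero vector is an error).
#' @return 3x3 symmetric numeric matrix.
#' @examples
#' tensor_from_eigensystem(c(1.4, 0.5, 0.5) * 1e-3, c(0, 0, 1))
#' @export
tensor_from_eigensystem <- function(eigenvalues, principal_axis) {
  if (length(eigenvalues) != 3 || any(!is.finite(eigenvalues))) {
    stopf("`eigenvalues` must be three finite numbers")
  }
  if (any(eigenvalues < 0)) stopf("eigenvalues must be non-negative")
  if (is.unsorted(rev(eigenvalues))) {
    stopf("`eigenvalues` must be sorted in descending order")
  }
  a <- as.numeric(principal_axis)
  if (length(a) != 3) stopf("`principal_axis` must be a 3-vector")
  nrm <- sqrt(sum(a^2))
  if (nrm < 1e-12) stopf("`principal_axis` must not be the zero vector")
  a <- a / nrm

  # deterministic orthonormal completion
  basis <- diag(3)
  h <- basis[, which.min(abs(a))]
  e2 <- h - sum(h * a) * a
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(
    a[2] * e2[3] - a[3] * e2[2],
    a[3] * e2[1] - a[1] * e2[3],
    a[1] * e2[2] - a[2] * e2[1]
  )
  v <- cbind(a, e2, e3)
  v %*% diag(eigenvalues) %*% t(v)
}

# Diagonal tensor directly from axis-aligned diffusivities (mm^2/s).
# Used by subject phantoms where the drawn components need not be ordered.
diagonal_tensor <- function(dxx, dyy, dzz) {
  if (any(c(dxx, dyy, dzz) < 0)) stopf("diffusivities must be non-negative")
  diag(c(dxx, dyy, dzz))
}
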