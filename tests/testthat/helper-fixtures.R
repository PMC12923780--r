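# Shared fixtures: small schemes and phantoms built in code at test time.

tiny_scheme <- function(n_dirs = 30, b = 800, seed = 0) {
  make_gradient_scheme(n_dirs, b, n_b0 = 1, seed = seed)
}

# Small noiseless phantom on a 12 x 12 x 6 grid with the diabetic-group
# default eigenvalues; fast enough for per-test pipelines.
tiny_phantom <- function(...) {
  build_phantom(phantom_spec(grid_shape = c(12L, 12L, 6L), noise_sigma = 0,
                             ...))
}

# Uniform tensor field: every voxel carries the same 3x3 tensor.
uniform_field <- function(tensor, dims = c(4L, 4L, 2L)) {
  v <- c(tensor[1, 1], tensor[2, 2], tensor[3, 3],
         tensor[1, 2], tensor[1, 3], tensor[2, 3])
  array(rep(v, each = prod(dims)), dim = c(dims, 6L))
}

# Independent normal-equations least squares (the generic oracle route,
# distinct from the package's QR path).
pinv_fit <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# Random rotation matrix from a QR decomposition with positive diagonal.
random_rotation <- function(seed) {
  set.seed(seed)
  qrd <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qrd)
  q %*% diag(sign(diag(qr.R(qrd))))
}
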