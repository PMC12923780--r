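#' Construct a diffusion gradient scheme
#'
#' Builds an acquisition scheme of `n_b0` unweighted (b = 0) volumes followed
#' by `n_directions` diffusion-weighted volumes at a single shell `b_value`,
#' with gradient directions spread approximately uniformly over the sphere by
#' seeded electrostatic repulsion (antipodally symmetric Coulomb energy, so
#' directions and their negatives repel alike, as in standard DTI design
#' optimisation).
#'
#' The default acquisition mirrors a single-shell clinical DTI protocol:
#' 30 directions at b = 800 s/mm^2 plus one b = 0 reference volume.
#'
#' @param n_directions Number of diffusion-weighted directions (>= 6; fewer
#'   leaves the six-component tensor fit under-determined).
#' @param b_value Diffusion weighting in s/mm^2 (> 0).
#' @param n_b0 Number of b = 0 volumes (>= 1).
#' @param seed Integer seed; the scheme is deterministic given the seed.
#' @return An object of class `gradient_scheme`: a list with `bvals`
#'   (length-n numeric), `bvecs` (n x 3 matrix, zero rows for b = 0, unit rows
#'   otherwise) and `n_volumes`.
#' @examples
#' sch <- make_gradient_scheme(30, 800, n_b0 = 1, seed = 0)
#' sch$n_volumes  # 31
#' @export
make_gradient_scheme <- function(n_directions, b_value = 800, n_b0 = 1,
                                 seed = 0) {
  if (!is_scalar_num(n_directions) || n_directions < 6) {
    stopf(paste(
      "`n_directions` must be >= 6: fewer directions leave the",
      "6-component diffusion tensor fit under-determined"
    ))
  }
  if (!is_scalar_num(b_value) || b_value <= 0) {
    stopf("`b_value` must be a positive scalar (s/mm^2)")
  }
  if (!is_scalar_num(n_b0) || n_b0 < 1) {
    stopf("at least one b = 0 volume is required")
  }
  n_directions <- as.integer(n_directions)
  n_b0 <- as.integer(n_b0)

  dirs <- with_seed(seed, repulsion_directions(n_directions))
  bvals <- c(rep(0, n_b0), rep(b_value, n_directions))
  bvecs <- rbind(
    matrix(0, nrow = n_b0, ncol = 3),
    dirs
  )
  scheme <- structure(
    list(bvals = bvals, bvecs = bvecs, n_volumes = n_b0 + n_directions),
    class = "gradient_scheme"
  )
  validate_scheme(scheme)
  scheme
}

# Antipodally-symmetric electrostatic repulsion on the unit sphere.
# Deterministic given the RNG state (callers fix it via with_seed()).
repulsion_directions <- function(n, n_iter = 300L) {
  p <- matrix(stats::rnorm(3 * n), ncol = 3)
  p <- p / sqrt(rowSums(p^2))
  step0 <- 0.1 / n
  for (it in seq_len(n_iter)) {
    q <- rbind(p, -p)
    force <- matrix(0, nrow = n, ncol = 3)
    for (i in seq_len(n)) {
      d <- sweep(q, 2, p[i, ], "-")           # vectors from p_i to charges
      r2 <- rowSums(d * d)
      r2[r2 < 1e-12] <- Inf                   # self term
      force[i, ] <- -colSums(d / r2^1.5)      # Coulomb repulsion
    }
    # project onto tangent plane and take a decaying step
    radial <- rowSums(force * p)
    force <- force - radial * p
    p <- p + step0 * exp(-3 * it / n_iter) * force
    p <- p / sqrt(rowSums(p^2))
  }
  p
}

#' Validate a gradient scheme
#'
#' Checks the structural invariants: matching lengths, unit-norm directions
#' for every b > 0 volume (tolerance 1e-8), at least one b = 0 volume, and at
#' least six pairwise non-collinear weighted directions.
#'
#' @param scheme A `gradient_scheme`.
#' @return The scheme, invisibly, if valid; otherwise an error.
#' @export
validate_scheme <- function(scheme) {
  if (!inherits(scheme, "gradient_scheme")) {
    stopf("`scheme` must be a gradient_scheme")
  }
  n <- scheme$n_volumes
  if (length(scheme$bvals) != n || nrow(scheme$bvecs) != n) {
    stopf("bvals/bvecs lengths do not match n_volumes = %d", n)
  }
  if (any(scheme$bvals < 0) || any(!is.finite(scheme$bvals))) {
    stopf("b-values must be finite and non-negative")
  }
  weighted <- scheme$bvals > 0
  if (!any(!weighted)) stopf("scheme has no b = 0 volume")
  dirs <- scheme$bvecs[weighted, , drop = FALSE]
  norms <- sqrt(rowSums(dirs^2))
  if (any(abs(norms - 1) > 1e-8)) {
    stopf("every b > 0 direction must have unit norm (tolerance 1e-8)")
  }
  if (qr(tensor_design(scheme))$rank < 7L) {
    stopf(paste(
      "gradient scheme is rank-deficient for tensor fitting:",
      "need >= 6 non-collinear b > 0 directions plus a b = 0 volume"
    ))
  }
  invisible(scheme)
}

#' @export
print.gradient_scheme <- function(x, ...) {
  nb0 <- sum(x$bvals == 0)
  cat(sprintf(
    "<gradient_scheme> %d volumes: %d b=0 + %d directions at b = %g s/mm^2\n",
    x$n_volumes, nb0, x$n_volumes - nb0, max(x$bvals)
  ))
  invisible(x)
}

# Design matrix for log-linear tensor estimation. One row per volume:
# log S = [1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz]
#         %*% (log S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
tensor_design <- function(scheme) {
  b <- scheme$bvals
  g <- scheme$bvecs
  cbind(
    1,
    -b * g[, 1]^2,
    -b * g[, 2]^2,
    -b * g[, 3]^2,
    -2 * b * g[, 1] * g[, 2],
    -2 * b * g[, 1] * g[, 3],
    -2 * b * g[, 2] * g[, 3]
  )
}
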