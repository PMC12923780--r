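#' Estimate the background noise level of a DWI volume
#'
#' Measures the mean signal outside the brain parenchyma across all volumes
#' (diffusion- and non-diffusion-weighted alike). If no explicit background
#' mask is supplied, the eight corner sub-blocks of the grid — each spanning
#' 10% of every dimension — are used, on the assumption that the object sits
#' centrally in the field of view.
#'
#' @param dwi A `dwi_volume`.
#' @param background_mask Optional logical 3-D array marking background
#'   voxels; overrides the corner-block default.
#' @return Scalar mean background signal (the noise floor).
#' @export
estimate_background_noise <- function(dwi, background_mask = NULL) {
  if (!inherits(dwi, "dwi_volume")) stopf("`dwi` must be a dwi_volume")
  dims <- dim(dwi$data)[1:3]
  if (is.null(background_mask)) {
    background_mask <- corner_mask(dims)
  }
  if (!is.logical(background_mask) ||
      !identical(dim(background_mask), as.integer(dims))) {
    stopf("`background_mask` must be a logical array matching the grid")
  }
  if (!any(background_mask)) {
    stopf("background region is empty; cannot estimate the noise level")
  }
  flat <- matrix(dwi$data, nrow = prod(dims))
  mean(flat[which(background_mask), , drop = FALSE])
}

corner_mask <- function(dims) {
  m <- array(FALSE, dim = dims)
  ext <- pmax(1L, floor(dims * 0.1))
  lo <- lapply(seq_len(3), function(i) seq_len(ext[i]))
  hi <- lapply(seq_len(3), function(i) seq(dims[i] - ext[i] + 1L, dims[i]))
  for (ix in list(lo[[1]], hi[[1]])) {
    for (iy in list(lo[[2]], hi[[2]])) {
      for (iz in list(lo[[3]], hi[[3]])) {
        m[ix, iy, iz] <- TRUE
      }
    }
  }
  m
}

#' Threshold a brain mask from the b = 0 signal
#'
#' A voxel is included when its mean unweighted (b = 0) signal exceeds
#' `k` times the background noise floor — the conventional multiple-of-
#' background criterion for removing non-brain voxels before tensor
#' calculation.
#'
#' @param dwi A `dwi_volume`.
#' @param noise_floor Scalar background level, usually from
#'   [estimate_background_noise()].
#' @param k Positive threshold multiplier (default 3).
#' @return Logical 3-D array; `TRUE` marks in-brain voxels. An empty mask
#'   triggers a warning.
#' @export
make_brain_mask <- function(dwi, noise_floor, k = 3) {
  if (!inherits(dwi, "dwi_volume")) stopf("`dwi` must be a dwi_volume")
  if (!is_scalar_num(k) || k <= 0) stopf("`k` must be > 0")
  if (!is_scalar_num(noise_floor) || noise_floor < 0) {
    stopf("`noise_floor` must be a non-negative scalar")
  }
  b0 <- which(dwi$scheme$bvals == 0)
  dims <- dim(dwi$data)[1:3]
  flat <- matrix(dwi$data, nrow = prod(dims))
  mean_b0 <- rowMeans(flat[, b0, drop = FALSE])
  mask <- array(mean_b0 > k * noise_floor, dim = dims)
  if (!any(mask)) {
    warning("brain mask is empty: threshold k * noise_floor exceeds all b=0 signal",
            call. = FALSE)
  }
  mask
}

#' Fit diffusion tensors by log-linear least squares
#'
#' Per masked voxel, ordinary least squares of the log-signal on the
#' diffusion design matrix recovers the six tensor components and log S0.
#' Noiseless monoexponential data are inverted exactly (to numerical
#' precision). Non-positive signals inside the mask — possible under
#' magnitude noise — are clamped to half the noise floor (or `1e-6 * S0`
#' when the noise floor is 0) before the logarithm. Negative fitted diagonal
#' diffusivities are retained, not clipped, and flagged so downstream ROI
#' means stay unbiased but auditable.
#'
#' @param dwi A `dwi_volume`.
#' @param scheme Gradient scheme (defaults to the one carried by `dwi`).
#' @param mask Logical 3-D inclusion mask; default includes every voxel.
#' @param noise_floor Scalar used for the clamping rule (default 0).
#' @param weighted If `TRUE`, use signal-weighted least squares (weights
#'   equal to the squared predicted signal from an initial OLS pass) instead
#'   of plain OLS.
#' @return An object of class `diffusivity_maps`: list with `maps` (named
#'   list of six 3-D arrays `dxx` ... `dyz`, mm^2/s, `NA` outside the mask),
#'   `s0` (3-D array), `mask`, `noise_floor`, and `n_negative_diag` (count of
#'   flagged voxels with a negative fitted diagonal component).
#' @export
fit_tensor_loglinear <- function(dwi, scheme = dwi$scheme, mask = NULL,
                                 noise_floor = 0, weighted = FALSE) {
  if (!inherits(dwi, "dwi_volume")) stopf("`dwi` must be a dwi_volume")
  validate_scheme(scheme)
  if (scheme$n_volumes != dim(dwi$data)[4]) {
    stopf("scheme has %d volumes but data has %d",
          scheme$n_volumes, dim(dwi$data)[4])
  }
  dims <- dim(dwi$data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dim = dims)
  if (!any(mask)) stopf("mask excludes every voxel; nothing to fit")

  X <- tensor_design(scheme)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stopf(paste(
      "tensor design is rank-deficient (rank %d < 7):",
      "the scheme needs >= 6 non-collinear b > 0 directions and a b = 0 volume"
    ), qrX$rank)
  }

  idx <- which(mask)
  flat <- matrix(dwi$data, nrow = prod(dims))
  S <- t(flat[idx, , drop = FALSE])             # n_vol x n_vox
  floor_val <- if (noise_floor > 0) noise_floor / 2 else 1e-6 * max(S)
  S[S <= 0] <- floor_val
  logS <- log(S)

  beta <- qr.coef(qrX, logS)                    # 7 x n_vox
  if (weighted) {
    # one reweighting pass: weights = squared predicted signal
    pred <- exp(X %*% beta)
    for (j in seq_along(idx)) {
      w <- pred[, j]^2
      beta[, j] <- qr.coef(qr(X * sqrt(w)), logS[, j] * sqrt(w))
    }
  }

  maps <- stats::setNames(vector("list", 6L), TENSOR_COMPONENTS)
  for (i in seq_len(6L)) {
    m <- array(NA_real_, dim = dims)
    m[idx] <- beta[i + 1L, ]
    maps[[i]] <- m
  }
  s0 <- array(NA_real_, dim = dims)
  s0[idx] <- exp(beta[1L, ])

  n_neg <- sum(beta[2:4, ] < 0)
  structure(
    list(
      maps = maps, s0 = s0, mask = mask,
      noise_floor = noise_floor, n_negative_diag = n_neg
    ),
    class = "diffusivity_maps"
  )
}

#' @export
print.diffusivity_maps <- function(x, ...) {
  cat(sprintf(
    "<diffusivity_maps> %s grid, %d voxels in mask, %d negative diagonal fits\n",
    paste(dim(x$mask), collapse = " x "), sum(x$mask), x$n_negative_diag
  ))
  invisible(x)
}
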