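test_that("background noise is zero for a noiseless phantom and exact for a pinned mask", {
  ph <- tiny_phantom()
  dwi <- simulate_dwi(ph, tiny_scheme(), noise_model = "none")
  expect_equal(estimate_background_noise(dwi), 0)

  # explicit one-voxel mask returns that voxel's mean over volumes
  m <- array(FALSE, dim = dim(dwi$data)[1:3])
  m[1, 1, 1] <- TRUE
  dwi$data[1, 1, 1, ] <- 42
  expect_equal(estimate_background_noise(dwi, m), 42)

  expect_error(estimate_background_noise(dwi, m & FALSE), "empty")
})

test_that("background estimate matches the Rayleigh closed form", {
  # Rician noise on a zero-signal background is Rayleigh(sigma):
  # mean sigma * sqrt(pi / 2), variance (2 - pi/2) * sigma^2
  sigma <- 10
  ph <- tiny_phantom()
  sch <- tiny_scheme(12)
  dwi <- simulate_dwi(ph, sch, noise_sigma = sigma, noise_model = "rician",
                      seed = 21)
  bg <- glymphalps:::corner_mask(dim(dwi$data)[1:3])
  stopifnot(!any(bg & ph$parenchyma))
  est <- estimate_background_noise(dwi, bg)
  n <- sum(bg) * sch$n_volumes
  se <- sqrt((2 - pi / 2) * sigma^2 / n)
  expect_lt(abs(est - sigma * sqrt(pi / 2)), 3 * se)
})

test_that("brain mask recovers the parenchyma from thresholding", {
  ph <- tiny_phantom()
  sch <- tiny_scheme()
  noiseless <- simulate_dwi(ph, sch, noise_model = "none")
  # noise floor 0: every positive-signal voxel included
  expect_identical(make_brain_mask(noiseless, 0, k = 3), ph$parenchyma)

  # S0 = 1000 parenchyma vs background noise mean ~ 20, k = 3
  sigma <- 20 / sqrt(pi / 2)
  noisy <- simulate_dwi(ph, sch, noise_sigma = sigma, noise_model = "rician",
                        seed = 4)
  floor_est <- estimate_background_noise(noisy)
  mask <- make_brain_mask(noisy, floor_est, k = 3)
  expect_identical(mask, ph$parenchyma)

  # threshold above S0: empty mask with a warning
  expect_warning(empty <- make_brain_mask(noiseless, 1e6, k = 3), "empty")
  expect_false(any(empty))
})

test_that("noiseless log-linear fit inverts the signal model exactly", {
  for (scheme in list(tiny_scheme(30, 800, seed = 0),
                      make_gradient_scheme(6, 1000, seed = 2))) {
    # isotropic
    iso <- uniform_field(diag(rep(0.7e-3, 3)))
    dwi <- simulate_dwi(iso, scheme, S0 = 900, noise_model = "none")
    maps <- fit_tensor_loglinear(dwi, scheme)
    expect_equal(mean(maps$maps$dxx), 0.7e-3, tolerance = 1e-9)
    expect_equal(mean(maps$maps$dyy), 0.7e-3, tolerance = 1e-9)
    expect_equal(mean(maps$maps$dzz), 0.7e-3, tolerance = 1e-9)
    expect_equal(max(abs(c(maps$maps$dxy, maps$maps$dxz, maps$maps$dyz))),
                 0, tolerance = 1e-12)
    expect_equal(mean(maps$s0), 900, tolerance = 1e-6)

    # anisotropic z-fiber
    tensor <- tensor_from_eigensystem(c(1.4, 0.5, 0.5) * 1e-3, c(0, 0, 1))
    dwi <- simulate_dwi(uniform_field(tensor), scheme, S0 = 900,
                        noise_model = "none")
    maps <- fit_tensor_loglinear(dwi, scheme)
    fitted <- vapply(maps$maps, mean, numeric(1))
    truth <- glymphalps:::tensor_to_vec(tensor)
    expect_equal(unname(fitted), truth, tolerance = 1e-9)
  }
})

test_that("fit is equivariant under rotations and S0 rescaling", {
  scheme <- tiny_scheme(30, 800, seed = 0)
  tensor <- tensor_from_eigensystem(c(1.4, 0.6, 0.3) * 1e-3, c(0, 0, 1))
  rot <- random_rotation(9)
  rotated_tensor <- rot %*% tensor %*% t(rot)
  rotated_scheme <- scheme
  rotated_scheme$bvecs <- scheme$bvecs %*% t(rot)

  fit_evals <- function(field, sch) {
    maps <- fit_tensor_loglinear(
      simulate_dwi(field, sch, S0 = 1000, noise_model = "none"), sch
    )
    v <- vapply(maps$maps, function(m) m[1, 1, 1], numeric(1))
    eigen(glymphalps:::vec_to_tensor(v), symmetric = TRUE,
          only.values = TRUE)$values
  }
  e1 <- fit_evals(uniform_field(tensor), scheme)
  e2 <- fit_evals(uniform_field(rotated_tensor), rotated_scheme)
  expect_equal(e1, e2, tolerance = 1e-8)

  # multiplying S0 by any c > 0 leaves the tensor untouched
  field <- uniform_field(tensor)
  m1 <- fit_tensor_loglinear(
    simulate_dwi(field, scheme, S0 = 250, noise_model = "none"), scheme)
  m2 <- fit_tensor_loglinear(
    simulate_dwi(field, scheme, S0 = 250 * 7.3, noise_model = "none"), scheme)
  expect_equal(m1$maps$dxx, m2$maps$dxx, tolerance = 1e-10)
  expect_equal(m1$maps$dyz, m2$maps$dyz, tolerance = 1e-10)
})

test_that("noisy fits agree with an independent normal-equations oracle", {
  scheme <- tiny_scheme(30, 800, seed = 0)
  tensor <- tensor_from_eigensystem(c(1.2, 0.6, 0.4) * 1e-3, c(0, 1, 0))
  field <- uniform_field(tensor, dims = c(10L, 10L, 5L))   # 500 voxels
  dwi <- simulate_dwi(field, scheme, S0 = 1000, noise_sigma = 1000 / 30,
                      noise_model = "rician", seed = 6)
  maps <- fit_tensor_loglinear(dwi, scheme)

  X <- glymphalps:::tensor_design(scheme)
  flat <- t(matrix(dwi$data, ncol = scheme$n_volumes))   # volumes x voxels
  oracle <- pinv_fit(X, log(flat))                       # 7 x n_vox
  expect_equal(mean(maps$maps$dxx), mean(oracle[2, ]), tolerance = 1e-10)
  expect_equal(mean(maps$maps$dyy), mean(oracle[3, ]), tolerance = 1e-10)
  # and the mean fitted Dxx sits within 3 SE of the truth
  se <- sd(maps$maps$dxx) / sqrt(length(maps$maps$dxx))
  expect_lt(abs(mean(maps$maps$dxx) - tensor[1, 1]), 3 * se)
})

test_that("masked-out voxels carry NA, never zero", {
  ph <- tiny_phantom()
  dwi <- simulate_dwi(ph, tiny_scheme(), noise_model = "none")
  maps <- fit_tensor_loglinear(dwi, mask = ph$parenchyma)
  expect_true(all(is.na(maps$maps$dxx[!ph$parenchyma])))
  expect_false(anyNA(maps$maps$dxx[ph$parenchyma]))
})

test_that("rank-deficient schemes are rejected by the fitter", {
  sch <- tiny_scheme(6, 800, seed = 1)
  sch$bvecs[-1, ] <- matrix(rep(c(0, 0, 1), 6), ncol = 3, byrow = TRUE)
  field <- uniform_field(diag(rep(1e-3, 3)))
  dwi <- structure(
    list(data = array(1, dim = c(4, 4, 2, 7)), scheme = sch,
         voxel_size = c(1.7, 1.7, 1.7)),
    class = "dwi_volume"
  )
  expect_error(fit_tensor_loglinear(dwi, sch), "rank-deficient")
})
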