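random_spd_tensor <- function() {
  A <- matrix(rnorm(9), 3, 3)
  D <- (A %*% t(A) + diag(3) * 0.1) * 2e-4
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

field_from_t6 <- function(t6mat, shape) {
  comps <- list(dxx = array(t6mat[, 1], shape), dyy = array(t6mat[, 2], shape),
                dzz = array(t6mat[, 3], shape), dxy = array(t6mat[, 4], shape),
                dxz = array(t6mat[, 5], shape), dyz = array(t6mat[, 6], shape))
  tensor_field(comps, diag(4))
}

test_that("fit_tensor recovers known tensors exactly from clean signal", {
  set.seed(5)
  sh <- c(4, 3, 3)
  t6 <- t(replicate(prod(sh), random_spd_tensor()))
  field <- field_from_t6(t6, sh)
  gt <- default_gradient_table()
  dwi <- synthesize_dwi(field, gt$gradients, gt$bvals, S0 = 100, sigma = 0)
  fit <- fit_tensor(dwi, gt$gradients, gt$bvals)
  for (cn in names(field$comps))
    expect_lt(max(abs(fit$comps[[cn]] - field$comps[[cn]])), 1e-8)
})

test_that("fit matches an independent normal-equations oracle", {
  set.seed(6)
  sh <- c(3, 3, 2)
  t6 <- t(replicate(prod(sh), random_spd_tensor()))
  field <- field_from_t6(t6, sh)
  gt <- default_gradient_table()
  dwi <- synthesize_dwi(field, gt$gradients, gt$bvals, S0 = 80, sigma = 2,
                        seed = 9)
  # disable the eigenvalue floor so the raw least-squares path is compared
  fit <- fit_tensor(dwi, gt$gradients, gt$bvals, lambda_min = -Inf)
  # oracle: explicit pseudo-inverse of the log design matrix per voxel
  g <- gt$gradients; b <- gt$bvals
  X <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  pinv <- solve(t(X) %*% X) %*% t(X)
  S <- matrix(dwi, nrow = prod(sh))
  for (v in sample(prod(sh), 6)) {
    beta <- pinv %*% log(S[v, ])
    expect_equal(c(fit$comps$dxx[v], fit$comps$dyy[v], fit$comps$dzz[v],
                   fit$comps$dxy[v], fit$comps$dxz[v], fit$comps$dyz[v]),
                 as.vector(beta[2:7]), tolerance = 1e-9)
  }
})

test_that("isotropic signal fits to FA below 1e-6", {
  sh <- c(3, 3, 3)
  t6 <- matrix(rep(c(7e-4, 7e-4, 7e-4, 0, 0, 0), each = prod(sh)),
               ncol = 6)
  field <- field_from_t6(t6, sh)
  gt <- default_gradient_table()
  dwi <- synthesize_dwi(field, gt$gradients, gt$bvals, sigma = 0)
  # isotropy: every weighted direction sees the same signal (up to the
  # 10-digit precision of the stored direction table)
  wtd <- which(gt$bvals > 0)
  expect_lt(max(apply(matrix(dwi, ncol = length(gt$bvals))[, wtd], 1,
                      function(r) diff(range(r)))), 1e-7)
  fit <- fit_tensor(dwi, gt$gradients, gt$bvals)
  expect_lt(max(fa_map(fit)$data), 1e-6)
})

test_that("signal is minimal along the principal diffusion axis", {
  ev <- cedplan:::axisym_eigenvalues(0.7, 7e-4)
  tdir <- c(1, 2, -1) / sqrt(6)
  D <- ev[2] * diag(3) + (ev[1] - ev[2]) * tdir %*% t(tdir)
  gt <- default_gradient_table()
  g <- gt$gradients[gt$bvals > 0, ]
  atten <- vapply(seq_len(nrow(g)),
                  function(i) g[i, ] %*% D %*% g[i, ], numeric(1))
  # the direction most aligned with tdir attenuates most
  expect_equal(which.max(atten), which.max(abs(g %*% tdir)))
})

test_that("fractional anisotropy follows the eigenvalue formula", {
  expect_equal(fractional_anisotropy(diag(3) * 7e-4), 0)
  expect_equal(fa_from_eigenvalues(1, 0, 0), 1)
  l <- c(1.7e-3, 0.3e-3, 0.3e-3)
  lb <- mean(l)
  want <- sqrt(3 / 2) * sqrt(sum((l - lb)^2)) / sqrt(sum(l^2))
  expect_equal(fa_from_eigenvalues(l[1], l[2], l[3]), want,
               tolerance = 1e-12)
  # matrix route agrees with eigen() on random SPD tensors
  set.seed(8)
  for (i in 1:10) {
    t6 <- random_spd_tensor()
    D <- cedplan:::tensor6_to_mat(t6)
    ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(fractional_anisotropy(D),
                 fa_from_eigenvalues(ev[1], ev[2], ev[3]),
                 tolerance = 1e-10)
  }
  expect_equal(fa_from_eigenvalues(0, 0, 0), 0)  # zero tensor convention
  expect_error(fractional_anisotropy(matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1),
                                            3, 3)), "symmetric")
})

test_that("zero-signal voxels are marked invalid, not NaN", {
  sh <- c(2, 2, 2)
  t6 <- t(replicate(prod(sh), random_spd_tensor()))
  field <- field_from_t6(t6, sh)
  gt <- default_gradient_table()
  dwi <- synthesize_dwi(field, gt$gradients, gt$bvals)
  dwi[1, 1, 1, ] <- 0
  fit <- fit_tensor(dwi, gt$gradients, gt$bvals)
  expect_equal(fit$valid[1, 1, 1], 0L)
  expect_false(anyNA(fit$comps$dxx))
})

test_that("DWI synthesis validates its inputs and is seed-reproducible", {
  field <- field_from_t6(matrix(rep(c(7e-4, 7e-4, 7e-4, 0, 0, 0), 8),
                                ncol = 6, byrow = TRUE), c(2, 2, 2))
  g5 <- rbind(c(0, 0, 0), diag(3), c(1, 1, 0) / sqrt(2))
  expect_error(synthesize_dwi(field, g5, c(0, rep(1000, 4))), "6 diffusion")
  gt <- default_gradient_table()
  expect_error(synthesize_dwi(field, gt$gradients, -gt$bvals), "b-value")
  a <- synthesize_dwi(field, gt$gradients, gt$bvals, sigma = 3, seed = 4)
  b <- synthesize_dwi(field, gt$gradients, gt$bvals, sigma = 3, seed = 4)
  c2 <- synthesize_dwi(field, gt$gradients, gt$bvals, sigma = 3, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, c2))
  expect_true(all(a >= 0))  # Rician magnitudes are non-negative
})
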