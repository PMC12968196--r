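#' Construct a diffusion tensor field
#'
#' Per-voxel symmetric 3x3 tensors stored as six component arrays
#' (xx, yy, zz, xy, xz, yz; units mm^2/s) plus a validity mask.
#'
#' @param comps named list of six 3-D arrays `dxx, dyy, dzz, dxy, dxz, dyz`.
#' @param affine 4x4 voxel-to-world affine.
#' @param valid binary 3-D array marking voxels with a meaningful tensor.
#' @return object of class `tensor_field`.
#' @export
tensor_field <- function(comps, affine, valid = NULL) {
  need <- c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz")
  stopifnot(all(need %in% names(comps)))
  d <- dim(comps$dxx)
  if (is.null(valid)) valid <- array(1L, dim = d)
  structure(list(comps = comps[need], affine = as.matrix(affine),
                 valid = valid),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat("<tensor_field> ", paste(dim(x$comps$dxx), collapse = " x "),
      " voxels, ", sum(x$valid > 0), " valid\n", sep = "")
  invisible(x)
}

tensor6_to_mat <- function(t6) {
  matrix(c(t6[1], t6[4], t6[5],
           t6[4], t6[2], t6[6],
           t6[5], t6[6], t6[3]), 3, 3)
}

# Eigenvalues of many symmetric 3x3 tensors at once (Cardano closed form).
# Input: 6-column matrix (xx, yy, zz, xy, xz, yz). Output: n x 3, descending.
eig3_sym_values <- function(m6) {
  a <- m6[, 1]; b <- m6[, 2]; c <- m6[, 3]
  d <- m6[, 4]; e <- m6[, 5]; f <- m6[, 6]
  p1 <- d^2 + e^2 + f^2
  q <- (a + b + c) / 3
  p2 <- (a - q)^2 + (b - q)^2 + (c - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  l1 <- l2 <- l3 <- q
  nz <- p > 0
  if (any(nz)) {
    aa <- (a - q) / p; bb <- (b - q) / p; cc <- (c - q) / p
    dd <- d / p; ee <- e / p; ff <- f / p
    # det of (A - qI)/p  for the shifted matrix
    detB <- aa * (bb * cc - ff^2) - dd * (dd * cc - ff * ee) +
      ee * (dd * ff - bb * ee)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    l1[nz] <- (q + 2 * p * cos(phi))[nz]
    l3[nz] <- (q + 2 * p * cos(phi + 2 * pi / 3))[nz]
    l2[nz] <- (3 * q - l1 - l3)[nz]
  }
  cbind(l1, l2, l3, deparse.level = 0)
}

#' Fractional anisotropy
#'
#' FA of a symmetric diffusion tensor from its eigenvalues:
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`. Zero tensors
#' have FA defined as 0.
#'
#' @param t a symmetric 3x3 matrix, or a length-6 vector
#'   (xx, yy, zz, xy, xz, yz).
#' @return scalar in `[0, 1]`.
#' @export
fractional_anisotropy <- function(t) {
  if (is.matrix(t) && all(dim(t) == c(3, 3))) {
    if (max(abs(t - base::t(t))) > 1e-8 * max(1, max(abs(t))))
      stop("tensor must be symmetric")
    t <- c(t[1, 1], t[2, 2], t[3, 3], t[1, 2], t[1, 3], t[2, 3])
  }
  l <- eig3_sym_values(matrix(t, 1, 6))[1, ]
  fa_from_eigenvalues(l[1], l[2], l[3])
}

#' @rdname fractional_anisotropy
#' @param l1,l2,l3 eigenvalues (any order).
#' @export
fa_from_eigenvalues <- function(l1, l2, l3) {
  ss <- l1^2 + l2^2 + l3^2
  out <- rep(0, length(l1))
  nz <- ss > 0
  lb <- (l1 + l2 + l3) / 3
  num <- (l1 - lb)^2 + (l2 - lb)^2 + (l3 - lb)^2
  out[nz] <- sqrt(1.5 * num[nz] / ss[nz])
  pmin(pmax(out, 0), 1)
}

#' FA map of a tensor field
#'
#' @param field a [tensor_field()].
#' @return a scalar `ced_volume` of FA values (0 outside the validity mask).
#' @export
fa_map <- function(field) {
  d <- dim(field$comps$dxx)
  m6 <- cbind(as.vector(field$comps$dxx), as.vector(field$comps$dyy),
              as.vector(field$comps$dzz), as.vector(field$comps$dxy),
              as.vector(field$comps$dxz), as.vector(field$comps$dyz))
  l <- eig3_sym_values(m6)
  fa <- fa_from_eigenvalues(l[, 1], l[, 2], l[, 3])
  fa[as.vector(field$valid) == 0] <- 0
  volume(array(fa, dim = d), field$affine)
}

# design matrix for the log-linear tensor fit: ln S = ln S0 - b g' D g
dti_design <- function(gradients, bvals) {
  g <- as.matrix(gradients)
  cbind(1,
        -bvals * g[, 1]^2, -bvals * g[, 2]^2, -bvals * g[, 3]^2,
        -2 * bvals * g[, 1] * g[, 2], -2 * bvals * g[, 1] * g[, 3],
        -2 * bvals * g[, 2] * g[, 3])
}

#' Fit diffusion tensors by log-linear least squares
#'
#' Solves, per voxel, `ln S_i = ln S0 - b_i g_i' D g_i` for `ln S0` and the
#' six unique tensor components in one least-squares solve over all voxels.
#' Voxels with any non-positive signal are marked invalid (not NaN).
#' Negative eigenvalues are clamped to `lambda_min`.
#'
#' @param dwi 4-D array (x, y, z, measurement) of signal intensities.
#' @param gradients n x 3 unit direction vectors (rows may be zero for b=0).
#' @param bvals length-n b-values in s/mm^2 (include at least one b ~ 0
#'   unless S0 is known from elsewhere).
#' @param affine 4x4 voxel-to-world affine for the output field.
#' @param mask optional binary 3-D array restricting the fit.
#' @param lambda_min eigenvalue floor in mm^2/s.
#' @return a [tensor_field()].
#' @export
fit_tensor <- function(dwi, gradients, bvals, affine = diag(4), mask = NULL,
                       lambda_min = 1e-7) {
  d <- dim(dwi)
  stopifnot(length(d) == 4L)
  g <- as.matrix(gradients)
  if (nrow(g) != d[4] || length(bvals) != d[4])
    stop("gradient table does not match the 4th dimension of the signal")
  if (sum(bvals > 0) < 6) stop("need at least 6 diffusion-weighted directions")
  X <- dti_design(g, bvals)
  nvox <- prod(d[1:3])
  S <- matrix(dwi, nrow = nvox)
  ok <- matrixStats_rowMins(S) > 0
  if (!is.null(mask)) ok <- ok & (as.vector(mask) > 0)
  beta <- matrix(0, nvox, 7)
  if (any(ok)) {
    Y <- log(t(S[ok, , drop = FALSE]))
    qx <- qr(X)
    if (qx$rank < 7) stop("gradient directions are collinear: rank-deficient fit")
    beta[ok, ] <- t(qr.coef(qx, Y))
  }
  comps <- list(dxx = beta[, 2], dyy = beta[, 3], dzz = beta[, 4],
                dxy = beta[, 5], dxz = beta[, 6], dyz = beta[, 7])
  # clamp negative eigenvalues where needed
  m6 <- do.call(cbind, comps)
  l <- eig3_sym_values(m6)
  bad <- which(ok & l[, 3] < lambda_min)
  for (i in bad) {
    e <- eigen(tensor6_to_mat(m6[i, ]), symmetric = TRUE)
    ev <- pmax(e$values, lambda_min)
    Dm <- e$vectors %*% diag(ev) %*% t(e$vectors)
    comps$dxx[i] <- Dm[1, 1]; comps$dyy[i] <- Dm[2, 2]; comps$dzz[i] <- Dm[3, 3]
    comps$dxy[i] <- Dm[1, 2]; comps$dxz[i] <- Dm[1, 3]; comps$dyz[i] <- Dm[2, 3]
  }
  comps <- lapply(comps, function(x) array(x, dim = d[1:3]))
  tensor_field(comps, affine, valid = array(as.integer(ok), dim = d[1:3]))
}

matrixStats_rowMins <- function(m) {
  out <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) out <- pmin(out, m[, j])
  out
}

#' Synthesize diffusion-weighted signal from a tensor field
#'
#' Monoexponential forward model `S_i = S0 exp(-b_i g_i' D g_i)` with
#' optional Rician noise (magnitude of two independent Gaussian channels),
#' matching magnitude MRI.
#'
#' @param field a [tensor_field()].
#' @param gradients n x 3 direction table (zero rows mean b = 0).
#' @param bvals length-n b-values in s/mm^2.
#' @param S0 non-diffusion-weighted signal level.
#' @param sigma Rician noise standard deviation (0 = noise free).
#' @param seed RNG seed used when `sigma > 0`.
#' @return 4-D array (x, y, z, measurement).
#' @export
synthesize_dwi <- function(field, gradients, bvals, S0 = 100, sigma = 0,
                           seed = 1L) {
  g <- as.matrix(gradients)
  if (any(bvals < 0) || all(bvals <= 0)) stop("b-values must include b > 0")
  if (sum(bvals > 0) < 6) stop("need at least 6 diffusion-weighted directions")
  d <- dim(field$comps$dxx)
  n <- nrow(g)
  cvec <- lapply(field$comps, as.vector)
  out <- array(0, dim = c(d, n))
  nvox <- prod(d)
  for (i in seq_len(n)) {
    gi <- g[i, ]
    quad <- cvec$dxx * gi[1]^2 + cvec$dyy * gi[2]^2 + cvec$dzz * gi[3]^2 +
      2 * cvec$dxy * gi[1] * gi[2] + 2 * cvec$dxz * gi[1] * gi[3] +
      2 * cvec$dyz * gi[2] * gi[3]
    out[(i - 1) * nvox + seq_len(nvox)] <- S0 * exp(-bvals[i] * quad)
  }
  if (sigma > 0) {
    rs <- local_rng(seed)
    on.exit(restore_rng(rs))
    nr <- length(out)
    out[] <- sqrt((out + stats::rnorm(nr, 0, sigma))^2 +
                    stats::rnorm(nr, 0, sigma)^2)
  }
  out
}

# RNG scoping helpers: isolate package RNG use from the global stream
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
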