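#' Construct a volume (3-D array plus world affine)
#'
#' A `ced_volume` couples a 3-D data array with a 4x4 affine that maps
#' 0-based voxel indices `(i, j, k, 1)` to world coordinates in mm, RAS+.
#' A voxel's world position is the position of its *center*; all geometry in
#' the package (distances, radii, margins, streamline lengths) is computed in
#' world mm so anisotropic grids need no special handling.
#'
#' @param data numeric/integer/logical 3-D array. Logical arrays are stored
#'   as integer 0/1.
#' @param affine 4x4 numeric matrix, invertible, last row `(0,0,0,1)`.
#' @return an object of class `ced_volume` with elements `data` and `affine`
#'   and attribute `frame = "world-RAS"`.
#' @export
volume <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L)
    stop("expected 3-D volume, got ", length(dim(data)), "-D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps * 100)
    stop("affine is singular")
  if (is.logical(data)) data <- array(as.integer(data), dim = dim(data))
  structure(list(data = data, affine = affine, frame = "world-RAS"),
            class = "ced_volume")
}

#' @export
print.ced_volume <- function(x, ...) {
  cat("<ced_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, voxel size ",
      paste(sprintf("%.3g", unlist(voxel_dimensions(x$affine))), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

is_binary_volume <- function(v) {
  u <- unique(as.vector(v$data))
  all(u %in% c(0, 1))
}

stopifnot_same_grid <- function(a, b) {
  if (!all(dim(a$data) == dim(b$data)) ||
      max(abs(a$affine - b$affine)) > 1e-4)
    stop("volumes are not on the same grid (co-registration contract violated)")
  invisible(TRUE)
}

#' Read a NIfTI-1 volume
#'
#' Loads a 3-D NIfTI file and returns a [volume()]. Files whose stored
#' orientation is not RAS+ are reoriented on load so that the world frame is
#' always RAS+. Integer-coded label images are preserved without rescaling.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a `ced_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (RNifti::orientation(img) != "RAS") RNifti::orientation(img) <- "RAS"
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) dim(img) <- d[1:3]
  if (length(dim(img)) != 3L)
    stop("expected 3-D volume: ", path, " is ", length(d), "-D")
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  volume(array(as.vector(img), dim = dim(img)), aff)
}

#' Write a volume as NIfTI-1
#'
#' Binary and integer label volumes are written with an integer datatype so
#' labels survive the round trip exactly; other data are written as float.
#'
#' @param v a `ced_volume`.
#' @param path destination `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "ced_volume"))
  dat <- v$data
  integral <- all(is.finite(dat)) && max(abs(dat - round(dat))) == 0 &&
    min(dat) >= -32768 && max(dat) <= 32767
  if (integral) storage.mode(dat) <- "integer"
  img <- RNifti::asNifti(dat)
  dims <- unlist(voxel_dimensions(v$affine))
  RNifti::pixdim(img) <- dims
  RNifti::qform(img) <- structure(v$affine, code = 2L)
  RNifti::sform(img) <- structure(v$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = if (integral) "int16" else "double")
  invisible(path)
}

#' Voxel dimensions from an affine
#'
#' The mm extent of one voxel along each index axis: the Euclidean norms of
#' the first three columns of the affine. Invariant under pure rotation.
#'
#' @param affine 4x4 affine matrix.
#' @return list with `dx`, `dy`, `dz` (mm), all strictly positive.
#' @export
voxel_dimensions <- function(affine) {
  if (inherits(affine, "ced_volume")) affine <- affine$affine
  if (abs(det(affine)) < .Machine$double.eps * 100) stop("affine is singular")
  n <- sqrt(colSums(affine[1:3, 1:3]^2))
  list(dx = n[1], dy = n[2], dz = n[3])
}

#' Voxel index to world coordinates (and back)
#'
#' Indices are 0-based and refer to voxel centers. `world_to_voxel` is the
#' exact inverse and may return out-of-grid (continuous) indices; callers
#' clip as needed.
#'
#' @param v a `ced_volume` (or 4x4 affine).
#' @param index numeric length-3 (or n x 3 matrix of) 0-based voxel indices.
#' @return mm coordinates (length 3 or n x 3).
#' @export
voxel_to_world <- function(v, index) {
  aff <- if (inherits(v, "ced_volume")) v$affine else v
  idx <- rbind2mat(index)
  out <- idx %*% t(aff[1:3, 1:3]) +
    matrix(aff[1:3, 4], nrow(idx), 3, byrow = TRUE)
  if (is.null(dim(index))) out[1, ] else out
}

#' @rdname voxel_to_world
#' @param point mm point(s), length 3 or n x 3.
#' @export
world_to_voxel <- function(v, point) {
  aff <- if (inherits(v, "ced_volume")) v$affine else v
  inv <- solve(aff)
  pts <- rbind2mat(point)
  out <- pts %*% t(inv[1:3, 1:3]) +
    matrix(inv[1:3, 4], nrow(pts), 3, byrow = TRUE)
  if (is.null(dim(point))) out[1, ] else out
}

rbind2mat <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), 1, 3) else {
    storage.mode(x) <- "double"
    x
  }
}

# Exact 1-D squared-distance transform (lower envelope of parabolas).
# f: squared distances sampled at positions (0:(n-1)) * w.
dt1d_sq <- function(f, w) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (length(fin) == 0L) return(f)
  if (length(fin) == n && all(f == 0)) return(f)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1] <- fin[1]; z[1] <- -Inf; z[2] <- Inf
  if (length(fin) > 1L) for (q in fin[-1]) {
    qq <- q
    repeat {
      p <- v[k]
      s <- ((f[qq] + (qq - 1)^2 * w^2) - (f[p] + (p - 1)^2 * w^2)) /
        (2 * w * (qq - p))
      if (s > z[k]) break
      k <- k - 1L
    }
    k <- k + 1L; v[k] <- qq; z[k] <- s; z[k + 1L] <- Inf
  }
  d <- numeric(n); j <- 1L
  for (q in seq_len(n)) {
    x <- (q - 1) * w
    while (z[j + 1L] < x) j <- j + 1L
    p <- v[j]
    d[q] <- (x - (p - 1) * w)^2 + f[p]
  }
  d
}

dt_axis <- function(arr, w) {
  # transform along the first array axis
  d <- dim(arr)
  m <- matrix(arr, nrow = d[1])
  for (j in seq_len(ncol(m))) m[, j] <- dt1d_sq(m[, j], w)
  array(m, dim = d)
}

#' Euclidean distance transform of a binary mask
#'
#' At every voxel, the exact Euclidean distance in mm to the nearest voxel
#' center where the mask is 1 (0 inside the mask). Anisotropy-aware: each
#' axis is scaled by its voxel dimension. Computed with the separable
#' lower-envelope (parabola) algorithm, so it is exact, not a chamfer
#' approximation.
#'
#' @param mask a binary `ced_volume`.
#' @return a scalar `ced_volume` of distances in mm; if the mask is empty
#'   all distances are `Inf` and a warning is raised.
#' @export
distance_to_mask <- function(mask) {
  stopifnot(inherits(mask, "ced_volume"))
  if (!is_binary_volume(mask)) stop("distance_to_mask needs a binary mask")
  vd <- unlist(voxel_dimensions(mask$affine))
  f <- array(ifelse(mask$data > 0, 0, Inf), dim = dim(mask$data))
  if (all(!is.finite(f))) {
    warning("empty mask: all distances are infinite")
    return(volume(f, mask$affine))
  }
  f <- dt_axis(f, vd[1])
  f <- aperm(dt_axis(aperm(f, c(2, 1, 3)), vd[2]), c(2, 1, 3))
  f <- aperm(dt_axis(aperm(f, c(3, 2, 1)), vd[3]), c(3, 2, 1))
  volume(sqrt(f), mask$affine)
}

#' Trilinear interpolation of a scalar volume at world points
#'
#' Points outside the grid are clamped to the nearest voxel center before
#' interpolation.
#'
#' @param v a scalar `ced_volume`.
#' @param points n x 3 matrix (or length-3 vector) of mm points.
#' @return numeric vector of interpolated values.
#' @export
interpolate_volume <- function(v, points) {
  pts <- rbind2mat(points)
  idx <- world_to_voxel(v, pts)
  trilinear_gather(list(v$data), idx)[[1]]
}

# Shared trilinear kernel: interpolate each array in `arrs` at continuous
# 0-based voxel indices (n x 3), clamped to the grid.
trilinear_gather <- function(arrs, idx) {
  d <- dim(arrs[[1]])
  ix <- pmin(pmax(idx[, 1], 0), d[1] - 1)
  iy <- pmin(pmax(idx[, 2], 0), d[2] - 1)
  iz <- pmin(pmax(idx[, 3], 0), d[3] - 1)
  x0 <- pmin(floor(ix), d[1] - 2); y0 <- pmin(floor(iy), d[2] - 2)
  z0 <- pmin(floor(iz), d[3] - 2)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0); z0 <- pmax(z0, 0)
  fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
  n12 <- d[1] * d[2]
  base <- x0 + d[1] * y0 + n12 * z0 + 1  # 1-based linear index of corner 000
  w <- list(
    (1 - fx) * (1 - fy) * (1 - fz), fx * (1 - fy) * (1 - fz),
    (1 - fx) * fy * (1 - fz),       fx * fy * (1 - fz),
    (1 - fx) * (1 - fy) * fz,       fx * (1 - fy) * fz,
    (1 - fx) * fy * fz,             fx * fy * fz)
  off <- c(0, 1, d[1], d[1] + 1, n12, n12 + 1, n12 + d[1], n12 + d[1] + 1)
  lapply(arrs, function(a) {
    av <- as.vector(a)
    out <- 0
    for (c8 in 1:8) out <- out + w[[c8]] * av[base + off[c8]]
    out
  })
}

# world points -> 0-based nearest voxel index, or NA if outside the grid
nearest_voxel <- function(v, points) {
  idx <- round(world_to_voxel(v, rbind2mat(points)))
  d <- dim(v$data)
  bad <- idx[, 1] < 0 | idx[, 1] >= d[1] | idx[, 2] < 0 | idx[, 2] >= d[2] |
    idx[, 3] < 0 | idx[, 3] >= d[3]
  idx[bad, ] <- NA_real_
  idx
}

# membership of world points in a binary mask (voxel-center convention)
points_in_mask <- function(mask, points) {
  idx <- nearest_voxel(mask, points)
  ok <- !is.na(idx[, 1])
  out <- logical(nrow(idx))
  if (any(ok)) {
    lin <- idx[ok, 1] + dim(mask$data)[1] * idx[ok, 2] +
      dim(mask$data)[1] * dim(mask$data)[2] * idx[ok, 3] + 1
    out[ok] <- mask$data[lin] > 0
  }
  out
}
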