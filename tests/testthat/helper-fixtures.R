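# Shared fixtures and independent oracles, built in code at test time.

.fixture_cache <- new.env(parent = emptyenv())

# default 64^3 @ 2 mm phantom, generated once per test run
cached_phantom <- function() {
  if (is.null(.fixture_cache$phantom))
    .fixture_cache$phantom <- generate_phantom(phantom_spec())
  .fixture_cache$phantom
}

cached_frame <- function() {
  sp <- phantom_spec()
  acpc_frame(sp$ac, sp$pc, sp$ih)
}

# random rotation matrix (det +1) from QR of a Gaussian matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Hand-built tensor field: near-isotropic background plus straight tube
# segments (list of list(p0, p1)) of anisotropic tensors tangent to each
# segment. Independent of the phantom generator's bundle machinery.
make_line_field <- function(shape, segments, tube_radius = 2.5,
                            fa_bundle = 0.7, fa_bg = 0.05, md = 7e-4,
                            affine = diag(4)) {
  grid <- volume(array(0L, dim = shape), affine)
  ev_bg <- cedplan:::axisym_eigenvalues(fa_bg, md)
  ev_bu <- cedplan:::axisym_eigenvalues(fa_bundle, md)
  n <- prod(shape)
  comps <- list(dxx = rep(ev_bg[2] + (ev_bg[1] - ev_bg[2]), n),
                dyy = rep(ev_bg[2], n), dzz = rep(ev_bg[2], n),
                dxy = rep(0, n), dxz = rep(0, n), dyz = rep(0, n))
  for (sgm in segments) {
    p0 <- sgm$p0; p1 <- sgm$p1
    len <- sqrt(sum((p1 - p0)^2))
    tg <- (p1 - p0) / len
    for (s in seq(0, len, by = 0.5)) {
      ctr <- p0 + s * tg
      lin <- cedplan:::sphere_voxels(ctr, tube_radius, grid)
      comps$dxx[lin] <- ev_bu[2] + (ev_bu[1] - ev_bu[2]) * tg[1]^2
      comps$dyy[lin] <- ev_bu[2] + (ev_bu[1] - ev_bu[2]) * tg[2]^2
      comps$dzz[lin] <- ev_bu[2] + (ev_bu[1] - ev_bu[2]) * tg[3]^2
      comps$dxy[lin] <- (ev_bu[1] - ev_bu[2]) * tg[1] * tg[2]
      comps$dxz[lin] <- (ev_bu[1] - ev_bu[2]) * tg[1] * tg[3]
      comps$dyz[lin] <- (ev_bu[1] - ev_bu[2]) * tg[2] * tg[3]
    }
  }
  comps <- lapply(comps, array, dim = shape)
  tensor_field(comps, affine)
}

# O(n^2) brute-force distance transform oracle (mm, anisotropy-aware)
brute_force_edt <- function(mask_arr, voxdims) {
  d <- dim(mask_arr)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  pts <- sweep(idx, 2, voxdims, `*`)
  src <- pts[as.vector(mask_arr) > 0, , drop = FALSE]
  if (nrow(src) == 0) return(array(Inf, dim = d))
  out <- numeric(nrow(pts))
  for (v in seq_len(nrow(pts))) {
    dv <- sweep(src, 2, pts[v, ], `-`)
    out[v] <- sqrt(min(rowSums(dv^2)))
  }
  array(out, dim = d)
}

# Exhaustive mid-p McNemar oracle: enumerate all 2^(b+c) equally likely
# orderings of the discordant pairs under the null.
enumerate_midp <- function(b, cc) {
  n <- b + cc
  if (n == 0) return(1)
  m <- max(b, cc)
  x <- rowSums(as.matrix(expand.grid(rep(list(0:1), n))))
  c_ge <- sum(x >= m)
  c_eq <- sum(x == m)
  min((2 * c_ge - c_eq) / 2^n, 1)
}

# small seeded GA instance: blobby segment + <= 6 valid centers inside it
ga_instance <- function(seed) {
  set.seed(seed)
  seg <- random_blob_mask(c(12, 12, 12), diag(4), n_spheres = 2)
  if (sum(seg$data) < 10) seg$data[4:9, 4:9, 4:9] <- 1L
  w <- which(seg$data > 0)
  pick <- sample(w, min(6, length(w)))
  vc <- voxel_to_world(seg, arrayInd(pick, dim(seg$data)) - 1)
  list(seg = seg, vc = vc)
}

# random blobby binary mask: union of a few spheres inside a small grid
random_blob_mask <- function(shape, affine = diag(4), n_spheres = 3) {
  grid <- volume(array(0L, dim = shape), affine)
  arr <- array(0L, dim = shape)
  ext <- voxel_to_world(affine, shape - 1)
  org <- voxel_to_world(affine, c(0, 0, 0))
  for (i in seq_len(n_spheres)) {
    ctr <- org + runif(3, 0.25, 0.75) * (ext - org)
    r <- runif(1, 0.15, 0.3) * min(ext - org)
    arr[cedplan:::sphere_voxels(ctr, r, grid)] <- 1L
  }
  volume(arr, affine)
}
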