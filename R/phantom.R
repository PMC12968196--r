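#' Specification of a synthetic CED planning phantom
#'
#' Describes a fully ground-truthed digital phantom emulating the study
#' conditions of the pipeline's intended inputs: axis-alignable label
#' volumes at 2 mm isotropic resolution, a 64-direction b = 1000 s/mm^2
#' diffusion protocol, anisotropic fiber bundles connecting cortical ROIs to
#' chosen putamen quadrants, ventricle/vessel-like critical structures, and
#' per-hemisphere frontal/occipital entry and target points.
#'
#' Default geometry (world mm, RAS, grid centered on the origin): an
#' ellipsoidal brain; one putamen ellipsoid per hemisphere straddling all
#' four AC-PC quadrants; an SMA-like motor ROI (superior-medial) connected
#' by a curved bundle to the superior-posterior quadrant, and an
#' amygdala-like non-motor ROI (anterior-inferior) connected to the
#' inferior-posterior quadrant; a midline ventricle slab and a lateral
#' vessel cylinder as critical structures; frontal (anterior-superior) and
#' occipital (posterior) entry points per hemisphere.
#'
#' @param grid_shape integer triple of voxel counts.
#' @param voxel_size_mm isotropic voxel edge in mm.
#' @param n_subjects cohort size emulated by the pipeline (phantom anatomy
#'   is shared; per-subject noise differs through the seed).
#' @param hemispheres "both", "left" or "right".
#' @param ac,pc,ih landmark mm points (AC, PC, superior reference).
#' @param fa_bundle target FA inside fiber bundles.
#' @param fa_background background FA.
#' @param md_mm2s mean diffusivity everywhere, mm^2/s.
#' @param n_directions,b_svalue DWI protocol (64 directions, 1000 s/mm^2).
#' @param S0 non-weighted signal level.
#' @param noise_sigma Rician noise sd (0 = clean fixture mode).
#' @param seed RNG seed; the only source of randomness.
#' @return object of class `phantom_spec` (a validated list, including the
#'   per-hemisphere putamen/ROI/bundle/critical-structure geometry and the
#'   entry/target points; all overridable via `...`-free list editing).
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L), voxel_size_mm = 2,
                         n_subjects = 2L,
                         hemispheres = c("both", "left", "right"),
                         ac = c(0, 8, 0), pc = c(0, -18, 0),
                         ih = c(0, 8, 40),
                         fa_bundle = 0.7, fa_background = 0.05,
                         md_mm2s = 7e-4,
                         n_directions = 64L, b_svalue = 1000,
                         S0 = 100, noise_sigma = 0, seed = 1L) {
  hemispheres <- match.arg(hemispheres)
  if (max(abs(ac - pc)) < 1e-9) stop("AC and PC must differ")
  hemi_sign <- function(h) if (h == "left") -1 else 1
  hs <- switch(hemispheres, both = c("left", "right"),
               left = "left", right = "right")
  mk_hemi <- function(h) {
    s <- hemi_sign(h)
    list(
      putamen = list(center = c(s * 24, 2, 2), semi = c(7, 16, 11)),
      rois = list(
        SMA = list(center = c(s * 10, 0, 48), radius = 6, motor = TRUE),
        amygdala = list(center = c(s * 24, 14, -30), radius = 6,
                        motor = FALSE)),
      bundles = list(
        list(roi = "SMA", quadrant = "superior-posterior", tube_radius = 3,
             p0 = c(s * 10, 0, 48), ctrl = c(s * 14, -2, 28),
             p1 = c(s * 24, -2, 6)),
        list(roi = "amygdala", quadrant = "inferior-posterior",
             tube_radius = 3,
             p0 = c(s * 24, 14, -30), ctrl = c(s * 24, 7, -18),
             p1 = c(s * 24, 0, -6))),
      entries = list(
        frontal = list(entry = c(s * 20, 48, 30), target = c(s * 24, -8, 4)),
        occipital = list(entry = c(s * 20, -52, 20),
                         target = c(s * 24, 6, 6))))
  }
  structure(list(
    grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
    n_subjects = as.integer(n_subjects), hemispheres = hs,
    ac = ac, pc = pc, ih = ih,
    brain = list(center = c(0, 0, 6), semi = c(55, 60, 50)),
    hemi = stats::setNames(lapply(hs, mk_hemi), hs),
    critical = list(
      ventricles = list(type = "box", lo = c(-6, -30, 0), hi = c(6, 20, 28)),
      vessel = list(type = "cylinder_z", center_xy = c(34, 30), radius = 1.5,
                    z = c(-10, 40))),
    fa_bundle = fa_bundle, fa_background = fa_background,
    md_mm2s = md_mm2s,
    dwi = list(n_directions = as.integer(n_directions), b = b_svalue,
               S0 = S0, sigma = noise_sigma),
    seed = as.integer(seed)), class = "phantom_spec")
}

phantom_affine <- function(spec) {
  aff <- diag(4)
  aff[1, 1] <- aff[2, 2] <- aff[3, 3] <- spec$voxel_size_mm
  aff[1:3, 4] <- -(spec$grid_shape - 1) / 2 * spec$voxel_size_mm
  aff
}

# world coordinates of all voxel centers, n x 3
grid_points <- function(shape, affine) {
  idx <- as.matrix(expand.grid(i = seq_len(shape[1]) - 1,
                               j = seq_len(shape[2]) - 1,
                               k = seq_len(shape[3]) - 1))
  voxel_to_world(affine, idx)
}

#' Geometric mask builders
#'
#' Voxel-center membership masks for simple solids, used by the phantom
#' generator and handy for constructing test geometry.
#'
#' @param grid a `ced_volume` (shape/affine template).
#' @param center,semi ellipsoid center and semi-axes, mm.
#' @return binary `ced_volume`.
#' @export
ellipsoid_mask <- function(grid, center, semi) {
  p <- grid_points(dim(grid$data), grid$affine)
  v <- ((p[, 1] - center[1]) / semi[1])^2 +
    ((p[, 2] - center[2]) / semi[2])^2 +
    ((p[, 3] - center[3]) / semi[3])^2 <= 1
  volume(array(as.integer(v), dim = dim(grid$data)), grid$affine)
}

#' @rdname ellipsoid_mask
#' @param lo,hi opposite corners of an axis-aligned box, mm.
#' @export
box_mask <- function(grid, lo, hi) {
  p <- grid_points(dim(grid$data), grid$affine)
  v <- p[, 1] >= lo[1] & p[, 1] <= hi[1] &
    p[, 2] >= lo[2] & p[, 2] <= hi[2] &
    p[, 3] >= lo[3] & p[, 3] <= hi[3]
  volume(array(as.integer(v), dim = dim(grid$data)), grid$affine)
}

#' @rdname ellipsoid_mask
#' @param center_xy axis position (x, y) of a z-aligned cylinder, mm.
#' @param radius cylinder radius, mm.
#' @param zrange length-2 z extent, mm.
#' @export
cylinder_z_mask <- function(grid, center_xy, radius, zrange) {
  p <- grid_points(dim(grid$data), grid$affine)
  v <- (p[, 1] - center_xy[1])^2 + (p[, 2] - center_xy[2])^2 <= radius^2 &
    p[, 3] >= zrange[1] & p[, 3] <= zrange[2]
  volume(array(as.integer(v), dim = dim(grid$data)), grid$affine)
}

# axially symmetric eigenvalues with given FA and mean diffusivity
axisym_eigenvalues <- function(fa, md) {
  stopifnot(fa >= 0, fa < 1)
  if (fa == 0) return(c(md, md))
  f <- function(r) (1 - r) / sqrt(1 + 2 * r^2) - fa
  r <- stats::uniroot(f, c(0, 1), tol = 1e-14)$root
  l_par <- 3 * md / (1 + 2 * r)
  c(l_par, r * l_par)  # (lambda_parallel, lambda_perp)
}

# quadratic Bezier curve samples + unit tangents
bezier_curve <- function(p0, ctrl, p1, ds = 0.5) {
  # arc-length-ish parameterization: oversample then walk
  tt <- seq(0, 1, length.out = 512)
  B <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), ctrl) +
    outer(tt^2, p1)
  seg <- sqrt(rowSums((B[-1, ] - B[-nrow(B), ])^2))
  s <- c(0, cumsum(seg))
  keep <- findInterval(seq(0, s[length(s)], by = ds), s)
  keep <- unique(pmin(keep, nrow(B)))
  pts <- B[keep, , drop = FALSE]
  Tg <- 2 * outer(1 - tt[keep], ctrl - p0) + 2 * outer(tt[keep], p1 - ctrl)
  Tg <- Tg / sqrt(rowSums(Tg^2))
  list(points = pts, tangents = Tg, length = s[length(s)])
}

quadrant_of_points <- function(p, frame) {
  rel <- p - matrix(frame$ac, nrow(p), 3, byrow = TRUE)
  sup <- rel %*% frame$z_si >= 0
  ant <- rel %*% frame$y_ap >= 0
  code <- integer(nrow(p))
  code[sup & ant] <- 1L; code[sup & !ant] <- 2L
  code[!sup & !ant] <- 3L; code[!sup & ant] <- 4L
  code
}

#' Generate a synthetic phantom
#'
#' Builds all label volumes, the diffusion tensor field (axially symmetric
#' tensors with the principal eigenvector along the local bundle tangent
#' inside each tube, near-isotropic elsewhere), the planted-connection truth
#' table, landmarks, and entry/target points. Deterministic given
#' `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @param with_dwi also synthesize the 4-D DWI signal (slower; the tensor
#'   field itself is always returned).
#' @return object of class `phantom`: `brain_mask`, `putamen_mask` (named by
#'   hemisphere), `roi_masks` (named list per hemisphere), `critical_masks`,
#'   `tensor_field`, optional `dwi` (`signal`, `gradients`, `bvals`),
#'   `truth` (data.frame roi/quadrant/hemisphere), `landmarks`, `entries`
#'   (data.frame), `spec`.
#' @export
generate_phantom <- function(spec, with_dwi = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  aff <- phantom_affine(spec)
  shape <- spec$grid_shape
  template <- volume(array(0L, dim = shape), aff)
  brain <- ellipsoid_mask(template, spec$brain$center, spec$brain$semi)
  frame <- acpc_frame(spec$ac, spec$pc, spec$ih)

  putamen <- list(); rois <- list()
  for (h in spec$hemispheres) {
    hg <- spec$hemi[[h]]
    putamen[[h]] <- ellipsoid_mask(template, hg$putamen$center,
                                   hg$putamen$semi)
    rois[[h]] <- lapply(hg$rois, function(r)
      ellipsoid_mask(template, r$center, rep(r$radius, 3)))
  }

  crit <- list()
  for (cn in names(spec$critical)) {
    cs <- spec$critical[[cn]]
    m <- switch(cs$type,
                box = box_mask(template, cs$lo, cs$hi),
                cylinder_z = cylinder_z_mask(template, cs$center_xy,
                                             cs$radius, cs$z),
                stop("unknown critical structure type: ", cs$type))
    # clip to the brain so every phantom mask lies inside the brain mask
    m$data <- m$data * brain$data
    crit[[cn]] <- m
  }

  # tensor field: near-isotropic background inside the brain, axially
  # symmetric bundle tensors with eigenvector along the tube tangent
  ev_bg <- axisym_eigenvalues(spec$fa_background, spec$md_mm2s)
  ev_bu <- axisym_eigenvalues(spec$fa_bundle, spec$md_mm2s)
  nvox <- prod(shape)
  bg_dir <- c(1, 0, 0)
  comps <- list(
    dxx = rep(ev_bg[2] + (ev_bg[1] - ev_bg[2]) * bg_dir[1]^2, nvox),
    dyy = rep(ev_bg[2] + (ev_bg[1] - ev_bg[2]) * bg_dir[2]^2, nvox),
    dzz = rep(ev_bg[2] + (ev_bg[1] - ev_bg[2]) * bg_dir[3]^2, nvox),
    dxy = rep(0, nvox), dxz = rep(0, nvox), dyz = rep(0, nvox))

  vd <- rep(spec$voxel_size_mm, 3)
  best_d2 <- rep(Inf, nvox)
  truth <- NULL
  for (h in spec$hemispheres) {
    for (bu in spec$hemi[[h]]$bundles) {
      bz <- bezier_curve(bu$p0, bu$ctrl, bu$p1, ds = spec$voxel_size_mm / 4)
      entered <- FALSE
      for (si in seq_len(nrow(bz$points))) {
        ctr <- bz$points[si, ]
        tg <- bz$tangents[si, ]
        lin <- sphere_voxels(ctr, bu$tube_radius, template)
        if (length(lin) == 0) next
        idx <- arrayInd(lin, shape) - 1
        w <- voxel_to_world(aff, idx)
        d2 <- rowSums((w - matrix(ctr, nrow(w), 3, byrow = TRUE))^2)
        upd <- lin[d2 < best_d2[lin]]
        d2u <- d2[d2 < best_d2[lin]]
        if (length(upd)) {
          best_d2[upd] <- d2u
          comps$dxx[upd] <- ev_bu[2] + (ev_bu[1] - ev_bu[2]) * tg[1]^2
          comps$dyy[upd] <- ev_bu[2] + (ev_bu[1] - ev_bu[2]) * tg[2]^2
          comps$dzz[upd] <- ev_bu[2] + (ev_bu[1] - ev_bu[2]) * tg[3]^2
          comps$dxy[upd] <- (ev_bu[1] - ev_bu[2]) * tg[1] * tg[2]
          comps$dxz[upd] <- (ev_bu[1] - ev_bu[2]) * tg[1] * tg[3]
          comps$dyz[upd] <- (ev_bu[1] - ev_bu[2]) * tg[2] * tg[3]
        }
        if (!entered &&
            points_in_mask(putamen[[h]], matrix(ctr, 1)) &&
            quadrant_of_points(matrix(ctr, 1), frame) ==
            SEGMENT_CODES[[bu$quadrant]])
          entered <- TRUE
      }
      if (!entered)
        stop("configuration error: bundle '", bu$roi, "' (", h,
             ") never enters its stated quadrant ", bu$quadrant)
      truth <- rbind(truth, data.frame(roi = bu$roi, quadrant = bu$quadrant,
                                       hemisphere = h,
                                       stringsAsFactors = FALSE))
    }
  }
  comps <- lapply(comps, function(x) array(x, dim = shape))
  field <- tensor_field(comps, aff, valid = brain$data)

  entries <- do.call(rbind, lapply(spec$hemispheres, function(h) {
    do.call(rbind, lapply(names(spec$hemi[[h]]$entries), function(ap) {
      e <- spec$hemi[[h]]$entries[[ap]]
      data.frame(hemisphere = h, approach = ap,
                 entry_x = e$entry[1], entry_y = e$entry[2],
                 entry_z = e$entry[3],
                 target_x = e$target[1], target_y = e$target[2],
                 target_z = e$target[3], stringsAsFactors = FALSE)
    }))
  }))

  ph <- structure(list(
    brain_mask = brain, putamen_mask = putamen, roi_masks = rois,
    critical_masks = crit, tensor_field = field, truth = truth,
    landmarks = list(ac = spec$ac, pc = spec$pc, ih = spec$ih),
    entries = entries, spec = spec), class = "phantom")

  if (with_dwi) {
    gt <- default_gradient_table(spec$dwi$n_directions, spec$dwi$b)
    ph$dwi <- list(
      signal = synthesize_dwi(field, gt$gradients, gt$bvals,
                              S0 = spec$dwi$S0, sigma = spec$dwi$sigma,
                              seed = spec$seed),
      gradients = gt$gradients, bvals = gt$bvals)
  }
  ph
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom> ", paste(x$spec$grid_shape, collapse = "x"), " @ ",
      x$spec$voxel_size_mm, " mm, hemispheres: ",
      paste(x$spec$hemispheres, collapse = ", "), "\n", sep = "")
  cat("planted connections:\n")
  print(x$truth)
  invisible(x)
}

#' Electrostatically repelled unit vectors (gradient scheme generator)
#'
#' Generates `n` approximately uniformly spread unit vectors by iterative
#' pairwise repulsion on the sphere with antipodal symmetry (the standard
#' construction for diffusion gradient schemes). Deterministic given the
#' seed. The packaged 64-direction table fixture was produced with this
#' function.
#'
#' @param n number of directions.
#' @param seed RNG seed for the initial configuration.
#' @param iters repulsion iterations.
#' @return n x 3 matrix of unit vectors.
#' @export
generate_gradient_directions <- function(n, seed = 42L, iters = 2000L) {
  rs <- local_rng(seed)
  on.exit(restore_rng(rs))
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2))
  step <- 0.05
  for (it in seq_len(iters)) {
    frc <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      d1 <- v - matrix(v[i, ], n, 3, byrow = TRUE)   # toward i: repulsion
      d2 <- -v - matrix(v[i, ], n, 3, byrow = TRUE)  # antipodes
      r1 <- rowSums(d1^2); r2 <- rowSums(d2^2)
      r1[i] <- Inf
      r2[r2 < 1e-12] <- Inf
      frc[i, ] <- -colSums(d1 / (r1^1.5 + 1e-12)) - colSums(d2 / (r2^1.5 + 1e-12))
    }
    v <- v + step * frc / n
    v <- v / sqrt(rowSums(v^2))
    step <- step * 0.999
  }
  v
}

#' Read / fetch the packaged FSL-style gradient table
#'
#' The package ships a fixed 64-direction table (plus one b = 0
#' measurement) as an FSL-style bvec/bval text pair under `extdata`.
#'
#' @param n_directions number of diffusion-weighted directions expected.
#' @param b b-value assigned to the weighted measurements, s/mm^2.
#' @return list with `gradients` ((n+1) x 3, first row zero) and `bvals`.
#' @export
default_gradient_table <- function(n_directions = 64L, b = 1000) {
  bvec <- system.file("extdata", "dwi64.bvec", package = "cedplan")
  g <- t(as.matrix(utils::read.table(bvec)))
  if (n_directions != nrow(g) - 1)
    stop("packaged table has ", nrow(g) - 1, " directions")
  list(gradients = unname(g), bvals = c(0, rep(b, nrow(g) - 1)))
}

#' Write a phantom to disk
#'
#' Writes every mask and a JSON manifest (truth table, landmarks,
#' entry/target points, seed) to a directory; the DWI signal, if present,
#' is written as a 4-D NIfTI plus FSL-style bvec/bval.
#'
#' @param ph a [generate_phantom()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(ph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(ph$brain_mask, file.path(dir, "brain_mask.nii.gz"))
  for (h in names(ph$putamen_mask))
    write_volume(ph$putamen_mask[[h]],
                 file.path(dir, paste0("putamen_", h, ".nii.gz")))
  for (h in names(ph$roi_masks))
    for (r in names(ph$roi_masks[[h]]))
      write_volume(ph$roi_masks[[h]][[r]],
                   file.path(dir, paste0("roi_", r, "_", h, ".nii.gz")))
  for (cn in names(ph$critical_masks))
    write_volume(ph$critical_masks[[cn]],
                 file.path(dir, paste0("critical_", cn, ".nii.gz")))
  manifest <- list(truth = ph$truth, landmarks = ph$landmarks,
                   entries = ph$entries, seed = ph$spec$seed,
                   voxel_size_mm = ph$spec$voxel_size_mm)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(ph$dwi)) {
    img <- RNifti::asNifti(ph$dwi$signal)
    RNifti::pixdim(img) <- rep(ph$spec$voxel_size_mm, 3)
    aff <- phantom_affine(ph$spec)
    RNifti::qform(img) <- structure(aff, code = 2L)
    RNifti::sform(img) <- structure(aff, code = 2L)
    RNifti::writeNifti(img, file.path(dir, "dwi.nii.gz"))
    utils::write.table(t(ph$dwi$gradients), file.path(dir, "dwi.bvec"),
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(t(ph$dwi$bvals), file.path(dir, "dwi.bval"),
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
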