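#' Deterministic tracking criteria
#'
#' Stopping and retention rules for deterministic single-tensor streamline
#' tracking: minimum FA 0.2, minimum fiber length 20 mm, maximum per-step
#' angulation 50 degrees. Step size defaults to half the smallest voxel
#' dimension at the 2 mm protocol resolution.
#'
#' @param fa_min FA threshold below which a side of the track terminates.
#' @param length_min mm; shorter streamlines are discarded.
#' @param angle_max degrees; turning angle between successive steps above
#'   which the track terminates.
#' @param step_mm Euler integration step in mm.
#' @param max_steps per-direction step cap.
#' @param seeds_per_voxel seeds placed per segment voxel (at the center for
#'   1; jittered grids are not used by the default pipeline).
#' @return object of class `tracking_criteria`.
#' @export
tracking_criteria <- function(fa_min = 0.2, length_min = 20, angle_max = 50,
                              step_mm = 1.0, max_steps = 200,
                              seeds_per_voxel = 1L) {
  stopifnot(fa_min > 0, fa_min < 1, angle_max > 0, angle_max < 90,
            step_mm > 0, max_steps >= 1)
  structure(list(fa_min = fa_min, length_min = length_min,
                 angle_max = angle_max, step_mm = step_mm,
                 max_steps = max_steps, seeds_per_voxel = seeds_per_voxel),
            class = "tracking_criteria")
}

# interpolate the 6 tensor components at world points; returns n x 6 matrix
interp_tensor <- function(field, points, inv_affine = solve(field$affine)) {
  pts <- rbind2mat(points)
  idx <- pts %*% t(inv_affine[1:3, 1:3]) +
    matrix(inv_affine[1:3, 4], nrow(pts), 3, byrow = TRUE)
  vals <- trilinear_gather(field$comps, idx)
  do.call(cbind, vals)
}

# principal eigenvector + FA at one world point
principal_direction <- function(field, point, inv_affine) {
  t6 <- interp_tensor(field, point, inv_affine)[1, ]
  e <- eigen(tensor6_to_mat(t6), symmetric = TRUE)
  list(dir = e$vectors[, 1], fa = fa_from_eigenvalues(e$values[1],
                                                      e$values[2],
                                                      e$values[3]))
}

#' Trace one deterministic streamline
#'
#' Bidirectional fixed-step Euler integration from the seed along the
#' principal eigenvector of the trilinearly interpolated tensor, with the
#' eigenvector sign aligned to the incoming direction. A side terminates
#' when FA drops below `fa_min`, the turning angle between successive steps
#' exceeds `angle_max`, the point leaves the brain mask, or `max_steps` is
#' reached. The two half-tracks are concatenated; streamlines shorter than
#' `length_min` are discarded.
#'
#' @param field a [tensor_field()].
#' @param seed mm point inside the brain mask.
#' @param criteria a [tracking_criteria()].
#' @param brain binary `ced_volume` brain mask.
#' @return a `streamline` (list with `points` n x 3 mm matrix and `length`
#'   mm), or `NULL` if the track is discarded.
#' @export
track_streamline <- function(field, seed, criteria, brain) {
  seed <- as.numeric(seed)
  if (!points_in_mask(brain, matrix(seed, 1))) stop("seed outside brain mask")
  inv <- solve(field$affine)
  pd <- principal_direction(field, seed, inv)
  if (pd$fa < criteria$fa_min) return(NULL)
  cosmax <- cos(criteria$angle_max * pi / 180)
  half <- function(dir0) {
    pts <- matrix(NA_real_, criteria$max_steps, 3)
    p <- seed
    v <- dir0
    n <- 0L
    repeat {
      if (n >= criteria$max_steps) break
      pnew <- p + criteria$step_mm * v
      if (!points_in_mask(brain, matrix(pnew, 1))) break
      pdn <- principal_direction(field, pnew, inv)
      if (pdn$fa < criteria$fa_min) break
      n <- n + 1L
      pts[n, ] <- pnew
      vn <- pdn$dir
      if (sum(vn * v) < 0) vn <- -vn
      if (sum(vn * v) < cosmax) break  # turning angle exceeded
      p <- pnew
      v <- vn
    }
    pts[seq_len(n), , drop = FALSE]
  }
  fwd <- half(pd$dir)
  bwd <- half(-pd$dir)
  pts <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
               matrix(seed, 1), fwd)
  if (nrow(pts) < 2) return(NULL)
  seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                            pts[-nrow(pts), , drop = FALSE])^2))
  len <- sum(seglen)
  if (len < criteria$length_min) return(NULL)
  structure(list(points = pts, length = len), class = "streamline")
}

#' Seed and track from every voxel of a mask
#'
#' One seed per voxel center of the seed mask (the putamen segments in the
#' default pipeline). Tracking is deterministic: identical field and seeds
#' give identical streamlines.
#'
#' @param field a [tensor_field()].
#' @param seed_mask binary `ced_volume`; each voxel center seeds one track.
#' @param criteria a [tracking_criteria()].
#' @param brain binary `ced_volume` brain mask.
#' @return list of `streamline` objects (discarded seeds are dropped).
#' @export
track_from_mask <- function(field, seed_mask, criteria, brain) {
  stopifnot_same_grid(seed_mask, brain)
  w <- which(seed_mask$data > 0)
  if (length(w) == 0L) return(list())
  idx <- arrayInd(w, dim(seed_mask$data)) - 1
  seeds <- voxel_to_world(seed_mask, idx)
  out <- vector("list", nrow(seeds))
  k <- 0L
  for (i in seq_len(nrow(seeds))) {
    s <- track_streamline(field, seeds[i, ], criteria, brain)
    if (!is.null(s)) { k <- k + 1L; out[[k]] <- s }
  }
  out[seq_len(k)]
}

#' Is a connection present between an ROI and a putamen segment?
#'
#' A connection is considered present iff at least one retained streamline
#' has at least one point inside the ROI mask and at least one point inside
#' the segment mask (traversal semantics; endpoint-only mode available).
#'
#' @param streamlines list of `streamline` objects.
#' @param roi,segment binary `ced_volume` masks on a shared grid.
#' @param endpoints_only if `TRUE`, only streamline endpoints count as
#'   visiting the ROI.
#' @return logical scalar.
#' @export
connection_present <- function(streamlines, roi, segment,
                               endpoints_only = FALSE) {
  stopifnot_same_grid(roi, segment)
  for (s in streamlines) {
    pts <- s$points
    rpts <- if (endpoints_only) pts[c(1, nrow(pts)), , drop = FALSE] else pts
    if (any(points_in_mask(roi, rpts)) && any(points_in_mask(segment, pts)))
      return(TRUE)
  }
  FALSE
}

#' Cohort connection-presence counts
#'
#' Aggregates per-hemisphere boolean connection matrices (region x segment)
#' into a count matrix: each entry is the number of hemispheres in which the
#' connection is present, bounded by the number of contributed hemispheres
#' (0-40 for 20 subjects scanned bilaterally).
#'
#' @param hemisphere_matrices list of logical matrices with identical
#'   dimnames (regions x segments), one per hemisphere.
#' @return integer count matrix with the same dimnames.
#' @export
connectivity_counts <- function(hemisphere_matrices) {
  stopifnot(length(hemisphere_matrices) >= 1)
  ref <- hemisphere_matrices[[1]]
  for (m in hemisphere_matrices) {
    if (!identical(dimnames(m), dimnames(ref)) ||
        !identical(dim(m), dim(ref)))
      stop("inconsistent region/segment sets across hemispheres")
  }
  out <- Reduce(`+`, lapply(hemisphere_matrices, function(m) {
    storage.mode(m) <- "integer"; m
  }))
  out
}

#' Write streamlines in TCK format
#'
#' Minimal MRtrix TCK writer: mm coordinates, Float32LE triplets, tracks
#' separated by NaN triplets, file terminated by an Inf triplet.
#'
#' @param streamlines list of `streamline` objects.
#' @param path output `.tck` path.
#' @return `path`, invisibly.
#' @export
write_tck <- function(streamlines, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_fixed <- paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ",
                      length(streamlines), "\n")
  # file_offset field must include its own length; iterate to a fixed point
  off <- nchar(hdr_fixed) + nchar("file: . \nEND\n") + 4
  for (i in 1:3) off <- nchar(hdr_fixed) + nchar(sprintf("file: . %d\nEND\n", off))
  hdr <- paste0(hdr_fixed, sprintf("file: . %d\nEND\n", off))
  writeChar(hdr, con, eos = NULL)
  pad <- off - nchar(hdr)
  if (pad > 0) writeBin(raw(pad), con)
  for (s in streamlines) {
    writeBin(as.vector(t(s$points)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}
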