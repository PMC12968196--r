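#' Build an AC-PC anatomical frame
#'
#' Derives a right-handed orthonormal axis set from the anterior commissure
#' (AC), posterior commissure (PC) and a third, superior reference point
#' (e.g. an interhemispheric point above AC). Two landmarks fix only the
#' AC-PC line; the third is required to pin down the superior direction.
#'
#' Axes: `y_ap` points from PC toward AC (anterior-positive); `z_si` is the
#' superior reference direction orthogonalized against `y_ap`
#' (superior-positive); `x_lr = y_ap x z_si`.
#'
#' @param ac,pc,ih mm points (length-3 numeric): AC, PC and the superior
#'   reference point.
#' @return an object of class `acpc_frame` with fields `ac`, `pc`, `ih`,
#'   `y_ap`, `z_si`, `x_lr`.
#' @export
acpc_frame <- function(ac, pc, ih) {
  ac <- as.numeric(ac); pc <- as.numeric(pc); ih <- as.numeric(ih)
  stopifnot(length(ac) == 3, length(pc) == 3, length(ih) == 3)
  y <- ac - pc
  ny <- sqrt(sum(y^2))
  if (ny < 1e-9) stop("degenerate geometry: AC and PC coincide")
  y <- y / ny
  z <- ih - ac
  z <- z - sum(z * y) * y
  nz <- sqrt(sum(z^2))
  if (nz < 1e-9)
    stop("degenerate geometry: superior reference point lies on the AC-PC line")
  z <- z / nz
  x <- c(y[2] * z[3] - y[3] * z[2],
         y[3] * z[1] - y[1] * z[3],
         y[1] * z[2] - y[2] * z[1])
  structure(list(ac = ac, pc = pc, ih = ih, y_ap = y, z_si = z, x_lr = x),
            class = "acpc_frame")
}

#' @export
print.acpc_frame <- function(x, ...) {
  cat("<acpc_frame> AC", sprintf("(%.1f, %.1f, %.1f)", x$ac[1], x$ac[2], x$ac[3]),
      " PC", sprintf("(%.1f, %.1f, %.1f)", x$pc[1], x$pc[2], x$pc[3]), "\n")
  invisible(x)
}

#' Quadrant label codes
#'
#' Integer codes used throughout for the four putamen segments.
#' @export
SEGMENT_CODES <- c("superior-anterior" = 1L, "superior-posterior" = 2L,
                   "inferior-posterior" = 3L, "inferior-anterior" = 4L)

#' Parcellate a putamen mask into AC-PC quadrants
#'
#' Splits a putamen mask into four segments with two planes through the AC
#' point: the axial plane containing the AC-PC line (separating superior from
#' inferior) and the coronal plane perpendicular to it (separating anterior
#' from posterior). A voxel with center `p` is superior iff
#' `(p - ac) . z_si >= 0` and anterior iff `(p - ac) . y_ap >= 0`; boundary
#' voxels (dot product exactly zero) deterministically go to
#' superior / anterior. The four labels partition the mask exactly.
#'
#' @param putamen binary `ced_volume` putamen mask.
#' @param frame an [acpc_frame()].
#' @param hemisphere optional tag ("left"/"right") carried into the result.
#' @return an object of class `putamen_parcellation`: `labels` (a
#'   `ced_volume` with codes 1 superior-anterior, 2 superior-posterior,
#'   3 inferior-posterior, 4 inferior-anterior, 0 outside), `counts` (voxels
#'   per segment), `volumes_mm3`, `hemisphere`.
#' @export
parcellate_putamen <- function(putamen, frame, hemisphere = NA_character_) {
  stopifnot(inherits(putamen, "ced_volume"), inherits(frame, "acpc_frame"))
  if (!is_binary_volume(putamen)) stop("putamen mask must be binary")
  which_in <- which(putamen$data > 0)
  if (length(which_in) == 0L) stop("empty putamen mask")
  d <- dim(putamen$data)
  idx <- arrayInd(which_in, d) - 1  # 0-based
  p <- voxel_to_world(putamen, idx)
  rel <- p - matrix(frame$ac, nrow(p), 3, byrow = TRUE)
  sup <- rel %*% frame$z_si >= 0
  ant <- rel %*% frame$y_ap >= 0
  code <- integer(length(which_in))
  code[sup & ant]   <- 1L
  code[sup & !ant]  <- 2L
  code[!sup & !ant] <- 3L
  code[!sup & ant]  <- 4L
  lab <- array(0L, dim = d)
  lab[which_in] <- code
  counts <- vapply(1:4, function(k) sum(code == k), integer(1))
  names(counts) <- names(SEGMENT_CODES)
  vd <- unlist(voxel_dimensions(putamen$affine))
  structure(list(labels = volume(lab, putamen$affine),
                 counts = counts,
                 volumes_mm3 = counts * prod(vd),
                 hemisphere = hemisphere),
            class = "putamen_parcellation")
}

#' @export
print.putamen_parcellation <- function(x, ...) {
  cat("<putamen_parcellation>", if (!is.na(x$hemisphere)) x$hemisphere, "\n")
  print(data.frame(segment = names(x$counts), voxels = unname(x$counts),
                   mm3 = unname(x$volumes_mm3)))
  invisible(x)
}

#' Extract one segment of a parcellation as a binary mask
#'
#' @param parc a `putamen_parcellation`.
#' @param code segment code 1-4 or a name from [SEGMENT_CODES].
#' @return binary `ced_volume`.
#' @export
segment_mask <- function(parc, code) {
  if (is.character(code)) code <- SEGMENT_CODES[[code]]
  volume(array(as.integer(parc$labels$data == code),
               dim = dim(parc$labels$data)),
         parc$labels$affine)
}
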