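#' Sample a straight trajectory
#'
#' Linear interpolation from entry to target, divided into `n` equidistant
#' sample points including both endpoints (spacing
#' `||target - entry|| / (n - 1)`).
#'
#' @param entry,target mm points; must differ.
#' @param n number of sample points (default 100).
#' @return n x 3 matrix of mm points, first row = entry, last row = target.
#' @export
sample_trajectory <- function(entry, target, n = 100L) {
  entry <- as.numeric(entry); target <- as.numeric(target)
  if (sqrt(sum((target - entry)^2)) < 1e-12)
    stop("entry and target coincide")
  t <- seq(0, 1, length.out = n)
  outer(rep(1, n), entry) + outer(t, target - entry)
}

#' Build a trajectory object
#'
#' @param entry,target mm points.
#' @param approach "frontal" or "occipital".
#' @param hemisphere "left" or "right".
#' @param n number of sample points along the line.
#' @return object of class `trajectory` with `entry`, `target`, `approach`,
#'   `hemisphere`, `sample_points`, `spacing_mm`.
#' @export
trajectory <- function(entry, target, approach = c("frontal", "occipital"),
                       hemisphere = c("left", "right"), n = 100L) {
  approach <- match.arg(approach)
  hemisphere <- match.arg(hemisphere)
  pts <- sample_trajectory(entry, target, n)
  structure(list(entry = as.numeric(entry), target = as.numeric(target),
                 approach = approach, hemisphere = hemisphere,
                 sample_points = pts,
                 spacing_mm = sqrt(sum((as.numeric(target) -
                                          as.numeric(entry))^2)) / (n - 1)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", x$approach, x$hemisphere, ":",
      sprintf("(%.1f,%.1f,%.1f) -> (%.1f,%.1f,%.1f), %d points\n",
              x$entry[1], x$entry[2], x$entry[3],
              x$target[1], x$target[2], x$target[3], nrow(x$sample_points)))
  invisible(x)
}

#' Valid sphere centers along a trajectory
#'
#' The trajectory sample points whose containing voxel lies inside the
#' target segment mask, in path order. These are the only admissible
#' infusion-sphere centers. An empty result means the trajectory misses the
#' segment (reported distinctly from an unsafe trajectory).
#'
#' @param traj a [trajectory()].
#' @param segment binary `ced_volume`.
#' @return list with `centers` (m x 3 matrix, possibly 0-row) and
#'   `in_segment_length_mm` (path length between first and last valid
#'   sample).
#' @export
valid_centers <- function(traj, segment) {
  stopifnot(inherits(traj, "trajectory"))
  inside <- points_in_mask(segment, traj$sample_points)
  ctr <- traj$sample_points[inside, , drop = FALSE]
  len <- if (sum(inside) >= 2)
    (max(which(inside)) - min(which(inside))) * traj$spacing_mm else 0
  list(centers = ctr, in_segment_length_mm = len)
}

#' Safety configuration
#'
#' @param margin_mm minimum clearance in mm required between every
#'   trajectory sample point and every critical structure (default 2 mm).
#' @param critical_masks named list of binary `ced_volume`s (e.g.
#'   ventricles, vessels, sulci). May be empty.
#' @return object of class `safety_config`.
#' @export
safety_config <- function(margin_mm = 2.0, critical_masks = list()) {
  stopifnot(margin_mm >= 0)
  structure(list(margin_mm = margin_mm, critical_masks = critical_masks),
            class = "safety_config")
}

#' Classify trajectory safety against critical structures
#'
#' A trajectory is safe iff, for every critical structure, the minimum over
#' its sample points of the (trilinearly interpolated) distance-map value is
#' at least `margin_mm`. Safety is monotone in the margin: safe at margin m
#' implies safe at any smaller margin.
#'
#' @param traj a [trajectory()].
#' @param cfg a [safety_config()].
#' @param distance_maps named list of scalar `ced_volume`s from
#'   [distance_to_mask()], one per critical structure in `cfg`. Computed
#'   from `cfg$critical_masks` when omitted.
#' @return list with `safe` (logical), `min_distance_mm` (named vector per
#'   structure), `offending` (name of the closest violating structure or
#'   `NA`).
#' @export
classify_safety <- function(traj, cfg, distance_maps = NULL) {
  stopifnot(inherits(traj, "trajectory"), inherits(cfg, "safety_config"))
  nm <- names(cfg$critical_masks)
  if (is.null(distance_maps))
    distance_maps <- lapply(cfg$critical_masks, distance_to_mask)
  if (length(nm) == 0)
    return(list(safe = TRUE, min_distance_mm = numeric(0), offending = NA))
  if (!all(nm %in% names(distance_maps)))
    stop("missing distance map for: ",
         paste(setdiff(nm, names(distance_maps)), collapse = ", "))
  mins <- vapply(nm, function(s) {
    min(interpolate_volume(distance_maps[[s]], traj$sample_points))
  }, numeric(1))
  viol <- mins < cfg$margin_mm
  list(safe = !any(viol),
       min_distance_mm = mins,
       offending = if (any(viol)) nm[which.min(mins)] else NA)
}
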