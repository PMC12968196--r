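#' Voxelized sphere mask
#'
#' Binary mask of the voxels whose centers lie within `radius` mm of
#' `center` (voxel-wise Euclidean metric in world mm). Radius 0 yields the
#' single containing voxel.
#'
#' @param center mm point.
#' @param radius mm, non-negative.
#' @param grid a `ced_volume` defining shape and affine.
#' @return binary `ced_volume`.
#' @export
sphere_mask <- function(center, radius, grid) {
  stopifnot(radius >= 0)
  lin <- sphere_voxels(center, radius, grid)
  m <- array(0L, dim = dim(grid$data))
  m[lin] <- 1L
  volume(m, grid$affine)
}

# bounding-box scan shared by sphere_voxels / optimize_radius: linear
# (1-based) voxel indices in the box around `center` at `radius`, plus the
# squared mm distance of each voxel center to `center`
sphere_scan <- function(center, radius, grid) {
  d <- dim(grid$data)
  cv <- world_to_voxel(grid, as.numeric(center))
  vd <- unlist(voxel_dimensions(grid$affine))
  lo <- pmax(floor(cv - radius / vd - 1), 0)
  hi <- pmin(ceiling(cv + radius / vd + 1), d - 1)
  if (any(lo > hi)) return(list(lin = integer(0), d2 = numeric(0)))
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  A <- grid$affine
  offdiag <- A[1:3, 1:3]; diag(offdiag) <- 0
  ni <- length(ii); nj <- length(jj); nk <- length(kk)
  if (all(offdiag == 0)) {
    # axis-aligned grid: squared distance separates per axis
    dx2 <- (A[1, 1] * ii + A[1, 4] - center[1])^2
    dy2 <- (A[2, 2] * jj + A[2, 4] - center[2])^2
    dz2 <- (A[3, 3] * kk + A[3, 4] - center[3])^2
    d2 <- rep(dx2, times = nj * nk) +
      rep(rep(dy2, each = ni), times = nk) +
      rep(dz2, each = ni * nj)
    lin <- rep(ii, times = nj * nk) +
      d[1] * rep(rep(jj, each = ni), times = nk) +
      d[1] * d[2] * rep(kk, each = ni * nj) + 1
  } else {
    idx <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
    w <- voxel_to_world(grid, idx)
    d2 <- (w[, 1] - center[1])^2 + (w[, 2] - center[2])^2 +
      (w[, 3] - center[3])^2
    lin <- idx[, 1] + d[1] * idx[, 2] + d[1] * d[2] * idx[, 3] + 1
  }
  list(lin = lin, d2 = d2)
}

# linear (1-based) indices of voxels whose centers are within radius of
# center; radius 0 -> the single nearest voxel (if on the grid)
sphere_voxels <- function(center, radius, grid) {
  sc <- sphere_scan(center, radius, grid)
  if (length(sc$lin) == 0) return(integer(0))
  if (radius == 0) sc$lin[which.min(sc$d2)]
  else sc$lin[sc$d2 <= radius^2 + 1e-9]
}

#' Shrink a sphere radius until it fits inside an ROI
#'
#' Implements the containment penalty: the requested radius is reduced in
#' decrements of `step` until every voxel of the sphere mask lies inside the
#' allowed ROI. This is the mechanism by which plans whose spheres exceed
#' the anatomical boundary are penalized (their effective radius shrinks).
#'
#' @param center mm point; must lie inside `allowed_roi`.
#' @param requested_radius mm.
#' @param allowed_roi binary `ced_volume` the sphere must stay inside.
#' @param step shrink decrement in mm.
#' @return the largest radius `requested_radius - k * step` (k >= 0) whose
#'   voxel mask is contained in the ROI (possibly 0, covering only the
#'   center voxel).
#' @export
optimize_radius <- function(center, requested_radius, allowed_roi,
                            step = 0.5) {
  stopifnot(requested_radius >= 0, step > 0)
  if (!points_in_mask(allowed_roi, matrix(as.numeric(center), 1)))
    stop("sphere center outside the allowed ROI")
  # A sphere's voxel mask is contained in the ROI iff no outside-voxel
  # center lies within the radius, so one bounding-box scan at the
  # requested radius decides every candidate radius at once.
  sc <- sphere_scan(center, requested_radius, allowed_roi)
  if (length(sc$lin) == 0) return(0)
  inside <- allowed_roi$data[sc$lin] > 0
  d_near2 <- min(sc$d2)                    # sphere covers >= 1 voxel
  d_out2 <- if (any(!inside)) min(sc$d2[!inside]) else Inf
  r <- requested_radius - step * (0:floor(requested_radius / step))
  r <- r[r > 0]
  feasible <- (r^2 + 1e-9 >= d_near2) & (r^2 + 1e-9 < d_out2)
  if (any(feasible)) r[which(feasible)[1]] else 0
}

#' Coverage of a target segment by an injection plan
#'
#' Fraction of the segment's voxels inside the union of the plan's sphere
#' masks (overlap counted once).
#'
#' @param plan an `injection_plan` (see [optimize_injection()]) or a list
#'   with `centers` (k x 3) and `radii` (length k).
#' @param target_segment binary `ced_volume`.
#' @return fraction in `[0, 1]`.
#' @export
coverage <- function(plan, target_segment) {
  seg <- as.vector(target_segment$data) > 0
  nseg <- sum(seg)
  if (nseg == 0) stop("empty target segment")
  cov <- covered_voxels(plan, target_segment)
  sum(seg[cov]) / nseg
}

covered_voxels <- function(plan, grid) {
  lin <- integer(0)
  for (i in seq_along(plan$radii))
    lin <- c(lin, sphere_voxels(plan$centers[i, ], plan$radii[i], grid))
  unique(lin)
}

#' GA configuration for infusion optimization
#'
#' The generation count follows the published protocol (20); the remaining
#' hyperparameters are package defaults, all exposed here.
#'
#' @param generations number of GA generations.
#' @param population_size individuals per generation.
#' @param crossover_prob,mutation_prob operator probabilities per pair /
#'   individual.
#' @param tournament_size selection tournament size.
#' @param n_spheres_max maximum spheres per plan.
#' @param radius_step_mm radius granularity and shrink decrement.
#' @param radius_max_mm largest requestable sphere radius.
#' @param seed RNG seed for the whole run.
#' @return object of class `ga_config`.
#' @export
ga_config <- function(generations = 20L, population_size = 50L,
                      crossover_prob = 0.7, mutation_prob = 0.3,
                      tournament_size = 3L, n_spheres_max = 4L,
                      radius_step_mm = 0.5, radius_max_mm = 6,
                      seed = 1L) {
  stopifnot(generations >= 1, population_size >= 2,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            n_spheres_max >= 1, radius_step_mm > 0, radius_max_mm > 0)
  structure(list(generations = as.integer(generations),
                 population_size = as.integer(population_size),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 tournament_size = as.integer(tournament_size),
                 n_spheres_max = as.integer(n_spheres_max),
                 radius_step_mm = radius_step_mm,
                 radius_max_mm = radius_max_mm,
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Mutate an injection plan
#'
#' Replaces the center of exactly one uniformly chosen sphere with a
#' uniformly drawn valid center; radii and sphere count are unchanged
#' (radii are re-optimized for containment at evaluation time).
#'
#' @param plan list with `centers`, `radii`.
#' @param valid_centers m x 3 matrix of admissible centers (m >= 1).
#' @return mutated plan.
#' @export
mutate_plan <- function(plan, valid_centers) {
  if (nrow(valid_centers) == 0) stop("no valid centers to mutate toward")
  k <- length(plan$radii)
  i <- if (k == 1) 1L else sample.int(k, 1)
  j <- sample.int(nrow(valid_centers), 1)
  plan$centers[i, ] <- valid_centers[j, ]
  plan
}

#' One-point crossover of two injection plans
#'
#' Cuts each parent's sphere list at an independently chosen random
#' position and exchanges the tails, so sphere counts can change while the
#' combined multiset of spheres is conserved across the pair. Cut positions
#' are redrawn (bounded) if an offspring would be empty or exceed the
#' sphere cap.
#'
#' @param a,b parent plans.
#' @param n_max maximum spheres per offspring.
#' @return list of two offspring plans.
#' @export
crossover_plans <- function(a, b, n_max = 4L) {
  la <- length(a$radii); lb <- length(b$radii)
  ok <- FALSE
  for (attempt in 1:20) {
    ca <- sample.int(la + 1L, 1) - 1L  # 0..la
    cb <- sample.int(lb + 1L, 1) - 1L
    n1 <- ca + (lb - cb); n2 <- cb + (la - ca)
    if (n1 >= 1 && n2 >= 1 && n1 <= n_max && n2 <= n_max) { ok <- TRUE; break }
  }
  if (!ok) { ca <- 0L; cb <- 0L }  # always admissible: swapped copies
  take <- function(p, idx) list(centers = p$centers[idx, , drop = FALSE],
                                radii = p$radii[idx])
  cat2 <- function(p, q) list(centers = rbind(p$centers, q$centers),
                              radii = c(p$radii, q$radii))
  o1 <- cat2(take(a, seq_len(ca)), take(b, setdiff(seq_len(lb), seq_len(cb))))
  o2 <- cat2(take(b, seq_len(cb)), take(a, setdiff(seq_len(la), seq_len(ca))))
  list(o1, o2)
}

# evaluate a plan: shrink radii for containment, then score coverage
evaluate_plan <- function(plan, target_segment, allowed_roi, step) {
  k <- length(plan$radii)
  radii_eff <- numeric(k)
  for (i in seq_len(k))
    radii_eff[i] <- optimize_radius(plan$centers[i, ], plan$radii[i],
                                    allowed_roi, step)
  eff <- list(centers = plan$centers, radii = radii_eff)
  list(fitness = coverage(eff, target_segment), effective = eff)
}

#' Optimize an infusion plan with a genetic algorithm
#'
#' Evolves variable-length plans (1 to `n_spheres_max` spheres, centers
#' drawn from the trajectory's valid centers, radii on a discrete grid) by
#' tournament selection, one-point crossover and center mutation, with
#' elitism (the best-so-far individual is never lost, so the
#' per-generation best fitness is non-decreasing). Fitness is the target
#' coverage after per-sphere containment shrinking. Fully reproducible
#' given `cfg$seed`.
#'
#' @param valid_centers m x 3 matrix of admissible sphere centers (m >= 1);
#'   see [valid_centers()].
#' @param target_segment binary `ced_volume` whose coverage is maximized.
#' @param allowed_roi binary `ced_volume` the spheres must stay inside.
#'   Defaults to the target segment (conservative containment); pass a
#'   brain mask for the looser whole-brain containment mode.
#' @param cfg a [ga_config()].
#' @return object of class `injection_plan`: `centers`, `radii` (effective,
#'   post-containment), `requested_radii`, `coverage`,
#'   `sphere_volumes_mm3` (analytic 4/3 pi r^3), `fitness_log`
#'   (per-generation best), `coverage_mask` (binary `ced_volume`), or a
#'   `no_feasible_plan` condition when `valid_centers` is empty.
#' @export
optimize_injection <- function(valid_centers, target_segment,
                               allowed_roi = target_segment,
                               cfg = ga_config()) {
  if (is.list(valid_centers) && !is.null(valid_centers$centers))
    valid_centers <- valid_centers$centers
  if (is.null(dim(valid_centers)) || nrow(valid_centers) == 0)
    stop(structure(class = c("no_feasible_plan", "error", "condition"),
                   list(message = "no valid centers: trajectory does not enter the target segment",
                        call = sys.call())))
  stopifnot_same_grid(target_segment, allowed_roi)
  rs <- local_rng(cfg$seed)
  on.exit(restore_rng(rs))
  radius_levels <- seq(cfg$radius_step_mm, cfg$radius_max_mm,
                       by = cfg$radius_step_mm)
  random_plan <- function() {
    k <- sample.int(cfg$n_spheres_max, 1)
    list(centers = valid_centers[sample.int(nrow(valid_centers), k,
                                            replace = TRUE), , drop = FALSE],
         radii = sample(radius_levels, k, replace = TRUE))
  }
  pop <- replicate(cfg$population_size, random_plan(), simplify = FALSE)
  evals <- lapply(pop, evaluate_plan, target_segment = target_segment,
                  allowed_roi = allowed_roi, step = cfg$radius_step_mm)
  fit <- vapply(evals, `[[`, numeric(1), "fitness")
  best_i <- which.max(fit)
  best <- list(plan = pop[[best_i]], eval = evals[[best_i]])
  log <- numeric(cfg$generations + 1L)
  log[1] <- best$eval$fitness
  tournament <- function() {
    cand <- sample.int(cfg$population_size, cfg$tournament_size,
                       replace = TRUE)
    pop[[cand[which.max(fit[cand])]]]
  }
  for (gen in seq_len(cfg$generations)) {
    newpop <- vector("list", cfg$population_size)
    newpop[[1]] <- best$plan  # elitism
    i <- 2L
    while (i <= cfg$population_size) {
      p1 <- tournament()
      if (i < cfg$population_size && stats::runif(1) < cfg$crossover_prob) {
        p2 <- tournament()
        off <- crossover_plans(p1, p2, cfg$n_spheres_max)
        newpop[[i]] <- off[[1]]; newpop[[i + 1L]] <- off[[2]]
        i <- i + 2L
      } else {
        newpop[[i]] <- p1
        i <- i + 1L
      }
    }
    for (j in 2:cfg$population_size)
      if (stats::runif(1) < cfg$mutation_prob)
        newpop[[j]] <- mutate_plan(newpop[[j]], valid_centers)
    pop <- newpop
    evals <- lapply(pop, evaluate_plan, target_segment = target_segment,
                    allowed_roi = allowed_roi, step = cfg$radius_step_mm)
    fit <- vapply(evals, `[[`, numeric(1), "fitness")
    bi <- which.max(fit)
    if (fit[bi] > best$eval$fitness)
      best <- list(plan = pop[[bi]], eval = evals[[bi]])
    log[gen + 1L] <- best$eval$fitness
  }
  eff <- best$eval$effective
  covm <- array(0L, dim = dim(target_segment$data))
  covm[covered_voxels(eff, target_segment)] <- 1L
  structure(list(centers = eff$centers,
                 radii = eff$radii,
                 requested_radii = best$plan$radii,
                 coverage = best$eval$fitness,
                 sphere_volumes_mm3 = 4 / 3 * pi * eff$radii^3,
                 fitness_log = log,
                 coverage_mask = volume(covm, target_segment$affine)),
            class = "injection_plan")
}

#' @export
print.injection_plan <- function(x, ...) {
  cat("<injection_plan> ", length(x$radii), " sphere(s), coverage ",
      sprintf("%.2f%%", 100 * x$coverage), "\n", sep = "")
  invisible(x)
}

#' Exhaustively enumerate injection plans (oracle)
#'
#' Brute-force search over every combination of sphere count, centers and
#' radius levels, evaluated with the same containment-then-coverage rule as
#' the GA. Exponential; intended for small instances as an independent
#' optimality check.
#'
#' @inheritParams optimize_injection
#' @param n_spheres_max maximum sphere count to enumerate.
#' @param radius_levels vector of requestable radii (mm).
#' @param radius_step_mm containment shrink decrement.
#' @return list with `coverage` (the global optimum) and `plan`.
#' @export
enumerate_injection_optimum <- function(valid_centers, target_segment,
                                        allowed_roi = target_segment,
                                        n_spheres_max = 2L,
                                        radius_levels = c(1, 2, 3),
                                        radius_step_mm = 0.5) {
  if (is.list(valid_centers) && !is.null(valid_centers$centers))
    valid_centers <- valid_centers$centers
  m <- nrow(valid_centers)
  best <- list(coverage = -1, plan = NULL)
  for (k in seq_len(n_spheres_max)) {
    ctr_idx <- as.matrix(expand.grid(rep(list(seq_len(m)), k)))
    rad_idx <- as.matrix(expand.grid(rep(list(seq_along(radius_levels)), k)))
    for (ci in seq_len(nrow(ctr_idx))) for (ri in seq_len(nrow(rad_idx))) {
      plan <- list(centers = valid_centers[ctr_idx[ci, ], , drop = FALSE],
                   radii = radius_levels[rad_idx[ri, ]])
      ev <- evaluate_plan(plan, target_segment, allowed_roi, radius_step_mm)
      if (ev$fitness > best$coverage)
        best <- list(coverage = ev$fitness, plan = ev$effective)
    }
  }
  best
}
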