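unit_grid <- function(n = 16) volume(array(0L, dim = rep(n, 3)), diag(4))

test_that("sphere masks match a brute-force distance scan", {
  g <- unit_grid(16)
  ctr <- c(7.3, 8.1, 6.9)
  m0 <- sphere_mask(ctr, 0, g)
  expect_equal(sum(m0$data), 1)
  m5 <- sphere_mask(ctr, 5, g)
  # exhaustive scan over every voxel of the grid
  idx <- as.matrix(expand.grid(i = 0:15, j = 0:15, k = 0:15))
  d2 <- rowSums(sweep(idx, 2, ctr)^2)
  expect_equal(sum(m5$data), sum(d2 <= 25 + 1e-9))
  expect_equal(which(m5$data > 0),
               which(array(d2 <= 25 + 1e-9, dim = rep(16, 3))))
  # reflection symmetry through the grid's central point (7.5 on 0..15)
  ms <- sphere_mask(c(7.5, 7.5, 7.5), 4.2, g)$data
  expect_identical(ms, ms[16:1, , ])
  expect_identical(ms, ms[, 16:1, ])
})

test_that("sphere masks honor anisotropic and rotated grids", {
  aff <- diag(c(1, 2, 2, 1))
  g <- volume(array(0L, dim = c(20, 10, 10)), aff)
  m <- sphere_mask(c(10, 10, 10), 3, g)
  w <- voxel_to_world(g, arrayInd(which(m$data > 0), dim(m$data)) - 1)
  expect_true(all(rowSums(sweep(w, 2, c(10, 10, 10))^2) <= 9 + 1e-6))
  # rotated affine falls back to the generic scan and agrees in world space
  R <- diag(4); th <- pi / 6
  R[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  gr <- volume(array(0L, dim = c(20, 20, 20)), R)
  mr <- sphere_mask(c(8, 8, 8), 4, gr)
  wr <- voxel_to_world(gr, arrayInd(which(mr$data > 0), dim(mr$data)) - 1)
  expect_true(all(rowSums(sweep(wr, 2, c(8, 8, 8))^2) <= 16 + 1e-6))
  # completeness: no in-radius voxel missed
  allw <- voxel_to_world(gr, as.matrix(expand.grid(0:19, 0:19, 0:19)))
  expect_equal(sum(mr$data),
               sum(rowSums(sweep(allw, 2, c(8, 8, 8))^2) <= 16 + 1e-9))
})

test_that("radius optimization shrinks to the anatomical boundary", {
  g <- unit_grid(24)
  roi <- ellipsoid_mask(g, c(12, 12, 12), c(9, 9, 9))
  # deep center, small request: returned unchanged
  expect_equal(optimize_radius(c(12, 12, 12), 2, roi), 2)
  # center 3 mm inside the boundary, request 10: the result is bounded by
  # the distance to the nearest outside voxel center (EDT of complement)
  ctr <- c(18, 12, 12)
  r <- optimize_radius(ctr, 10, roi, step = 0.5)
  comp <- volume(array(as.integer(roi$data == 0), dim = dim(roi$data)),
                 roi$affine)
  d_out <- distance_to_mask(comp)$data[19, 13, 13]
  expect_lte(r, d_out)
  # independent voxel-by-voxel containment audit
  inside <- which(sphere_mask(ctr, r, g)$data > 0)
  expect_true(all(roi$data[inside] > 0))
  # one step larger violates containment (r is maximal on the step grid)
  bigger <- which(sphere_mask(ctr, r + 0.5, g)$data > 0)
  expect_false(all(roi$data[bigger] > 0))
  # single-voxel ROI: shrinks until only the center voxel is covered
  solo <- volume(array(0L, dim = rep(8, 3)), diag(4))
  solo$data[4, 4, 4] <- 1L
  rs <- optimize_radius(c(3, 3, 3), 5, solo)
  expect_lt(rs, 1)  # next voxel center is 1 mm away
  expect_equal(which(sphere_mask(c(3, 3, 3), rs, solo)$data > 0),
               which(solo$data > 0))
  expect_error(optimize_radius(c(0, 0, 0), 1, solo), "outside")
})

test_that("coverage counts the union overlap once", {
  g <- unit_grid(12)
  seg <- volume(array(0L, dim = rep(12, 3)), diag(4))
  seg$data[3:10, 3:10, 3:10] <- 1L  # 8^3 block
  big <- list(centers = matrix(c(6.5, 6.5, 6.5), 1), radii = 12)
  expect_equal(coverage(big, seg), 1.0)
  one <- list(centers = matrix(c(6, 6, 6), 1), radii = 2)
  two <- list(centers = matrix(c(6, 6, 6, 6, 6, 6), 2, byrow = TRUE),
              radii = c(2, 2))
  expect_equal(coverage(two, seg), coverage(one, seg))
  # brute-force voxel count for the radius-2 sphere
  idx <- as.matrix(expand.grid(i = 0:11, j = 0:11, k = 0:11))
  d2 <- rowSums(sweep(idx, 2, c(6, 6, 6))^2)
  want <- sum(d2 <= 4 + 1e-9 & as.vector(seg$data) > 0) / sum(seg$data)
  expect_equal(coverage(one, seg), want)
  # union monotonicity: adding a sphere never decreases coverage
  three <- list(centers = rbind(two$centers, c(9, 9, 9)),
                radii = c(two$radii, 1.5))
  expect_gte(coverage(three, seg), coverage(two, seg))
  expect_error(coverage(one, volume(array(0L, dim = rep(12, 3)), diag(4))),
               "empty")
})

test_that("mutation replaces exactly one center, uniformly", {
  vc <- matrix(c(1, 1, 1, 2, 2, 2, 3, 3, 3, 4, 4, 4), 4, 3, byrow = TRUE)
  plan <- list(centers = vc[c(1, 2), ], radii = c(2, 3))
  set.seed(50)
  for (i in 1:50) {
    m <- mutate_plan(plan, vc)
    expect_equal(m$radii, plan$radii)
    changed <- rowSums(m$centers != plan$centers) > 0
    expect_lte(sum(changed), 1)
  }
  # single sphere, single valid center: plan unchanged
  p1 <- list(centers = vc[1, , drop = FALSE], radii = 2)
  expect_equal(mutate_plan(p1, vc[1, , drop = FALSE]), p1)
  # frequency test: each of 4 centers drawn uniformly
  draws <- integer(4)
  for (i in 1:10000) {
    m <- mutate_plan(p1, vc)
    draws[m$centers[1, 1]] <- draws[m$centers[1, 1]] + 1L
  }
  expect_gt(chisq.test(draws)$p.value, 0.001)
  expect_error(mutate_plan(p1, vc[0, , drop = FALSE]), "no valid centers")
})

test_that("crossover conserves the combined sphere multiset", {
  set.seed(51)
  key <- function(p) sort(paste(p$centers[, 1], p$centers[, 2],
                                p$centers[, 3], p$radii))
  for (i in 1:100) {
    la <- sample(1:4, 1); lb <- sample(1:4, 1)
    a <- list(centers = matrix(runif(3 * la), la, 3), radii = runif(la))
    b <- list(centers = matrix(runif(3 * lb), lb, 3), radii = runif(lb))
    off <- crossover_plans(a, b, n_max = 4L)
    expect_gte(length(off[[1]]$radii), 1)
    expect_lte(length(off[[1]]$radii), 4)
    expect_equal(sort(c(key(off[[1]]), key(off[[2]]))),
                 sort(c(key(a), key(b))))
  }
  # identical parents produce identical offspring
  off <- crossover_plans(a, a, n_max = 4L)
  expect_equal(key(off[[1]]), key(a))
  expect_equal(key(off[[2]]), key(a))
})

test_that("the GA never beats and usually matches exhaustive search", {
  hits <- 0L
  for (k in 1:6) {
    inst <- ga_instance(100 + k)
    cfg <- ga_config(generations = 20, population_size = 30,
                     n_spheres_max = 2, radius_step_mm = 1, radius_max_mm = 3,
                     seed = 200 + k)
    got <- optimize_injection(inst$vc, inst$seg, inst$seg, cfg)
    opt <- enumerate_injection_optimum(inst$vc, inst$seg, inst$seg,
                                       n_spheres_max = 2,
                                       radius_levels = c(1, 2, 3),
                                       radius_step_mm = 1)
    expect_lte(got$coverage, opt$coverage + 1e-12)
    if (abs(got$coverage - opt$coverage) < 1e-12) hits <- hits + 1L
  }
  expect_gte(hits, 5L)
})

test_that("GA runs are elitist, reproducible and containment-audited", {
  inst <- ga_instance(77)
  cfg <- ga_config(generations = 10, population_size = 20,
                   n_spheres_max = 2, radius_step_mm = 1, radius_max_mm = 3,
                   seed = 5)
  a <- optimize_injection(inst$vc, inst$seg, inst$seg, cfg)
  b <- optimize_injection(inst$vc, inst$seg, inst$seg, cfg)
  expect_identical(a[c("centers", "radii", "coverage", "fitness_log")],
                   b[c("centers", "radii", "coverage", "fitness_log")])
  expect_true(all(diff(a$fitness_log) >= 0))  # elitism
  expect_gte(a$coverage, 0); expect_lte(a$coverage, 1)
  # independent containment audit of the returned spheres
  for (i in seq_along(a$radii)) {
    vox <- which(sphere_mask(a$centers[i, ], a$radii[i], inst$seg)$data > 0)
    expect_true(all(inst$seg$data[vox] > 0))
  }
  # coverage mask voxel count consistent with the reported fraction
  expect_equal(sum(a$coverage_mask$data * (inst$seg$data > 0)) /
                 sum(inst$seg$data), a$coverage)
})

test_that("single-center single-sphere search space is solved exactly", {
  g <- unit_grid(12)
  seg <- volume(array(0L, dim = rep(12, 3)), diag(4))
  seg$data[4:9, 4:9, 4:9] <- 1L
  vc <- matrix(c(6, 6, 6), 1)
  cfg <- ga_config(generations = 5, population_size = 10, n_spheres_max = 1,
                   radius_step_mm = 1, radius_max_mm = 3, seed = 3)
  got <- optimize_injection(vc, seg, seg, cfg)
  opt <- enumerate_injection_optimum(vc, seg, seg, n_spheres_max = 1,
                                     radius_levels = c(1, 2, 3),
                                     radius_step_mm = 1)
  expect_equal(got$coverage, opt$coverage)
})

test_that("an empty valid-center set is a distinct failure", {
  g <- unit_grid(8)
  seg <- volume(array(1L, dim = rep(8, 3)), diag(4))
  expect_error(optimize_injection(matrix(0, 0, 3), seg, seg, ga_config()),
               class = "no_feasible_plan")
})
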