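all_ones_brain <- function(shape, affine = diag(4))
  volume(array(1L, dim = shape), affine)

test_that("a straight planted tube yields a straight retained streamline", {
  sh <- c(70, 20, 20)
  field <- make_line_field(sh, list(list(p0 = c(5, 10, 10),
                                         p1 = c(64, 10, 10))))
  brain <- all_ones_brain(sh)
  s <- track_streamline(field, c(35, 10, 10), tracking_criteria(), brain)
  expect_false(is.null(s))
  expect_gte(s$length, 40)
  # straightness: points stay within the tube axis
  expect_lt(max(abs(s$points[, 2] - 10)), 1)
  expect_lt(max(abs(s$points[, 3] - 10)), 1)
  # length equals the sum of inter-point distances
  seg <- diff(s$points)
  expect_equal(s$length, sum(sqrt(rowSums(seg^2))), tolerance = 1e-9)
  # consecutive spacing never exceeds the step
  expect_lte(max(sqrt(rowSums(seg^2))), tracking_criteria()$step_mm + 1e-9)
})

test_that("seeds in near-isotropic background are discarded immediately", {
  sh <- c(20, 20, 20)
  field <- make_line_field(sh, list())  # background only, FA ~ 0.05
  brain <- all_ones_brain(sh)
  expect_null(track_streamline(field, c(10, 10, 10), tracking_criteria(),
                               brain))
})

test_that("tracking terminates at a 90-degree elbow", {
  sh <- c(30, 40, 20)
  field <- make_line_field(sh, list(
    list(p0 = c(3, 10, 10), p1 = c(25, 10, 10)),
    list(p0 = c(25, 10, 10), p1 = c(25, 36, 10))))
  brain <- all_ones_brain(sh)
  s <- track_streamline(field, c(10, 10, 10), tracking_criteria(), brain)
  expect_false(is.null(s))
  # the streamline must not turn the corner: it stays on the x-arm,
  # never proceeding up the y-arm beyond the elbow blend region
  expect_lt(max(s$points[, 2]), 10 + 2 * 2.5 + 1)
  expect_gt(max(s$points[, 1]), 20)
})

test_that("tracking stops at the brain mask boundary", {
  sh <- c(40, 16, 16)
  field <- make_line_field(sh, list(list(p0 = c(2, 8, 8),
                                         p1 = c(38, 8, 8))))
  brain <- all_ones_brain(sh)
  brain$data[26:40, , ] <- 0L
  s <- track_streamline(field, c(10, 8, 8), tracking_criteria(), brain)
  expect_false(is.null(s))
  expect_lt(max(s$points[, 1]), 26)
  expect_error(track_streamline(field, c(30, 8, 8), tracking_criteria(),
                                brain), "outside brain")
})

test_that("tracking is deterministic and honors the length threshold", {
  ph <- cached_phantom()
  frame <- cached_frame()
  parc <- parcellate_putamen(ph$putamen_mask$right, frame, "right")
  seg <- segment_mask(parc, "superior-posterior")
  crit <- tracking_criteria()
  a <- track_from_mask(ph$tensor_field, seg, crit, ph$brain_mask)
  b <- track_from_mask(ph$tensor_field, seg, crit, ph$brain_mask)
  expect_identical(a, b)
  expect_gt(length(a), 0)
  for (s in a) expect_gte(s$length, crit$length_min)
})

test_that("connection presence requires traversal of both masks", {
  ph <- cached_phantom()
  frame <- cached_frame()
  parc <- parcellate_putamen(ph$putamen_mask$right, frame, "right")
  seg_sp <- segment_mask(parc, "superior-posterior")
  seg_ia <- segment_mask(parc, "inferior-anterior")
  streams <- track_from_mask(ph$tensor_field, seg_sp, tracking_criteria(),
                             ph$brain_mask)
  expect_true(connection_present(streams, ph$roi_masks$right$SMA, seg_sp))
  # same streamlines touch the SMA ROI but not the inferior-anterior segment
  expect_false(connection_present(streams, ph$roi_masks$right$SMA, seg_ia))
  expect_false(connection_present(streams, ph$roi_masks$right$amygdala,
                                  seg_sp))
  expect_false(connection_present(list(), ph$roi_masks$right$SMA, seg_sp))
})

test_that("connectivity counts aggregate hemispheres with bounds", {
  rn <- c("SMA", "amygdala"); sn <- names(SEGMENT_CODES)
  all_on <- matrix(TRUE, 2, 4, dimnames = list(rn, sn))
  all_off <- matrix(FALSE, 2, 4, dimnames = list(rn, sn))
  n <- 20
  expect_true(all(connectivity_counts(rep(list(all_on), 2 * n)) == 2 * n))
  expect_true(all(connectivity_counts(rep(list(all_off), 2 * n)) == 0))
  half <- all_off; half["SMA", "superior-posterior"] <- TRUE
  cnt <- connectivity_counts(c(rep(list(all_on), n), rep(list(half), n)))
  expect_equal(unname(cnt["SMA", "superior-posterior"]), 2 * n)
  expect_equal(unname(cnt["amygdala", "inferior-posterior"]), n)
  bad <- matrix(TRUE, 2, 4, dimnames = list(c("SMA", "insula"), sn))
  expect_error(connectivity_counts(list(all_on, bad)), "inconsistent")
})

test_that("tracking criteria validate their ranges", {
  expect_error(tracking_criteria(fa_min = 0), NULL)
  expect_error(tracking_criteria(angle_max = 95), NULL)
  expect_error(tracking_criteria(step_mm = -1), NULL)
})

test_that("TCK export writes a parseable header with the track count", {
  sh <- c(70, 20, 20)
  field <- make_line_field(sh, list(list(p0 = c(5, 10, 10),
                                         p1 = c(64, 10, 10))))
  s <- track_streamline(field, c(35, 10, 10), tracking_criteria(),
                        all_ones_brain(sh))
  f <- tempfile(fileext = ".tck")
  write_tck(list(s, s), f)
  hdr <- readLines(f, n = 3, warn = FALSE)
  expect_equal(hdr[1], "mrtrix tracks")
  expect_true(any(grepl("count: 2", hdr)))
})
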