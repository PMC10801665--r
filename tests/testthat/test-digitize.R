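# build a mask volume containing vertical tubes at given in-plane (mm)
# centres, one voxel wide
tube_mask <- function(centres, d = c(24, 24, 8), sp = c(0.8, 0.8, 5)) {
  arr <- array(0, dim = d)
  for (cc in centres) {
    i <- round(cc[1] / sp[1]) + 1
    j <- round(cc[2] / sp[2]) + 1
    arr[i, j, ] <- 1
    arr[i + 1, j, ] <- 1
  }
  volume3d(arr, spacing = sp, origin = c(0, 0, 0))
}

test_that("connected-component labeling separates and filters needles", {
  two <- tube_mask(list(c(4, 4), c(14, 14)))
  lab <- label_needles(two)
  expect_equal(attr(lab, "n_labels"), 2)

  empty <- volume3d(array(0, dim = c(8, 8, 8)))
  expect_warning(lab0 <- label_needles(empty), "empty")
  expect_equal(attr(lab0, "n_labels"), 0)

  # speckles below min_voxels are discarded
  sp <- tube_mask(list(c(4, 4)))
  sp$data[20, 20, 3] <- 1
  expect_equal(attr(label_needles(sp, min_voxels = 5), "n_labels"), 1)

  # phantom ground truth: labels match GT instances up to permutation
  ph <- make_phantom(phantom_config(seed = 31, min_separation_mm = 4))
  lab4 <- label_needles(binary_mask_volume(ph$truth))
  expect_equal(attr(lab4, "n_labels"), 4)
  overlap_label <- vapply(1:4, function(n) {
    found <- lab4$data[ph$truth$instance_mask$data == n]
    as.integer(names(sort(table(found), decreasing = TRUE))[1])
  }, 1L)
  expect_setequal(overlap_label, 1:4)
})

test_that("centerline extraction returns per-slice centroids in world mm", {
  m <- tube_mask(list(c(4, 4)))
  lab <- label_needles(m)
  pts <- extract_centerline(lab, 1)
  expect_equal(nrow(pts), 8)
  expect_equal(unname(pts[, 1]), rep(4.4, 8))  # centroid of the 2-voxel pair
  expect_equal(unname(pts[, 2]), rep(4.0, 8))
  expect_equal(unname(pts[, 3]), seq(0, 35, by = 5))
  expect_false(attr(pts, "flagged"))

  thin <- volume3d(array(0, dim = c(8, 8, 4)))
  thin$data[4, 4, 2] <- 1
  expect_error(extract_centerline(label_needles(thin, min_voxels = 1), 1),
               "< 2 slices")
})

test_that("merged touching needles trip the jump flag", {
  # an L-shaped component: column at x=4 mm for lower slices, a connecting
  # bar on slice 4, then a column at x=12 mm above - centroid jumps ~4 mm
  arr <- array(0, dim = c(24, 24, 8))
  arr[6, 6, 1:4] <- 1
  arr[6:16, 6, 4] <- 1
  arr[16, 6, 5:8] <- 1
  m <- volume3d(arr, spacing = c(0.8, 0.8, 5), origin = c(0, 0, 0))
  lab <- label_needles(m)
  expect_equal(attr(lab, "n_labels"), 1)
  expect_warning(pts <- extract_centerline(lab, 1), "flagged")
  expect_true(attr(pts, "flagged"))
  tr <- fit_trajectory(pts)
  expect_true(tr$flagged)
})

test_that("polynomial fits reproduce, smooth, and measure length", {
  z <- seq(0, 35, by = 5)
  x <- 2 + 0.05 * z + 0.002 * z^2
  y <- 10 - 0.03 * z
  tr <- fit_trajectory(cbind(x, y, z), degree = 3)
  expect_lt(max(abs(tr$points[, 1] - x)), 1e-9)
  expect_lt(max(abs(tr$points[, 2] - y)), 1e-9)

  straight <- fit_trajectory(cbind(1, 2, seq(50, 100, by = 5)), degree = 3)
  expect_equal(straight$length_mm, 50, tolerance = 1e-9)
  expect_equal(unname(straight$tip), c(1, 2, 100), tolerance = 1e-9)

  # refitting its own output changes nothing
  tr2 <- fit_trajectory(tr$points, degree = 3)
  expect_lt(max(abs(tr2$poly_x - tr$poly_x)), 1e-9)
  expect_lt(max(abs(tr2$poly_y - tr$poly_y)), 1e-9)

  expect_error(fit_trajectory(cbind(1, 2, c(5, 5, 5))), "one slice")
  expect_warning(fit_trajectory(cbind(1:3, 1:3, c(0, 5, 10)), degree = 3),
                 "degree lowered")
})

test_that("fitting suppresses centroid noise toward the true curve", {
  z <- seq(0, 75, by = 5)
  true_xy <- cbind(20 + 0.06 * z + 0.0015 * z^2, 25 - 0.04 * z)
  set.seed(99)
  rms_raw <- rms_fit <- numeric(100)
  for (i in 1:100) {
    noisy <- true_xy + matrix(rnorm(2 * length(z), sd = 0.3), ncol = 2)
    tr <- fit_trajectory(cbind(noisy, z), degree = 3)
    rms_raw[i] <- sqrt(mean((noisy - true_xy)^2))
    rms_fit[i] <- sqrt(mean((tr$points[, 1:2] - true_xy)^2))
  }
  expect_lt(mean(rms_fit), mean(rms_raw))
})

test_that("dwell positions walk the curve from the tip at fixed arc steps", {
  tr <- straight_traj(0, 0, 50, 100)
  dw <- sample_dwells(tr, step_mm = 2.5, offset_mm = 0, n_dwells = 3)
  expect_equal(unname(dw$positions[, 3]), c(100, 97.5, 95), tolerance = 1e-3)
  one <- sample_dwells(tr, step_mm = 2.5, offset_mm = 0, n_dwells = 1)
  expect_equal(unname(one$positions[1, ]), unname(tr$tip), tolerance = 1e-3)
  expect_error(sample_dwells(tr, step_mm = 2.5, n_dwells = 100), "too short")

  # curved needle: consecutive arc separations within 1% of the step
  ph <- make_phantom(phantom_config(seed = 41, curvature = 3))
  trc <- ph$truth$centerlines[[1]]
  dwc <- sample_dwells(trc, step_mm = 2.5, offset_mm = 1, n_dwells = 10)
  tab <- needletrace:::arc_table(trc)
  s_at <- approx(tab$z, tab$s, xout = dwc$positions[, 3])$y
  seps <- abs(diff(s_at))
  expect_true(all(abs(seps - 2.5) < 0.025))
  # dwell positions lie on the fitted curve
  on_curve <- needletrace:::traj_xy_at(trc, dwc$positions[, 3])
  expect_lt(max(abs(on_curve - dwc$positions[, 1:2])), 0.1)
})

test_that("dwell sets translate rigidly with the phantom", {
  ph <- make_phantom(phantom_config(seed = 42))
  base <- fit_trajectory(ph$truth$centerlines[[2]]$points, degree = 2)
  delta <- c(7.5, -3.25, 12)
  shifted <- fit_trajectory(sweep(base$points, 2, delta, `+`), degree = 2)
  d0 <- sample_dwells(base, 2.5, 0, 8)
  d1 <- sample_dwells(shifted, 2.5, 0, 8)
  expect_equal(sweep(d1$positions, 2, delta, `-`), d0$positions,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("needle matching recovers permutations under jitter", {
  ph <- make_phantom(phantom_config(seed = 43, min_separation_mm = 3))
  truth <- ph$truth$centerlines
  m_id <- match_needles(truth, truth)
  expect_equal(m_id$pairs$truth, m_id$pairs$pred)
  expect_lt(max(m_id$pairs$cost_mm), 1e-12)

  m_rev <- match_needles(rev(truth), truth)
  expect_equal(m_rev$pairs$truth, rev(seq_along(truth)))

  set.seed(7)
  hits <- 0
  for (trial in 1:100) {
    jit <- lapply(truth, function(tr) {
      pts <- tr$points
      pts[, 1:2] <- pts[, 1:2] + matrix(rnorm(2 * nrow(pts), sd = 0.5 / sqrt(2)),
                                        ncol = 2)
      fit_trajectory(pts, degree = 2)
    })
    perm <- sample(seq_along(truth))
    m <- match_needles(jit[perm], truth)
    # jittered needle at position i is a copy of truth needle perm[i]
    ok <- all(vapply(seq_len(nrow(m$pairs)), function(r)
      perm[m$pairs$pred[r]] == m$pairs$truth[r], TRUE))
    hits <- hits + ok
  }
  expect_equal(hits, 100)

  expect_error(match_needles(list(), truth), "nonempty")
})

test_that("digitizing the ground-truth mask recovers every needle", {
  ph <- make_phantom(phantom_config(seed = 44, min_separation_mm = 3))
  traj <- digitize_mask(binary_mask_volume(ph$truth))
  expect_length(traj, 4)
  pairs <- pair_trajectories(traj, ph$truth$centerlines)
  sh <- shaft_error(pairs)
  expect_lt(sh$mean_mm, 0.8)
})
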