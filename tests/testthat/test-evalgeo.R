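test_that("overlap metrics match their hand-computed cases", {
  a <- array(0, dim = c(4, 4, 4)); b <- a
  a[1:2, 1, 1] <- 1            # |P| = 2
  b[1:4, 1, 1] <- 1            # |T| = 4, overlap 2
  expect_equal(dsc(a, b), 2 * 2 / (2 + 4))
  expect_equal(jaccard(a, b), 2 / 4)
  expect_equal(dsc(b, b), 1)
  expect_equal(jaccard(b, b), 1)
  disj <- array(0, dim = c(4, 4, 4)); disj[1, 1, 2] <- 1
  disj2 <- array(0, dim = c(4, 4, 4)); disj2[4, 4, 4] <- 1
  expect_equal(dsc(disj, disj2), 0)
  empty <- array(0, dim = c(4, 4, 4))
  expect_warning(d <- dsc(empty, empty), "empty")
  expect_equal(d, 1)
  expect_warning(j <- jaccard(empty, empty), "empty")
  expect_equal(j, 1)
  expect_error(dsc(a, array(0, dim = c(3, 3, 3))), "shapes differ")
})

test_that("J = D/(2-D) identity holds on random masks", {
  set.seed(10)
  for (rep in 1:50) {
    p <- array(runif(6^3) < runif(1, 0.05, 0.6), dim = c(6, 6, 6)) * 1
    t <- array(runif(6^3) < runif(1, 0.05, 0.6), dim = c(6, 6, 6)) * 1
    if (sum(p) + sum(t) == 0) next
    d <- dsc(p, t); j <- jaccard(p, t)
    expect_lt(abs(j - d / (2 - d)), 1e-12)
    expect_lte(j, d + 1e-15)
  }
})

test_that("Hausdorff distance is exact in anisotropic mm", {
  a <- array(0, dim = c(8, 8, 4)); a[1, 1, 1] <- 1
  b <- array(0, dim = c(8, 8, 4)); b[4, 5, 1] <- 1
  expect_equal(hausdorff(a, b, spacing = c(1, 1, 1)), 5)  # 3-4-5 triangle
  expect_equal(hausdorff(a, a, spacing = c(0.8, 0.8, 5)), 0)
  expect_error(hausdorff(a, array(0, dim = c(8, 8, 4))), "empty")

  set.seed(11)
  for (rep in 1:20) {
    p <- array(runif(8^3) < 0.05, dim = c(8, 8, 8)) * 1
    t <- array(runif(8^3) < 0.05, dim = c(8, 8, 8)) * 1
    if (sum(p) == 0 || sum(t) == 0) next
    sp <- c(0.8, 0.8, 5)
    expect_equal(hausdorff(p, t, spacing = sp), oracle_hausdorff(p, t, sp),
                 tolerance = 1e-12)
  }
})

test_that("metrics are invariant under rigid translation of both masks", {
  set.seed(12)
  p <- array(0, dim = c(10, 10, 10)); p[2:4, 2:4, 2:4] <- runif(27) < 0.5
  t <- array(0, dim = c(10, 10, 10)); t[2:5, 2:4, 2:4] <- runif(36) < 0.5
  shift <- function(a) { s <- a * 0; s[4:10, 3:10, 3:10] <- a[1:7, 1:8, 1:8]; s }
  expect_equal(dsc(p, t), dsc(shift(p), shift(t)))
  expect_equal(jaccard(p, t), jaccard(shift(p), shift(t)))
  if (sum(p) > 0 && sum(t) > 0)
    expect_equal(hausdorff(p, t, c(1, 2, 3)),
                 hausdorff(shift(p), shift(t), c(1, 2, 3)))
})

test_that("tip error reads needle-length differences", {
  t1 <- straight_traj(0, 0, 0, 100, id = 1L)   # length 100
  t2 <- straight_traj(5, 5, 0, 100, id = 2L)
  p1 <- straight_traj(0, 0, 0, 100, id = 1L)
  p2 <- straight_traj(5, 5, 0, 102, n = 12, id = 2L)  # length 102
  pairs <- list(list(pred = p1, truth = t1), list(pred = p2, truth = t2))
  te <- tip_error(pairs)
  expect_equal(te$mean_mm, (0 + 2) / 2)
  expect_equal(tip_error(list(list(pred = t1, truth = t1)))$mean_mm, 0)

  # rigid translation leaves lengths untouched
  shift_traj <- function(tr, d) fit_trajectory(sweep(tr$points, 2, d, `+`),
                                               degree = 1)
  d <- c(3, -4, 10)
  pairs_sh <- list(list(pred = shift_traj(p1, d), truth = shift_traj(t1, d)),
                   list(pred = shift_traj(p2, d), truth = shift_traj(t2, d)))
  expect_equal(tip_error(pairs_sh)$mean_mm, te$mean_mm, tolerance = 1e-9)

  expect_error(tip_error(list()), "no matched")
})

test_that("shaft error averages in-plane curve separation at common slices", {
  t1 <- straight_traj(0, 0, 0, 50)
  p1 <- straight_traj(0.6, 0.8, 0, 50)  # uniform (0.6, 0.8) offset -> 1 mm
  expect_equal(shaft_error(list(list(pred = p1, truth = t1)))$mean_mm, 1,
               tolerance = 1e-9)
  expect_equal(shaft_error(list(list(pred = t1, truth = t1)))$mean_mm, 0)

  # jittered phantom trajectories against the independent double-sum oracle
  ph <- make_phantom(phantom_config(seed = 51))
  set.seed(13)
  pairs <- lapply(ph$truth$centerlines, function(tr) {
    pts <- tr$points
    pts[, 1:2] <- pts[, 1:2] + matrix(rnorm(2 * nrow(pts), sd = 0.4), ncol = 2)
    list(pred = fit_trajectory(pts, degree = 3), truth = tr)
  })
  expect_equal(shaft_error(pairs)$mean_mm, oracle_shaft(pairs),
               tolerance = 1e-10)

  # disjoint slice ranges: pair excluded, then nothing usable remains
  lo <- straight_traj(0, 0, 0, 20, n = 5)
  hi <- straight_traj(0, 0, 100, 120, n = 5)
  expect_warning(expect_error(shaft_error(list(list(pred = lo, truth = hi))),
                              "no usable"),
                 "no common")
})

test_that("flagged needle pairs are excluded from the error metrics", {
  t1 <- straight_traj(0, 0, 0, 50)
  bad <- straight_traj(1, 1, 0, 50); bad$flagged <- TRUE
  good <- straight_traj(0.5, 0, 0, 50)
  pairs <- list(list(pred = bad, truth = t1), list(pred = good, truth = t1))
  expect_warning(se <- shaft_error(pairs), "flagged")
  expect_equal(se$mean_mm, 0.5, tolerance = 1e-9)
})

test_that("paired t matches hand computation and a sign-flip permutation", {
  b <- c(10, 11, 12)
  a <- b + c(1, 2, 3)
  r <- paired_t(a, b)
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_error(paired_t(a, a), "zero variance")
  expect_error(paired_t(1, 2), "equal lengths")

  d <- c(-0.1, 0.55, -0.27, 1.68, 0.66, -0.26)  # six synthetic case differences
  r6 <- paired_t(d, rep(0, 6))
  tstat <- function(x) mean(x) / (sd(x) / sqrt(length(x)))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 6)))
  perm_t <- apply(signs, 1, function(s) tstat(d * s))
  p_perm <- mean(abs(perm_t) >= abs(tstat(d)) - 1e-12)
  expect_lt(abs(p_perm - r6$p), 0.02)
})

test_that("geo_report assembles the full panel with consistent ordering", {
  ph <- make_phantom(phantom_config(seed = 52))
  gt_mask <- binary_mask_volume(ph$truth)
  traj <- digitize_mask(gt_mask)
  rep <- geo_report(gt_mask, gt_mask, traj, ph$truth$centerlines)
  expect_equal(rep$dsc, 1)
  expect_equal(rep$jaccard, 1)
  expect_equal(rep$hausdorff_mm, 0)
  expect_gte(rep$jaccard, 0)
  expect_lte(rep$jaccard, rep$dsc)
  expect_equal(rep$n_needles, 4)
  expect_lt(rep$shaft_error_mm, 0.8)
  expect_lt(rep$tip_error_mm, 2.5)
})
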