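single_dwell_plan <- function(pos = c(0, 0, 0), time_s = 3600,
                              src = unity_source_model()) {
  dw <- structure(list(needle_id = 1L, positions = matrix(pos, 1, 3),
                       times = time_s, step_mm = 2.5, offset_mm = 0),
                  class = "dwell_set")
  brachy_plan(list(dw), 6, src)
}

test_that("unity tables reduce TG-43 to the inverse-square law", {
  # S_K * Lambda = 100 cGy/h at r0 -> 1 Gy at r0 after one hour
  plan <- single_dwell_plan(time_s = 3600,
                            src = unity_source_model(air_kerma_strength = 100))
  r0 <- plan$source$reference_r0
  d_r0 <- dose_at_point(c(r0, 0, 0), plan)
  expect_equal(d_r0, 1, tolerance = 1e-12)
  d_2r0 <- dose_at_point(c(2 * r0, 0, 0), plan)
  expect_equal(d_2r0 / d_r0, 0.25, tolerance = 1e-10)
  # dose * r^2 constant along a ray
  radii <- seq(2, 200, length.out = 10)
  doses <- dose_at_point(cbind(radii, 0, 0), plan)
  expect_lt(max(abs(doses * radii^2 - doses[1] * radii[1]^2)) /
              (doses[1] * radii[1]^2), 1e-10)
})

test_that("dose superposes over dwells and plans", {
  src <- unity_source_model(air_kerma_strength = 100)
  p1 <- single_dwell_plan(c(0, 0, 0), 1800, src)
  p2 <- single_dwell_plan(c(10, 5, 0), 900, src)
  both <- brachy_plan(c(p1$needles, p2$needles), 6, src)
  pts <- cbind(c(25, -10, 3), c(0, 8, -7), c(4, 4, 30))
  expect_equal(dose_at_point(pts, both),
               dose_at_point(pts, p1) + dose_at_point(pts, p2),
               tolerance = 1e-12)
})

test_that("the dose engine matches an independent loop oracle", {
  set.seed(15)
  src <- default_source_model(air_kerma_strength = 40800)
  dwells <- lapply(1:3, function(i) {
    n <- 4
    structure(list(needle_id = i,
                   positions = cbind(runif(n, 10, 40), runif(n, 10, 40),
                                     runif(n, 10, 60)),
                   times = runif(n, 1, 30), step_mm = 2.5, offset_mm = 0),
              class = "dwell_set")
  })
  plan <- brachy_plan(dwells, 6, src)
  pts <- cbind(runif(20, 0, 60), runif(20, 0, 60), runif(20, 0, 80))
  got <- dose_at_point(pts, plan, allow_extrapolation = TRUE)
  want <- oracle_dose(pts, plan)
  expect_lt(max(abs(got - want) / want), 1e-10)
})

test_that("dose grids are zero without time, equivariant, and peak near dwells", {
  grid <- volume3d(array(0, dim = c(16, 16, 8)), spacing = c(2, 2, 5),
                   origin = c(0, 0, 0))
  src <- unity_source_model(air_kerma_strength = 100)
  zero <- single_dwell_plan(c(15, 15, 15), 0, src)
  expect_true(all(dose_grid(grid, zero)$data == 0))

  plan <- single_dwell_plan(c(15.3, 14.2, 16.1), 600, src)
  g1 <- suppressWarnings(dose_grid(grid, plan))
  delta <- c(4, -6, 10)
  grid2 <- volume3d(grid$data, grid$spacing, grid$origin + delta)
  plan2 <- single_dwell_plan(c(15.3, 14.2, 16.1) + delta, 600, src)
  g2 <- suppressWarnings(dose_grid(grid2, plan2))
  expect_equal(g1$data, g2$data, tolerance = 1e-12)

  amax <- which(g1$data == max(g1$data), arr.ind = TRUE)[1, , drop = FALSE]
  w <- voxel_to_world(g1, amax - 1)
  expect_lt(sqrt(sum((w - c(15.3, 14.2, 16.1))^2)), sqrt(sum(c(2, 2, 5)^2)))

  expect_error(dose_at_point(c(5000, 0, 0), plan), "table range")
})

test_that("DVH metrics agree with a full voxel sort", {
  sp <- c(2, 2, 2.5)  # 10 cc structure of 1000 voxels
  arr <- array(1, dim = c(10, 10, 10))
  st <- volume3d(arr, spacing = sp)
  uni <- volume3d(array(7.3, dim = dim(arr)), spacing = sp)
  dv <- compute_dvh(uni, st)
  expect_equal(dv$d90, 7.3, tolerance = 0.011)
  expect_equal(dv$d100, 7.3, tolerance = 0.011)
  expect_equal(dv$structure_volume_cc, 10)
  expect_equal(dv$cumulative_volume[1], 1)
  expect_true(all(diff(dv$cumulative_volume) <= 0))

  half <- volume3d(array(rep(c(0, 10), each = 500), dim = dim(arr)),
                   spacing = sp)
  dvh <- compute_dvh(half, st)
  expect_lt(dvh$d90, 0.011)
  expect_lt(dvh$d100, 0.011)

  set.seed(16)
  rnd <- volume3d(array(runif(1000, 0, 12), dim = dim(arr)), spacing = sp)
  dvr <- compute_dvh(rnd, st)
  doses <- sort(as.vector(rnd$data), decreasing = TRUE)
  expect_lt(abs(dvr$d90 - doses[ceiling(0.9 * 1000)]), 0.011)
  expect_lt(abs(dvr$d2cc - doses[ceiling(2 / 10 * 1000)]), 0.011)
  expect_lte(dvr$d100, dvr$d90)
  expect_lte(dvr$d90, max(rnd$data))

  tiny <- volume3d(array(c(1, rep(0, 999)), dim = dim(arr)), spacing = sp)
  expect_message(dvt <- compute_dvh(rnd, tiny), "undefined")
  expect_true(is.na(dvt$d2cc))
})

test_that("D100 <= D90 on random structures", {
  set.seed(17)
  for (rep in 1:20) {
    sp <- c(1.5, 1.5, 3)
    dosev <- volume3d(array(rexp(8^3, 1 / 5), dim = c(8, 8, 8)), spacing = sp)
    st <- volume3d(array(runif(8^3) < 0.4, dim = c(8, 8, 8)) * 1, spacing = sp)
    if (sum(st$data) < 2) next
    dv <- compute_dvh(dosev, st)
    expect_lte(dv$d100, dv$d90 + 1e-12)
  }
})

test_that("dose differences follow the signed definitions", {
  same <- dose_difference(6, 6)
  expect_equal(same$absolute_gy, 0)
  expect_equal(same$relative, 0)
  d <- dose_difference(6.0, 5.9)
  expect_equal(d$absolute_gy, 0.1, tolerance = 1e-12)
  expect_equal(d$relative, 0.1 / 6, tolerance = 1e-12)
  sw <- dose_difference(5.9, 6.0)
  expect_equal(sw$absolute_gy, -d$absolute_gy)
  expect_lt(sw$relative, 0)
  expect_error(dose_difference(0, 1), "manual = 0")
})

test_that("1 mm dwell perturbations shift D90 by a bounded nonzero amount", {
  ph <- make_phantom(phantom_config(seed = 61))
  src <- unity_source_model(air_kerma_strength = 40800,
                            dose_rate_constant = 1.11)
  base_dw <- lapply(ph$truth$centerlines, sample_dwells, step_mm = 2.5,
                    offset_mm = 0, n_dwells = 10)
  plan <- brachy_plan(base_dw, 6, src)
  set.seed(18)
  pert_dw <- lapply(base_dw, function(d) {
    u <- matrix(rnorm(length(d$positions)), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    d$positions <- d$positions + u
    d
  })
  plan_p <- brachy_plan(pert_dw, 6, src)
  ctv <- ph$truth$structures$hrctv
  d90 <- compute_dvh(suppressWarnings(dose_grid(ph$volume, plan)), ctv)$d90
  d90p <- compute_dvh(suppressWarnings(dose_grid(ph$volume, plan_p)), ctv)$d90
  rel <- abs(d90 - d90p) / d90
  expect_gt(rel, 0)
  expect_lt(rel, 0.10)
})

test_that("source models validate their tables", {
  expect_error(source_model(1, 1,
                            data.frame(r_mm = c(1, 10, 10), g = c(1, 1, 1)),
                            data.frame(r_mm = c(1, 10), phi = c(1, 1))),
               "strictly increasing")
  expect_error(source_model(1, 1,
                            data.frame(r_mm = c(1, 10, 50), g = c(1, 0.9, 0.8)),
                            data.frame(r_mm = c(1, 50), phi = c(1, 1))),
               "must be 1")
  src <- default_source_model()
  expect_equal(approx(src$radial_dose$r_mm, src$radial_dose$g, 10)$y, 1)
})
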