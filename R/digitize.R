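#' Label needle instances in a binary mask
#'
#' 26-connected component labeling of a binary needle mask; components
#' smaller than `min_voxels` are discarded as segmentation noise. Labels are
#' 1..K in scan order.
#'
#' @param mask a binary [volume3d()].
#' @param min_voxels minimum component size kept (default 5).
#' @return a [volume3d()] of integer instance labels (0 = background), with
#'   attribute `n_labels`.
#' @export
label_needles <- function(mask, min_voxels = 5L) {
  stopifnot(inherits(mask, "volume3d"))
  d <- dim(mask$data)
  lab <- cpp_label26(as.logical(mask$data > 0), as.integer(d),
                     as.integer(min_voxels))
  k <- max(lab)
  if (k == 0L) warning("label_needles: no components found (empty mask)")
  out <- volume3d(array(as.numeric(lab), dim = d), mask$spacing, mask$origin)
  attr(out, "n_labels") <- k
  out
}

#' Extract a per-slice centroid centerline
#'
#' For every z-slice intersecting the instance, computes the unweighted
#' centroid of its voxels in world mm, ordered by increasing z. A jump
#' between consecutive slice centroids larger than twice the needle diameter
#' flags the centerline as a suspected merge of touching needles; flagged
#' needles are excluded from accuracy metrics downstream.
#'
#' @param labels an instance-labeled [volume3d()] (from [label_needles()]).
#' @param label which instance to trace.
#' @param needle_diameter_mm nominal needle diameter used in the merge flag
#'   threshold (default 1.5).
#' @return numeric matrix (n_slices x 3) of mm points with attribute
#'   `flagged` (logical).
#' @export
extract_centerline <- function(labels, label = 1L, needle_diameter_mm = 1.5) {
  stopifnot(inherits(labels, "volume3d"))
  d <- dim(labels$data)
  sp <- labels$spacing; orig <- labels$origin
  pts <- NULL
  for (k in seq_len(d[3])) {
    idx <- which(labels$data[, , k] == label, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    cx <- orig[1] + (mean(idx[, 1]) - 1) * sp[1]
    cy <- orig[2] + (mean(idx[, 2]) - 1) * sp[2]
    pts <- rbind(pts, c(cx, cy, orig[3] + (k - 1) * sp[3]))
  }
  if (is.null(pts) || nrow(pts) < 2L)
    stop_cfg("extract_centerline: instance %d spans < 2 slices (not a needle)",
             label)
  colnames(pts) <- c("x", "y", "z")
  jumps <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  flagged <- any(jumps > 2 * needle_diameter_mm)
  if (flagged)
    warning(sprintf("extract_centerline: instance %d has an in-plane jump > %.1f mm (possible merged needles); flagged",
                    label, 2 * needle_diameter_mm))
  attr(pts, "flagged") <- flagged
  pts
}

#' Fit a smooth trajectory through centerline points
#'
#' Least-squares polynomials `x(z)` and `y(z)` (default degree 3, in a
#' centered-z basis for conditioning) smooth the per-slice centroids; the
#' points are re-evaluated on the fit, suppressing slice-wise centroid noise.
#' The tip is the fitted point at the maximal-z end, extrapolated by
#' `extrapolate_mm` beyond the last observed slice (callers typically cap
#' this at half a slice thickness, the scale at which thick slices quantize
#' the true tip). Arc length is computed by fine trapezoid quadrature along
#' the fitted curve.
#'
#' @param points numeric (n x 3) matrix of mm points ordered in z (e.g. from
#'   [extract_centerline()]).
#' @param degree polynomial degree (1-5, default 3); lowered with a warning
#'   when fewer than `degree + 1` points are available.
#' @param extrapolate_mm tip extrapolation beyond the last point's z
#'   (default 0).
#' @param needle_id optional integer id carried through.
#' @return a `trajectory`: fitted `points`, `poly_x`/`poly_y` coefficients
#'   (ascending powers of `z - z_center`), `z_center`, `tip`, `length_mm`,
#'   `flagged`.
#' @export
fit_trajectory <- function(points, degree = 3L, extrapolate_mm = 0,
                           needle_id = NA_integer_) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop_cfg("fit_trajectory: points must be (n x 3)")
  if (is.unsorted(points[, 3], strictly = FALSE))
    points <- points[order(points[, 3]), , drop = FALSE]
  z <- points[, 3]
  if (length(unique(z)) < 2L)
    stop_cfg("fit_trajectory: all points on one slice; cannot fit z-parameterized curve")
  degree <- as.integer(degree)
  if (degree < 1L || degree > 5L) stop_cfg("fit_trajectory: degree must be in 1..5")
  n <- nrow(points)
  if (n < degree + 1L) {
    degree <- n - 1L
    warning(sprintf("fit_trajectory: only %d points; degree lowered to %d",
                    n, degree))
  }
  z_center <- mean(z)
  t <- z - z_center
  X <- outer(t, 0:degree, `^`)
  px <- as.numeric(lm.fit(X, points[, 1])$coefficients)
  py <- as.numeric(lm.fit(X, points[, 2])$coefficients)
  px[is.na(px)] <- 0; py[is.na(py)] <- 0
  tip_z <- max(z) + extrapolate_mm
  tr <- make_trajectory_from_poly(px, py, z_center, z, tip_z,
                                  needle_id = needle_id)
  tr$flagged <- isTRUE(attr(points, "flagged"))
  tr
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> needle %s: %d points, degree %d, length %.2f mm, tip (%.2f, %.2f, %.2f)%s\n",
              as.character(x$needle_id), nrow(x$points), x$degree,
              x$length_mm, x$tip[1], x$tip[2], x$tip[3],
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Digitize all needles in a mask
#'
#' Convenience pipeline: [label_needles()], then per instance
#' [extract_centerline()] and [fit_trajectory()]. The tip extrapolation
#' defaults to half the slice thickness. Instances spanning fewer than 2
#' slices are dropped.
#'
#' @param mask a binary [volume3d()].
#' @param degree polynomial degree for [fit_trajectory()].
#' @param min_voxels minimum component size kept.
#' @param needle_diameter_mm merge-flag scale for [extract_centerline()].
#' @param extrapolate_mm tip extrapolation; `NULL` means half a slice.
#' @return list of `trajectory` objects (possibly flagged).
#' @export
digitize_mask <- function(mask, degree = 3L, min_voxels = 5L,
                          needle_diameter_mm = 1.5, extrapolate_mm = NULL) {
  labels <- label_needles(mask, min_voxels = min_voxels)
  k <- attr(labels, "n_labels")
  if (k == 0L) return(list())
  if (is.null(extrapolate_mm)) extrapolate_mm <- mask$spacing[3] / 2
  out <- list()
  for (lbl in seq_len(k)) {
    pts <- tryCatch(
      extract_centerline(labels, lbl, needle_diameter_mm = needle_diameter_mm),
      error = function(e) NULL)
    if (is.null(pts)) next
    out[[length(out) + 1L]] <-
      fit_trajectory(pts, degree = degree, extrapolate_mm = extrapolate_mm,
                     needle_id = lbl)
  }
  out
}

# Cumulative arc-length table along a trajectory from the entry z to tip z.
arc_table <- function(traj, n = 4001L) {
  z0 <- min(traj$points[, 3]); z1 <- traj$tip[3]
  zg <- seq(z0, z1, length.out = n)
  t <- zg - traj$z_center
  dx <- eval_poly(poly_deriv(traj$poly_x), t)
  dy <- eval_poly(poly_deriv(traj$poly_y), t)
  f <- sqrt(dx^2 + dy^2 + 1)
  s <- c(0, cumsum((f[-1] + f[-n]) / 2 * diff(zg)))
  list(z = zg, s = s)
}

#' Sample source dwell positions along a trajectory
#'
#' Places `n_dwells` positions on the fitted curve, the first at arc length
#' `offset_mm` from the tip and subsequent ones every `step_mm` walking
#' toward the entry point. Positions are solved by inverting the cumulative
#' arc-length table (quadrature resolution well under 0.01 mm).
#'
#' @param traj a `trajectory`.
#' @param step_mm source step size along the curve (> 0; 2.5 mm typical).
#' @param offset_mm distance from the tip to the first dwell (>= 0).
#' @param n_dwells number of dwell positions.
#' @param times dwell times in seconds (length `n_dwells` or scalar).
#' @return a `dwell_set`: `needle_id`, `positions` (n x 3 mm), `times`,
#'   `step_mm`, `offset_mm`.
#' @export
sample_dwells <- function(traj, step_mm = 2.5, offset_mm = 0, n_dwells = 5L,
                          times = 10) {
  stopifnot(inherits(traj, "trajectory"))
  if (step_mm <= 0) stop_cfg("sample_dwells: step_mm must be > 0")
  if (offset_mm < 0) stop_cfg("sample_dwells: offset_mm must be >= 0")
  n_dwells <- as.integer(n_dwells)
  tab <- arc_table(traj)
  L <- max(tab$s)   # total arc length on the inversion table itself
  if (n_dwells * step_mm + offset_mm > L)
    stop_cfg("sample_dwells: needle %s too short (%.1f mm) for %d dwells at step %.2f mm + offset %.2f mm",
             as.character(traj$needle_id), L, n_dwells, step_mm, offset_mm)
  target_s <- L - (offset_mm + (seq_len(n_dwells) - 1) * step_mm)
  zt <- approx(tab$s, tab$z, xout = target_s, ties = "ordered")$y
  t <- zt - traj$z_center
  pos <- cbind(x = eval_poly(traj$poly_x, t), y = eval_poly(traj$poly_y, t),
               z = zt)
  structure(list(needle_id = traj$needle_id, positions = pos,
                 times = rep(as.numeric(times), length.out = n_dwells),
                 step_mm = step_mm, offset_mm = offset_mm),
            class = "dwell_set")
}

# In-plane (x, y) position of a trajectory's fitted curve at given z values.
traj_xy_at <- function(traj, z) {
  t <- z - traj$z_center
  cbind(eval_poly(traj$poly_x, t), eval_poly(traj$poly_y, t))
}

# z values present in both trajectories' point sets (tolerance 1e-6 mm).
common_z <- function(a, b) {
  za <- a$points[, 3]; zb <- b$points[, 3]
  za[vapply(za, function(z) any(abs(zb - z) < 1e-6), TRUE)]
}

# Mean in-plane distance between two trajectories over their common slices.
traj_pair_cost <- function(a, b) {
  z <- common_z(a, b)
  if (length(z) == 0L) return(Inf)
  pa <- traj_xy_at(a, z); pb <- traj_xy_at(b, z)
  mean(sqrt(rowSums((pa - pb)^2)))
}

perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub), n - 1L))))
}

#' Match predicted needles to ground-truth needles
#'
#' One-to-one assignment minimizing the total mean in-plane centerline
#' distance, solved exactly by enumeration (needle counts are small).
#' Unmatched predictions are reported as false positives, unmatched truths as
#' false negatives.
#'
#' @param pred,truth nonempty lists of `trajectory` objects.
#' @return list with `pairs` (data.frame `pred`, `truth`, `cost_mm`),
#'   `false_positive` and `false_negative` index vectors.
#' @export
match_needles <- function(pred, truth) {
  if (length(pred) == 0L || length(truth) == 0L)
    stop_cfg("match_needles: both lists must be nonempty")
  kp <- length(pred); kt <- length(truth)
  cost <- matrix(0, kp, kt)
  for (i in seq_len(kp)) for (j in seq_len(kt))
    cost[i, j] <- traj_pair_cost(pred[[i]], truth[[j]])
  big <- max(cost[is.finite(cost)], 0) + 1e6
  cost[!is.finite(cost)] <- big
  if (kp <= kt) {
    pm <- perms(kt)
    best <- NULL; best_cost <- Inf
    for (r in seq_len(nrow(pm))) {
      asg <- pm[r, seq_len(kp)]
      tc <- sum(cost[cbind(seq_len(kp), asg)])
      if (tc < best_cost) { best_cost <- tc; best <- asg }
    }
    pairs <- data.frame(pred = seq_len(kp), truth = best,
                        cost_mm = cost[cbind(seq_len(kp), best)])
  } else {
    pm <- perms(kp)
    best <- NULL; best_cost <- Inf
    for (r in seq_len(nrow(pm))) {
      asg <- pm[r, seq_len(kt)]
      tc <- sum(cost[cbind(asg, seq_len(kt))])
      if (tc < best_cost) { best_cost <- tc; best <- asg }
    }
    pairs <- data.frame(pred = best, truth = seq_len(kt),
                        cost_mm = cost[cbind(best, seq_len(kt))])
  }
  list(pairs = pairs,
       false_positive = setdiff(seq_len(kp), pairs$pred),
       false_negative = setdiff(seq_len(kt), pairs$truth))
}
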