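mask_array <- function(m, what) {
  if (inherits(m, "volume3d")) m$data > 0
  else if (is.array(m) || is.vector(m)) m > 0
  else stop_cfg("%s: expected a volume3d or array mask", what)
}

check_same_grid <- function(P, T_, what) {
  if (inherits(P, "volume3d") && inherits(T_, "volume3d")) {
    if (!same_grid(P, T_)) stop_cfg("%s: mask grids differ", what)
  } else if (!identical(dim(P) %||% length(P), dim(T_) %||% length(T_)))
    stop_cfg("%s: mask shapes differ", what)
}

#' Dice similarity coefficient
#'
#' `2|P intersect T| / (|P| + |T|)`, the standard overlap measure between a
#' predicted and a ground-truth segmentation; 1.0 (with a warning) when both
#' masks are empty.
#'
#' @param P,T binary masks ([volume3d()] or arrays) on the same grid.
#' @return fraction in \[0, 1\].
#' @export
dsc <- function(P, T) {
  check_same_grid(P, T, "dsc")
  p <- mask_array(P, "dsc"); t <- mask_array(T, "dsc")
  np <- sum(p); nt <- sum(t)
  if (np + nt == 0) {
    warning("dsc: both masks empty; defined as 1")
    return(1)
  }
  2 * sum(p & t) / (np + nt)
}

#' Jaccard index
#'
#' `|P intersect T| / |P union T|`; 1.0 (with a warning) when both masks are
#' empty. Related to Dice by `J = D / (2 - D)`.
#'
#' @inheritParams dsc
#' @return fraction in \[0, 1\].
#' @export
jaccard <- function(P, T) {
  check_same_grid(P, T, "jaccard")
  p <- mask_array(P, "jaccard"); t <- mask_array(T, "jaccard")
  u <- sum(p | t)
  if (u == 0) {
    warning("jaccard: both masks empty; defined as 1")
    return(1)
  }
  sum(p & t) / u
}

mask_coords_mm <- function(m, spacing) {
  arr <- mask_array(m, "hausdorff")
  if (inherits(m, "volume3d")) spacing <- m$spacing
  idx <- which(arr, arr.ind = TRUE)
  sweep(idx - 1, 2L, spacing, `*`)
}

directed_hausdorff <- function(A, B) {
  # max over a of min over b of ||a-b||; squared distances are formed from
  # explicit coordinate differences (no a^2+b^2-2ab cancellation)
  tB <- t(B)
  worst <- 0
  for (i in seq_len(nrow(A))) {
    m <- min(colSums((tB - A[i, ])^2))
    if (m > worst) worst <- m
  }
  sqrt(worst)
}

#' Hausdorff distance between two masks
#'
#' Exact symmetric Hausdorff distance `max(D(A,B), D(B,A))` with
#' `D(A,B) = max_a min_b ||a - b||`, computed between voxel centres in
#' physical mm (anisotropic spacing respected). The exact maximum is
#' reported, not a percentile.
#'
#' @param A,B nonempty binary masks ([volume3d()] or arrays) on the same
#'   grid.
#' @param spacing voxel spacing in mm (taken from the volumes when given).
#' @return distance in mm.
#' @export
hausdorff <- function(A, B, spacing = c(1, 1, 1)) {
  check_same_grid(A, B, "hausdorff")
  ca <- mask_coords_mm(A, spacing); cb <- mask_coords_mm(B, spacing)
  if (nrow(ca) == 0L || nrow(cb) == 0L)
    stop_cfg("hausdorff: undefined for an empty mask")
  max(directed_hausdorff(ca, cb), directed_hausdorff(cb, ca))
}

check_pairs <- function(pairs, what) {
  if (length(pairs) == 0L) stop_cfg("%s: no matched trajectory pairs", what)
  for (p in pairs)
    if (!inherits(p$pred, "trajectory") || !inherits(p$truth, "trajectory"))
      stop_cfg("%s: each pair needs $pred and $truth trajectories", what)
  keep <- !vapply(pairs, function(p) p$pred$flagged || p$truth$flagged, TRUE)
  if (!all(keep))
    warning(sprintf("%s: %d flagged pair(s) excluded", what, sum(!keep)))
  pairs[keep]
}

#' Needle tip error
#'
#' Mean absolute difference between predicted and ground-truth needle arc
#' lengths, `(1/N) sum |len(P_i) - len(T_i)|`, over matched needle pairs.
#' The mean Euclidean tip-to-tip distance is reported alongside as a
#' secondary diagnostic (`tip_distance_mm`); the length-difference reading is
#' the primary metric.
#'
#' @param pairs list of matched pairs, each `list(pred = trajectory, truth =
#'   trajectory)` (see [pair_trajectories()]).
#' @return list: `mean_mm` (primary tip error), `tip_distance_mm`
#'   (secondary), `per_needle` data.frame.
#' @export
tip_error <- function(pairs) {
  pairs <- check_pairs(pairs, "tip_error")
  if (length(pairs) == 0L) stop_cfg("tip_error: no unflagged pairs remain")
  len_diff <- vapply(pairs, function(p) abs(p$pred$length_mm - p$truth$length_mm), 0)
  tipd <- vapply(pairs, function(p) sqrt(sum((p$pred$tip - p$truth$tip)^2)), 0)
  list(mean_mm = mean(len_diff), tip_distance_mm = mean(tipd),
       per_needle = data.frame(
         needle = vapply(pairs, function(p) p$truth$needle_id, 1L),
         length_error_mm = len_diff, tip_distance_mm = tipd))
}

#' Needle shaft error
#'
#' Mean in-plane Euclidean distance `||P(x,y) - T(x,y)||` between the
#' predicted and ground-truth fitted curves evaluated at the same z, averaged
#' over the slices the two trajectories share and then over needles. Slices
#' present in only one trajectory are excluded; a pair with no common slice
#' is dropped with a warning.
#'
#' @inheritParams tip_error
#' @return list: `mean_mm`, `per_needle` data.frame.
#' @export
shaft_error <- function(pairs) {
  pairs <- check_pairs(pairs, "shaft_error")
  per <- numeric(0); ids <- integer(0)
  for (p in pairs) {
    z <- common_z(p$pred, p$truth)
    if (length(z) == 0L) {
      warning("shaft_error: pair with no common z-slices excluded")
      next
    }
    dp <- traj_xy_at(p$pred, z) - traj_xy_at(p$truth, z)
    per <- c(per, mean(sqrt(rowSums(dp^2))))
    ids <- c(ids, p$truth$needle_id)
  }
  if (length(per) == 0L) stop_cfg("shaft_error: no usable pairs")
  list(mean_mm = mean(per),
       per_needle = data.frame(needle = ids, shaft_error_mm = per))
}

#' Pair two trajectory lists via optimal matching
#'
#' Runs [match_needles()] and reshapes the result into the pair list consumed
#' by [tip_error()] and [shaft_error()].
#'
#' @param pred,truth lists of `trajectory` objects.
#' @return list of `list(pred=, truth=)` pairs.
#' @export
pair_trajectories <- function(pred, truth) {
  m <- match_needles(pred, truth)
  lapply(seq_len(nrow(m$pairs)), function(r)
    list(pred = pred[[m$pairs$pred[r]]], truth = truth[[m$pairs$truth[r]]]))
}

#' Paired t test between per-case metrics
#'
#' Classic paired t on the per-case differences (two-sided p from the t
#' distribution with n-1 degrees of freedom), as used to compare the two
#' network variants case by case.
#'
#' @param a,b equal-length numeric vectors (n >= 2) of per-case metric
#'   values.
#' @return list: `t`, `p`, `df`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop_cfg("paired_t: need equal lengths >= 2")
  d <- a - b
  if (sd(d) == 0)
    stop_cfg("paired_t: zero variance of differences; t statistic undefined")
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' Full geometric accuracy report
#'
#' Computes the complete metric panel for one case: Dice and Jaccard (as
#' fractions), Hausdorff distance, and the tip/shaft trajectory errors over
#' optimally matched, unflagged needle pairs.
#'
#' @param pred_mask,truth_mask binary [volume3d()] masks.
#' @param pred_traj,truth_traj lists of `trajectory` objects.
#' @return a `geo_report` list: `dsc`, `jaccard`, `hausdorff_mm`,
#'   `tip_error_mm`, `tip_distance_mm`, `shaft_error_mm`, `n_needles`,
#'   `false_positive`, `false_negative`, `per_needle`.
#' @export
geo_report <- function(pred_mask, truth_mask, pred_traj, truth_traj) {
  m <- match_needles(pred_traj, truth_traj)
  pairs <- lapply(seq_len(nrow(m$pairs)), function(r)
    list(pred = pred_traj[[m$pairs$pred[r]]],
         truth = truth_traj[[m$pairs$truth[r]]]))
  te <- tip_error(pairs)
  se <- shaft_error(pairs)
  per <- merge(te$per_needle, se$per_needle, by = "needle", all = TRUE)
  structure(list(
    dsc = dsc(pred_mask, truth_mask),
    jaccard = jaccard(pred_mask, truth_mask),
    hausdorff_mm = hausdorff(pred_mask, truth_mask),
    tip_error_mm = te$mean_mm,
    tip_distance_mm = te$tip_distance_mm,
    shaft_error_mm = se$mean_mm,
    n_needles = nrow(m$pairs),
    false_positive = m$false_positive,
    false_negative = m$false_negative,
    per_needle = per), class = "geo_report")
}

#' @export
print.geo_report <- function(x, ...) {
  cat(sprintf("<geo_report> DSC %.1f%%  JI %.1f%%  HD %.2f mm  tip %.2f mm  shaft %.2f mm  (%d needles)\n",
              100 * x$dsc, 100 * x$jaccard, x$hausdorff_mm, x$tip_error_mm,
              x$shaft_error_mm, x$n_needles))
  invisible(x)
}
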