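#' TG-43 point-source model
#'
#' Bundles the quantities of the 1-D (point-source) TG-43 dose formalism:
#' air-kerma strength `S_K` (U = uGy m^2/h), dose-rate constant `Lambda`
#' (cGy/(h U)), radial dose function `g(r)` and 1-D anisotropy function
#' `phi_an(r)` as interpolation tables over radius in mm, and the reference
#' radius `r0` (10 mm). Dose rate at distance r:
#' `S_K * Lambda * (r0/r)^2 * g(r) * phi_an(r)`.
#'
#' @param air_kerma_strength source strength in U.
#' @param dose_rate_constant Lambda in cGy/(h U).
#' @param radial_dose data.frame with columns `r_mm`, `g` (strictly
#'   increasing radii; `g` must be 1 at `reference_r0`).
#' @param anisotropy data.frame with columns `r_mm`, `phi`.
#' @param reference_r0 reference radius in mm (default 10).
#' @return a `source_model`.
#' @export
source_model <- function(air_kerma_strength, dose_rate_constant,
                         radial_dose, anisotropy, reference_r0 = 10) {
  stopifnot(all(c("r_mm", "g") %in% names(radial_dose)),
            all(c("r_mm", "phi") %in% names(anisotropy)))
  if (any(diff(radial_dose$r_mm) <= 0) || any(diff(anisotropy$r_mm) <= 0))
    stop_cfg("source_model: table radii must be strictly increasing")
  g_r0 <- approx(radial_dose$r_mm, radial_dose$g, reference_r0)$y
  if (is.na(g_r0) || abs(g_r0 - 1) > 1e-6)
    stop_cfg("source_model: g(r0 = %.1f mm) must be 1 (got %.6f)",
             reference_r0, g_r0)
  structure(list(air_kerma_strength = air_kerma_strength,
                 dose_rate_constant = dose_rate_constant,
                 radial_dose = radial_dose, anisotropy = anisotropy,
                 reference_r0 = reference_r0), class = "source_model")
}

#' Unity-table source model for analytic tests
#'
#' `g(r) = phi_an(r) = 1` everywhere, reducing TG-43 to a pure inverse-square
#' point source with closed-form doses.
#'
#' @param air_kerma_strength source strength in U.
#' @param dose_rate_constant Lambda in cGy/(h U); default 1 for convenience.
#' @param r_max_mm table extent in mm.
#' @return a `source_model`.
#' @export
unity_source_model <- function(air_kerma_strength = 1,
                               dose_rate_constant = 1, r_max_mm = 1000) {
  tab <- data.frame(r_mm = c(0.1, r_max_mm), g = c(1, 1))
  source_model(air_kerma_strength, dose_rate_constant,
               radial_dose = tab,
               anisotropy = data.frame(r_mm = c(0.1, r_max_mm),
                                       phi = c(1, 1)))
}

#' Generic high-dose-rate Ir-192-like source model
#'
#' Loads the bundled synthetic illustrative `g(r)` and `phi_an(r)` tables
#' (inst/extdata). These are generic smooth curves of the qualitative shape
#' of a high-energy HDR source, NOT consensus data for any commercial source;
#' dose comparisons in this package are differential (manual vs automatic
#' digitization with identical source and times), so only the shape matters.
#'
#' @param air_kerma_strength source strength in U (default 40800, a typical
#'   10 Ci Ir-192 afterloader charge).
#' @return a `source_model` with Lambda = 1.11 cGy/(h U).
#' @export
default_source_model <- function(air_kerma_strength = 40800) {
  g <- read_table_csv(system.file("extdata", "generic_ir192_radial_dose.csv",
                                  package = "needletrace"))
  phi <- read_table_csv(system.file("extdata", "generic_ir192_anisotropy.csv",
                                    package = "needletrace"))
  source_model(air_kerma_strength, 1.11, g, phi)
}

read_table_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Assemble a treatment plan
#'
#' @param needles list of `dwell_set` objects (>= 1), one per digitized
#'   needle channel.
#' @param prescription_dose_gy prescription dose per fraction in Gy.
#' @param source a [source_model()].
#' @return a `brachy_plan`.
#' @export
brachy_plan <- function(needles, prescription_dose_gy = 6,
                        source = unity_source_model()) {
  if (length(needles) < 1L) stop_cfg("brachy_plan: need >= 1 needle")
  for (n in needles) {
    if (!inherits(n, "dwell_set")) stop_cfg("brachy_plan: needles must be dwell_set objects")
    if (any(n$times < 0)) stop_cfg("brachy_plan: dwell times must be >= 0")
  }
  structure(list(needles = needles,
                 prescription_dose_gy = prescription_dose_gy,
                 source = source), class = "brachy_plan")
}

plan_dwell_matrix <- function(plan) {
  pos <- do.call(rbind, lapply(plan$needles, function(n) n$positions))
  times <- unlist(lapply(plan$needles, function(n) n$times))
  list(pos = pos, times = times)
}

#' TG-43 dose at arbitrary points
#'
#' Sums the point-source TG-43 dose rate over every dwell position, weighted
#' by its dwell time: `dose = sum_k S_K * Lambda * (r0/r_k)^2 * g(r_k) *
#' phi_an(r_k) * t_k`, with tables linearly interpolated and the result in
#' Gy. Distances below `min_r_mm` (default 0.5 mm) are clamped with a
#' warning, since the formalism diverges at the source.
#'
#' @param points numeric (n x 3) matrix of mm coordinates (or length-3
#'   vector).
#' @param plan a [brachy_plan()].
#' @param min_r_mm near-source clamp radius.
#' @param allow_extrapolation if `FALSE` (default), a point beyond the table
#'   radius range raises an error; if `TRUE`, the boundary table value is
#'   held.
#' @return numeric vector of doses in Gy.
#' @export
dose_at_point <- function(points, plan, min_r_mm = 0.5,
                          allow_extrapolation = FALSE) {
  stopifnot(inherits(plan, "brachy_plan"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  src <- plan$source
  dw <- plan_dwell_matrix(plan)
  r_max <- min(max(src$radial_dose$r_mm), max(src$anisotropy$r_mm))
  dose <- numeric(nrow(points))
  clamped <- FALSE
  for (k in seq_len(nrow(dw$pos))) {
    if (dw$times[k] == 0) next
    r <- sqrt((points[, 1] - dw$pos[k, 1])^2 +
              (points[, 2] - dw$pos[k, 2])^2 +
              (points[, 3] - dw$pos[k, 3])^2)
    if (any(r < min_r_mm)) { clamped <- TRUE; r <- pmax(r, min_r_mm) }
    if (any(r > r_max)) {
      if (!allow_extrapolation)
        stop_cfg("dose_at_point: point at r = %.1f mm beyond table range (%.1f mm); set allow_extrapolation = TRUE to clamp",
                 max(r), r_max)
      r <- pmin(r, r_max)
    }
    g <- approx(src$radial_dose$r_mm, src$radial_dose$g, r, rule = 2)$y
    phi <- approx(src$anisotropy$r_mm, src$anisotropy$phi, r, rule = 2)$y
    rate_cgy_h <- src$air_kerma_strength * src$dose_rate_constant *
      (src$reference_r0 / r)^2 * g * phi
    dose <- dose + rate_cgy_h * (dw$times[k] / 3600) / 100
  }
  if (clamped)
    warning(sprintf("dose_at_point: distances clamped at %.2f mm near a dwell", min_r_mm))
  dose
}

#' Dose grid over a volume
#'
#' Evaluates [dose_at_point()] at every voxel centre of the reference grid.
#'
#' @param grid a [volume3d()] supplying geometry (values ignored).
#' @param plan a [brachy_plan()].
#' @param ... passed to [dose_at_point()].
#' @return a [volume3d()] of Gy.
#' @export
dose_grid <- function(grid, plan, ...) {
  stopifnot(inherits(grid, "volume3d"))
  d <- dim(grid$data)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1,
                               k = seq_len(d[3]) - 1))
  pts <- voxel_to_world(grid, idx)
  dose <- dose_at_point(pts, plan, ...)
  volume3d(array(dose, dim = d), grid$spacing, grid$origin)
}

#' Cumulative dose-volume histogram of a structure
#'
#' Builds the cumulative DVH (fraction of the structure receiving at least
#' each dose level) and extracts the standard plan-quality metrics: `D90` and
#' `D100` (minimum dose to the hottest 90% / 100% of the volume, by linear
#' interpolation on the binned curve) and `D2cc` (minimum dose to the hottest
#' 2 cm^3, undefined with a message when the structure is smaller than 2
#' cm^3).
#'
#' @param dose a [volume3d()] of Gy.
#' @param structure a binary [volume3d()] on the same grid, nonempty.
#' @param bin_width_gy histogram bin width (default 0.01 Gy).
#' @return a `dvh_result`: `dose_axis`, `cumulative_volume`, `d90`, `d100`,
#'   `d2cc`, `structure_volume_cc`.
#' @export
compute_dvh <- function(dose, structure, bin_width_gy = 0.01) {
  stopifnot(inherits(dose, "volume3d"), inherits(structure, "volume3d"))
  if (!same_grid(dose, structure)) stop_cfg("compute_dvh: grids differ")
  doses <- dose$data[structure$data > 0]
  if (length(doses) == 0L) stop_cfg("compute_dvh: structure is empty")
  voxel_cc <- prod(dose$spacing) / 1000
  vol_cc <- length(doses) * voxel_cc
  axis <- seq(0, max(doses) + bin_width_gy, by = bin_width_gy)
  cum <- vapply(axis, function(d) mean(doses >= d), 0)
  dx <- function(frac) {
    # smallest dose d with cum(d) <= frac, linearly interpolated
    i <- which(cum < frac)[1]
    if (is.na(i)) return(axis[length(axis)])
    if (i == 1L) return(axis[1])
    d0 <- axis[i - 1]; d1 <- axis[i]
    c0 <- cum[i - 1]; c1 <- cum[i]
    if (c0 == c1) return(d0)
    d0 + (c0 - frac) / (c0 - c1) * (d1 - d0)
  }
  d2cc <- if (vol_cc < 2) {
    message("compute_dvh: structure volume ", sprintf("%.2f", vol_cc),
            " cc < 2 cc; D2cc undefined")
    NA_real_
  } else dx(2 / vol_cc)
  structure(list(dose_axis = axis, cumulative_volume = cum,
                 d90 = dx(0.90), d100 = dx(1.0), d2cc = d2cc,
                 structure_volume_cc = vol_cc), class = "dvh_result")
}

#' @export
print.dvh_result <- function(x, ...) {
  cat(sprintf("<dvh_result> %.2f cc: D90 %.3f Gy, D100 %.3f Gy, D2cc %s\n",
              x$structure_volume_cc, x$d90, x$d100,
              if (is.na(x$d2cc)) "undefined" else sprintf("%.3f Gy", x$d2cc)))
  invisible(x)
}

#' Manual-vs-automatic dose difference
#'
#' Signed difference `D_manual - D_automatic` and signed relative difference
#' `(D_manual - D_automatic) / D_manual` between the same DVH metric from the
#' manually and automatically digitized plan.
#'
#' @param manual,automatic scalar DVH metric values (Gy).
#' @param relative also compute the relative form (requires `manual != 0`).
#' @return list: `absolute_gy`, `relative` (NULL when `relative = FALSE`).
#' @export
dose_difference <- function(manual, automatic, relative = TRUE) {
  abs_diff <- manual - automatic
  rel <- NULL
  if (relative) {
    if (manual == 0)
      stop_cfg("dose_difference: relative difference undefined for manual = 0")
    rel <- abs_diff / manual
  }
  list(absolute_gy = abs_diff, relative = rel)
}

#' Compare a manual and an automatic plan dosimetrically
#'
#' Recomputes the dose grid for both plans on the same reference geometry and
#' reports DVH metric differences: D90/D100 for the target structure and D2cc
#' for every other structure.
#'
#' @param manual,automatic [brachy_plan()] objects (same source model and
#'   dwell times; only dwell geometry differs).
#' @param grid reference [volume3d()].
#' @param structures named list of binary [volume3d()] masks; the element
#'   named `target` is treated as the HR-CTV.
#' @param target name of the target structure (default "hrctv").
#' @param ... passed to [dose_grid()].
#' @return data.frame with one row per structure/metric: `structure`,
#'   `metric`, `manual_gy`, `automatic_gy`, `diff_gy`, `rel_diff`.
#' @export
compare_plans <- function(manual, automatic, grid, structures,
                          target = "hrctv", ...) {
  dm <- dose_grid(grid, manual, ...)
  da <- dose_grid(grid, automatic, ...)
  rows <- list()
  for (nm in names(structures)) {
    if (sum(structures[[nm]]$data) == 0) next
    vm <- compute_dvh(dm, structures[[nm]])
    va <- compute_dvh(da, structures[[nm]])
    metrics <- if (nm == target) c("d90", "d100") else "d2cc"
    for (met in metrics) {
      m <- vm[[met]]; a <- va[[met]]
      if (is.na(m) || is.na(a)) next
      dd <- dose_difference(m, a, relative = m != 0)
      rows[[length(rows) + 1L]] <- data.frame(
        structure = nm, metric = toupper(met), manual_gy = m,
        automatic_gy = a, diff_gy = dd$absolute_gy,
        rel_diff = dd$relative %||% NA_real_)
    }
  }
  do.call(rbind, rows)
}
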