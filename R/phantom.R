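#' Configuration for the synthetic needle phantom
#'
#' Describes a CT-like volume containing 3-6 near-parallel interstitial
#' needles (high-intensity tubes of 1.5 mm diameter by default) inside a
#' soft-tissue ellipse, with an HR-CTV ellipsoid enclosing the implant and
#' organ-at-risk structures nearby. The defaults mirror a clinical planning CT
#' for gynecologic interstitial brachytherapy: 0.8 mm in-plane voxels, 5 mm
#' slices, trocar needles of 1.5 mm diameter; the grid itself defaults to a
#' 64 x 64 x 16 region of interest around the implant.
#'
#' @param grid_shape integer length-3 voxels per axis (nx, ny, nz), each >= 8.
#' @param spacing_mm numeric length-3 voxel size in mm (in-plane, in-plane,
#'   slice thickness).
#' @param n_needles number of needles, >= 1 (clinically 3-6).
#' @param needle_radius_mm needle radius in mm (default 0.75, i.e. 1.5 mm
#'   diameter trocar).
#' @param needle_intensity HU-like intensity of the metal core (default 3000).
#' @param tissue_intensity_mean,tissue_intensity_sd background soft-tissue
#'   level and Gaussian noise sd (HU-like).
#' @param curvature maximum in-plane polynomial deviation of a needle from a
#'   straight path, in mm (0 gives straight needles).
#' @param artifact_strength streak-artifact amplitude, >= 0; applied by
#'   [make_phantom()] via [add_artifacts()] when positive.
#' @param min_separation_mm minimum in-plane distance between any two needle
#'   centerlines at every slice; 0 permits touching/crossing needles.
#' @param tilt_range_deg length-2 range of insertion tilt from the slice
#'   normal, degrees.
#' @param seed integer seed; the whole phantom is a deterministic function of
#'   the configuration.
#' @return A validated `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64L, 64L, 16L),
                           spacing_mm = c(0.8, 0.8, 5.0),
                           n_needles = 4L,
                           needle_radius_mm = 0.75,
                           needle_intensity = 3000,
                           tissue_intensity_mean = 40,
                           tissue_intensity_sd = 15,
                           curvature = 2.0,
                           artifact_strength = 0,
                           min_separation_mm = 3.0,
                           tilt_range_deg = c(0, 5),
                           seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              spacing_mm = as.numeric(spacing_mm),
              n_needles = as.integer(n_needles),
              needle_radius_mm = needle_radius_mm,
              needle_intensity = needle_intensity,
              tissue_intensity_mean = tissue_intensity_mean,
              tissue_intensity_sd = tissue_intensity_sd,
              curvature = curvature,
              artifact_strength = artifact_strength,
              min_separation_mm = min_separation_mm,
              tilt_range_deg = as.numeric(tilt_range_deg),
              seed = as.integer(seed))
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 8L))
    stop_cfg("phantom_config: all grid dimensions must be >= 8")
  if (length(cfg$spacing_mm) != 3L || any(cfg$spacing_mm <= 0))
    stop_cfg("phantom_config: all spacings must be > 0")
  if (cfg$n_needles < 1L) stop_cfg("phantom_config: n_needles must be >= 1")
  if (cfg$needle_radius_mm <= 0)
    stop_cfg("phantom_config: needle_radius_mm must be > 0")
  if (cfg$curvature < 0 || cfg$artifact_strength < 0 ||
      cfg$min_separation_mm < 0)
    stop_cfg("phantom_config: curvature/artifact/separation must be >= 0")
  # a priori feasibility: each needle claims a disc of radius
  # needle_radius + min_separation/2 inside the placement ellipse
  ext <- (cfg$grid_shape[1:2] - 1) * cfg$spacing_mm[1:2]
  place <- 0.30 * ext
  claim <- pi * (cfg$needle_radius_mm + cfg$min_separation_mm / 2)^2
  if (cfg$n_needles * claim > pi * prod(place))
    stop_cfg(paste("phantom_config: grid too small to place %d needles of",
                   "radius %.2f mm at separation %.2f mm"),
             cfg$n_needles, cfg$needle_radius_mm, cfg$min_separation_mm)
  structure(cfg, class = "phantom_config")
}

# Analytic needle curve: x(z) = polynomial in (z - z_center), same for y.
# Returns coefficient vectors (ascending powers) in the centered-z basis.
sample_needle_curve <- function(cfg, z, z_center) {
  ext <- (cfg$grid_shape[1:2] - 1) * cfg$spacing_mm[1:2]
  ctr <- ext / 2
  place <- 0.30 * ext
  repeat {
    u <- runif(2, -1, 1)
    if (sum(u^2) <= 1) break
  }
  x0 <- ctr[1] + u[1] * place[1]
  y0 <- ctr[2] + u[2] * place[2]
  tilt <- runif(1, cfg$tilt_range_deg[1], cfg$tilt_range_deg[2]) * pi / 180
  az <- runif(1, 0, 2 * pi)
  sx <- tan(tilt) * cos(az); sy <- tan(tilt) * sin(az)
  half_span <- (max(z) - min(z)) / 2
  dev <- cfg$curvature * runif(1)
  dev_az <- runif(1, 0, 2 * pi)
  ax <- dev * cos(dev_az) / max(half_span^2, 1e-9)
  ay <- dev * sin(dev_az) / max(half_span^2, 1e-9)
  list(px = c(x0 + sx * (z_center - min(z)), sx, ax),
       py = c(y0 + sy * (z_center - min(z)), sy, ay))
}

eval_poly <- function(coefs, t) {
  out <- numeric(length(t))
  for (p in seq_along(coefs)) out <- out + coefs[p] * t^(p - 1)
  out
}

poly_deriv <- function(coefs) {
  if (length(coefs) <= 1L) return(0)
  coefs[-1] * seq_len(length(coefs) - 1L)
}

# Arc length of the curve (x(z), y(z), z) between two z values, by trapezoid
# quadrature on the closed-form derivative.
poly_arc_length <- function(px, py, z_center, z_from, z_to, n = 2001L) {
  if (z_to == z_from) return(0)
  zg <- seq(z_from, z_to, length.out = n)
  t <- zg - z_center
  dx <- eval_poly(poly_deriv(px), t)
  dy <- eval_poly(poly_deriv(py), t)
  f <- sqrt(dx^2 + dy^2 + 1)
  sum((f[-1] + f[-n]) / 2) * (zg[2] - zg[1])
}

make_trajectory_from_poly <- function(px, py, z_center, z_pts, tip_z,
                                      needle_id = NA_integer_) {
  t <- z_pts - z_center
  pts <- cbind(x = eval_poly(px, t), y = eval_poly(py, t), z = z_pts)
  tip <- c(eval_poly(px, tip_z - z_center), eval_poly(py, tip_z - z_center),
           tip_z)
  len <- poly_arc_length(px, py, z_center, min(z_pts), tip_z)
  structure(list(points = pts, poly_x = px, poly_y = py, z_center = z_center,
                 tip = tip, length_mm = len,
                 degree = length(px) - 1L, flagged = FALSE,
                 needle_id = needle_id),
            class = "trajectory")
}

#' Generate a synthetic needle phantom
#'
#' Builds a CT-like volume plus full analytic ground truth: an instance-
#' labeled needle mask, one analytic centerline trajectory per needle, and
#' HR-CTV / bladder / rectum structure masks. Needles are tubes of the
#' configured radius around smooth z-monotone curves (per-axis polynomials of
#' degree <= 2) sampled inside a soft-tissue ellipse; the true tip sits a
#' random sub-slice distance above the last slice centre, emulating the tip
#' quantization introduced by thick CT slices.
#'
#' @param config a [phantom_config()].
#' @return list with elements `volume` (a [volume3d()]) and `truth` (class
#'   `ground_truth`: `instance_mask` volume3d of integer labels 1..n,
#'   `centerlines` list of `trajectory`, `structures` named list of binary
#'   volume3d masks, `tip_z` numeric per-needle true tip z).
#' @export
make_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, make_phantom_impl(config))
}

make_phantom_impl <- function(cfg) {
  d <- cfg$grid_shape; sp <- cfg$spacing_mm
  z <- (seq_len(d[3]) - 1) * sp[3]
  z_center <- mean(z)
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  ext <- (d[1:2] - 1) * sp[1:2]
  ctr <- ext / 2

  # sample needle curves with rejection on minimum pairwise separation
  curves <- list()
  tries <- 0L
  while (length(curves) < cfg$n_needles) {
    tries <- tries + 1L
    if (tries > 2000L)
      stop_cfg("make_phantom: cannot place %d needles at separation %.2f mm in this grid",
               cfg$n_needles, cfg$min_separation_mm)
    cand <- sample_needle_curve(cfg, z, z_center)
    cx <- eval_poly(cand$px, z - z_center)
    cy <- eval_poly(cand$py, z - z_center)
    margin <- cfg$needle_radius_mm + 1
    inside <- all(((cx - ctr[1]) / (0.40 * ext[1] - margin))^2 +
                  ((cy - ctr[2]) / (0.40 * ext[2] - margin))^2 <= 1)
    if (!inside) next
    ok <- TRUE
    for (cv in curves) {
      ox <- eval_poly(cv$px, z - z_center)
      oy <- eval_poly(cv$py, z - z_center)
      if (min(sqrt((cx - ox)^2 + (cy - oy)^2)) < cfg$min_separation_mm) {
        ok <- FALSE; break
      }
    }
    if (ok) curves[[length(curves) + 1L]] <- cand
  }

  tip_z <- max(z) + runif(cfg$n_needles, 0, sp[3] / 2)

  # rasterize: per slice, voxels within needle_radius of a centerline point;
  # contested voxels go to the nearest centerline
  inst <- array(0L, dim = d)
  best_d2 <- array(Inf, dim = d[1:2])
  r2 <- cfg$needle_radius_mm^2
  for (k in seq_len(d[3])) {
    best_d2[] <- Inf
    lab_k <- matrix(0L, d[1], d[2])
    for (n in seq_along(curves)) {
      cx <- eval_poly(curves[[n]]$px, z[k] - z_center)
      cy <- eval_poly(curves[[n]]$py, z[k] - z_center)
      d2 <- outer((xs - cx)^2, (ys - cy)^2, `+`)
      take <- d2 <= r2 & d2 < best_d2
      lab_k[take] <- n
      best_d2[take] <- d2[take]
    }
    inst[, , k] <- lab_k
  }

  # intensities: air outside body ellipse, noisy soft tissue inside, metal core
  body <- outer(((xs - ctr[1]) / (0.45 * ext[1]))^2,
                ((ys - ctr[2]) / (0.45 * ext[2]))^2, `+`) <= 1
  vol <- array(-1000, dim = d)
  noise <- array(rnorm(prod(d), cfg$tissue_intensity_mean,
                       cfg$tissue_intensity_sd), dim = d)
  body3 <- array(rep(body, d[3]), dim = d)
  vol[body3] <- noise[body3]
  vol[inst > 0L] <- cfg$needle_intensity

  # analytic centerlines as trajectory objects
  centerlines <- lapply(seq_along(curves), function(n)
    make_trajectory_from_poly(curves[[n]]$px, curves[[n]]$py, z_center, z,
                              tip_z[n], needle_id = n))

  structures <- make_structures(inst, d, sp, xs, ys, z)

  volume <- volume3d(vol, spacing = sp, origin = c(0, 0, 0))
  truth <- structure(list(
    instance_mask = volume3d(inst * 1.0, spacing = sp, origin = c(0, 0, 0)),
    centerlines = centerlines,
    structures = structures,
    tip_z = tip_z,
    config = cfg), class = "ground_truth")

  if (cfg$artifact_strength > 0)
    volume <- add_artifacts(volume, truth, cfg$artifact_strength,
                            seed = derive_seed(cfg$seed, "artifacts"))
  list(volume = volume, truth = truth)
}

# HR-CTV ellipsoid around the implant, scaled so that it encloses at least
# 95% of needle voxels (analytically, independent of grid clipping), with
# bladder (anterior) and rectum (posterior) ellipsoids kept disjoint.
make_structures <- function(inst, d, sp, xs, ys, z) {
  idx <- which(inst > 0L, arr.ind = TRUE)
  w <- cbind(xs[idx[, 1]], ys[idx[, 2]], z[idx[, 3]])
  cen <- colMeans(w)
  half <- pmax(apply(abs(sweep(w, 2, cen)), 2, max), sp)
  q <- sqrt(((w[, 1] - cen[1]) / half[1])^2 + ((w[, 2] - cen[2]) / half[2])^2 +
            ((w[, 3] - cen[3]) / half[3])^2)
  semi <- 1.05 * stats::quantile(q, 0.95) * half
  ellipsoid_mask <- function(cen, semi) {
    q <- outer(((xs - cen[1]) / semi[1])^2, ((ys - cen[2]) / semi[2])^2, `+`)
    arr <- array(0, dim = d)
    for (k in seq_len(d[3]))
      arr[, , k] <- (q + ((z[k] - cen[3]) / semi[3])^2 <= 1) * 1.0
    arr
  }
  ctv <- ellipsoid_mask(cen, semi)
  ext <- (d[1:2] - 1) * sp[1:2]
  oar_semi <- c(0.18 * ext[1], 0.10 * ext[2], (max(z) - min(z)) / 2 + sp[3])
  gap <- 1.0
  # keep the OAR centres on-grid even when the CTV is wide
  by <- min(cen[2] + semi[2] + oar_semi[2] + gap, ext[2])
  ry <- max(cen[2] - semi[2] - oar_semi[2] - gap, 0)
  bladder <- ellipsoid_mask(c(cen[1], by, cen[3]), oar_semi)
  rectum <- ellipsoid_mask(c(cen[1], ry, cen[3]), oar_semi)
  # enforce mutual disjointness (clipping can only shrink the OARs)
  bladder[ctv > 0] <- 0
  rectum[ctv > 0 | bladder > 0] <- 0
  lapply(list(hrctv = ctv, bladder = bladder, rectum = rectum),
         function(a) volume3d(a, spacing = sp, origin = c(0, 0, 0)))
}

#' Add streak artifacts around needles
#'
#' Superimposes radial streak perturbations emanating from each needle's
#' cross-section in every slice, a light-weight stand-in for the metal
#' artifacts that make clinical needle CTs hard to segment. The perturbation
#' field is linear in `strength`; needle-core voxels never drop below half the
#' configured core intensity.
#'
#' @param volume a [volume3d()].
#' @param truth the `ground_truth` of the same phantom.
#' @param strength artifact amplitude, >= 0; 0 returns the input unchanged.
#' @param seed integer seed for the streak pattern.
#' @return the perturbed `volume3d`.
#' @export
add_artifacts <- function(volume, truth, strength, seed = 1L) {
  stopifnot(inherits(volume, "volume3d"), inherits(truth, "ground_truth"))
  if (strength < 0) stop_cfg("add_artifacts: strength must be >= 0")
  if (strength == 0) return(volume)
  field <- with_seed(seed, artifact_field(volume, truth))
  out <- volume$data + strength * field
  core <- truth$instance_mask$data > 0
  floor_val <- truth$config$needle_intensity / 2
  out[core] <- pmax(out[core], floor_val)
  volume3d(out, spacing = volume$spacing, origin = volume$origin)
}

# Unit-strength streak field: per needle, an angular cosine fan decaying
# exponentially with in-plane distance from the needle centre.
artifact_field <- function(volume, truth) {
  d <- dim(volume$data); sp <- volume$spacing
  xs <- (seq_len(d[1]) - 1) * sp[1] + volume$origin[1]
  ys <- (seq_len(d[2]) - 1) * sp[2] + volume$origin[2]
  field <- array(0, dim = d)
  for (traj in truth$centerlines) {
    n_spokes <- sample(6:12, 1)
    phase <- runif(1, 0, 2 * pi)
    amp <- runif(1, 0.5, 1)
    for (k in seq_len(d[3])) {
      zk <- volume$origin[3] + (k - 1) * sp[3]
      t <- zk - traj$z_center
      cx <- eval_poly(traj$poly_x, t); cy <- eval_poly(traj$poly_y, t)
      dx <- xs - cx
      dy <- ys - cy
      r <- sqrt(outer(dx^2, dy^2, `+`))
      theta <- atan2(matrix(rep(dy, each = d[1]), d[1], d[2]),
                     matrix(rep(dx, d[2]), d[1], d[2]))
      field[, , k] <- field[, , k] +
        amp * 100 * cos(n_spokes * theta + phase) * exp(-r / 15)
    }
  }
  field
}

#' Write phantom ground truth to disk
#'
#' Writes the instance mask and structure masks as NIfTI and the analytic
#' centerlines as JSON (per needle: mm points, polynomial coefficients in the
#' centered-z basis, tip point, arc length).
#'
#' @param truth a `ground_truth`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_ground_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(file.path(dir, "instance_mask.nii.gz"))
  write_volume(truth$instance_mask, paths[1])
  for (nm in names(truth$structures)) {
    p <- file.path(dir, paste0("structure_", nm, ".nii.gz"))
    write_volume(truth$structures[[nm]], p)
    paths <- c(paths, p)
  }
  cl <- lapply(truth$centerlines, function(tr) list(
    needle_id = tr$needle_id,
    points_mm = unname(apply(tr$points, 1, as.numeric, simplify = FALSE)),
    poly_x = as.numeric(tr$poly_x), poly_y = as.numeric(tr$poly_y),
    z_center = tr$z_center, tip_mm = as.numeric(tr$tip),
    length_mm = tr$length_mm))
  pj <- file.path(dir, "centerlines.json")
  jsonlite::write_json(cl, pj, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, pj))
}
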