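# Independent brute-force oracles used to validate the package's metric and
# network implementations. These deliberately use naive loops and must stay
# independent of the implementations they check.

oracle_dice <- function(P, T) {
  inter <- 0; np <- 0; nt <- 0
  for (i in seq_along(P)) {
    p <- P[i] > 0; t <- T[i] > 0
    if (p && t) inter <- inter + 1
    if (p) np <- np + 1
    if (t) nt <- nt + 1
  }
  if (np + nt == 0) return(1)
  2 * inter / (np + nt)
}

oracle_jaccard <- function(P, T) {
  inter <- 0; uni <- 0
  for (i in seq_along(P)) {
    p <- P[i] > 0; t <- T[i] > 0
    if (p && t) inter <- inter + 1
    if (p || t) uni <- uni + 1
  }
  if (uni == 0) return(1)
  inter / uni
}

# Quadruple-loop Hausdorff over voxel-centre coordinates in mm.
oracle_hausdorff <- function(A, B, spacing) {
  ca <- which(A > 0, arr.ind = TRUE)
  cb <- which(B > 0, arr.ind = TRUE)
  directed <- function(from, to) {
    worst <- 0
    for (i in seq_len(nrow(from))) {
      best <- Inf
      for (j in seq_len(nrow(to))) {
        d <- sqrt(sum(((from[i, ] - to[j, ]) * spacing)^2))
        if (d < best) best <- d
      }
      if (best > worst) worst <- best
    }
    worst
  }
  max(directed(ca, cb), directed(cb, ca))
}

# Double-sum shaft error: mean over needles of the mean in-plane distance
# between the two fitted curves at shared slice z's.
oracle_shaft <- function(pairs) {
  per <- numeric(0)
  for (p in pairs) {
    za <- p$pred$points[, 3]; zb <- p$truth$points[, 3]
    total <- 0; m <- 0
    for (z in za) {
      if (!any(abs(zb - z) < 1e-6)) next
      ta <- z - p$pred$z_center; tb <- z - p$truth$z_center
      px <- sum(p$pred$poly_x * ta^(seq_along(p$pred$poly_x) - 1))
      py <- sum(p$pred$poly_y * ta^(seq_along(p$pred$poly_y) - 1))
      tx <- sum(p$truth$poly_x * tb^(seq_along(p$truth$poly_x) - 1))
      ty <- sum(p$truth$poly_y * tb^(seq_along(p$truth$poly_y) - 1))
      total <- total + sqrt((px - tx)^2 + (py - ty)^2)
      m <- m + 1
    }
    if (m > 0) per <- c(per, total / m)
  }
  mean(per)
}

# Voxel-by-voxel transcription of the additive attention gate: for each voxel
# of x's grid, q = psi' ReLU(Wx' x + Wg' g_up + bxg) + bpsi, alpha =
# sigmoid(q), output x * alpha. The gating signal is first resampled to x's
# grid by trilinear interpolation (computed here with explicit per-axis
# weights, independent of the C++ kernel).
oracle_attention_gate <- function(x, g, params) {
  xd <- dim(x)[1:3]; gd <- dim(g)[1:3]
  cx <- dim(x)[4]; cg <- dim(g)[4]
  taps <- function(n_out, n_in) {
    lapply(seq_len(n_out), function(i) {
      u <- (i - 0.5) * n_in / n_out - 0.5
      u <- min(max(u, 0), n_in - 1)
      i0 <- floor(u)
      list(i0 = i0 + 1, i1 = min(i0 + 1, n_in - 1) + 1, w = u - i0)
    })
  }
  tx <- taps(xd[1], gd[1]); ty <- taps(xd[2], gd[2]); tz <- taps(xd[3], gd[3])
  alpha <- array(0, dim = xd)
  gated <- array(0, dim = dim(x))
  for (i in seq_len(xd[1])) for (j in seq_len(xd[2])) for (k in seq_len(xd[3])) {
    g_up <- numeric(cg)
    for (c in seq_len(cg)) {
      acc <- 0
      for (a in 1:2) for (b in 1:2) for (cc in 1:2) {
        wi <- if (a == 1) 1 - tx[[i]]$w else tx[[i]]$w
        wj <- if (b == 1) 1 - ty[[j]]$w else ty[[j]]$w
        wk <- if (cc == 1) 1 - tz[[k]]$w else tz[[k]]$w
        ii <- if (a == 1) tx[[i]]$i0 else tx[[i]]$i1
        jj <- if (b == 1) ty[[j]]$i0 else ty[[j]]$i1
        kk <- if (cc == 1) tz[[k]]$i0 else tz[[k]]$i1
        acc <- acc + wi * wj * wk * g[ii, jj, kk, c]
      }
      g_up[c] <- acc
    }
    xv <- x[i, j, k, ]
    a_vec <- as.vector(t(params$Wx) %*% xv + t(params$Wg) %*% g_up) + params$bxg
    h <- pmax(a_vec, 0)
    q <- sum(params$psi * h) + params$bpsi
    al <- 1 / (1 + exp(-q))
    alpha[i, j, k] <- al
    gated[i, j, k, ] <- xv * al
  }
  list(gated = gated, alpha = alpha)
}

# TG-43 point-source dose re-implemented with explicit loops.
oracle_dose <- function(points, plan, min_r_mm = 0.5) {
  src <- plan$source
  out <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    total <- 0
    for (ndl in plan$needles) {
      for (k in seq_len(nrow(ndl$positions))) {
        r <- sqrt(sum((points[i, ] - ndl$positions[k, ])^2))
        r <- max(r, min_r_mm)
        g <- approx(src$radial_dose$r_mm, src$radial_dose$g, r, rule = 2)$y
        phi <- approx(src$anisotropy$r_mm, src$anisotropy$phi, r, rule = 2)$y
        rate <- src$air_kerma_strength * src$dose_rate_constant *
          (src$reference_r0 / r)^2 * g * phi
        total <- total + rate * ndl$times[k] / 3600 / 100
      }
    }
    out[i] <- total
  }
  out
}

# Straight vertical trajectory fixture with controllable length/offset.
straight_traj <- function(x0 = 0, y0 = 0, z_from = 0, z_to = 50, n = 11,
                          id = 1L) {
  z <- seq(z_from, z_to, length.out = n)
  fit_trajectory(cbind(x0, y0, z), degree = 1, needle_id = id)
}

binary_mask_volume <- function(truth) {
  volume3d((truth$instance_mask$data > 0) * 1.0,
           truth$instance_mask$spacing, truth$instance_mask$origin)
}

phantom_samples <- function(phantoms) {
  lapply(phantoms, function(p) list(volume = p$volume,
                                    mask = binary_mask_volume(p$truth)))
}
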