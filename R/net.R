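#' Segmentation network configuration
#'
#' Describes a 3D encoder-decoder (U-Net) with two 3x3x3 convolutions per
#' resolution level (zero padding, group normalization, ReLU), 2x max-pooling
#' between encoder levels, stride-2 transposed convolutions in the decoder,
#' skip concatenation optionally gated by additive attention gates, and a
#' 1x1x1 sigmoid head. Channels double per level from `base_channels`.
#'
#' @param depth number of resolution levels (>= 2). The full clinical-scale topology
#'   is `depth = 5` (see [count_conv_layers()]); the test-scale default is 4.
#' @param base_channels channels at the finest level; must be divisible by
#'   `gn_groups`.
#' @param use_attention gate each skip connection with an additive attention
#'   gate (CNN + AG) or not (plain CNN).
#' @param gn_groups group count for group normalization.
#' @param gn_encoder_only if `TRUE`, group normalization is applied in the
#'   encoder only; by default it follows every 3x3x3 convolution.
#' @param in_channels,out_channels input and output channel counts.
#' @return A validated `net_config`.
#' @export
net_config <- function(depth = 4L, base_channels = 16L, use_attention = TRUE,
                       gn_groups = 4L, gn_encoder_only = FALSE,
                       in_channels = 1L, out_channels = 1L) {
  cfg <- list(depth = as.integer(depth),
              base_channels = as.integer(base_channels),
              use_attention = isTRUE(use_attention),
              gn_groups = as.integer(gn_groups),
              gn_encoder_only = isTRUE(gn_encoder_only),
              in_channels = as.integer(in_channels),
              out_channels = as.integer(out_channels))
  if (cfg$depth < 2L) stop_cfg("net_config: depth must be >= 2")
  if (cfg$base_channels < 1L || cfg$base_channels %% cfg$gn_groups != 0L)
    stop_cfg("net_config: base_channels must be a positive multiple of gn_groups")
  if (cfg$in_channels != 1L || cfg$out_channels != 1L)
    stop_cfg("net_config: only single-channel input/output is supported")
  structure(cfg, class = "net_config")
}

#' Soft Dice loss configuration
#' @param epsilon smoothing constant added to the denominator (> 0).
#' @return a `loss_config`.
#' @export
loss_config <- function(epsilon = 1e-4) {
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop_cfg("loss_config: epsilon must be > 0")
  structure(list(epsilon = epsilon), class = "loss_config")
}

#' Soft Dice loss
#'
#' `1 - 2 * sum(pred * target) / (sum(pred) + sum(target) + epsilon)`: the
#' overlap-based loss used to train the network, robust to the extreme
#' foreground/background imbalance of thin needle masks. Differentiable in
#' `pred`; the internal gradient is available to the training loop.
#'
#' @param pred numeric array of probabilities in \[0, 1\].
#' @param target binary array of the same shape.
#' @param cfg a [loss_config()].
#' @return scalar loss in \[0, 1\].
#' @export
soft_dice_loss <- function(pred, target, cfg = loss_config()) {
  if (!identical(dim(pred) %||% length(pred), dim(target) %||% length(target)))
    stop_cfg("soft_dice_loss: pred and target shapes differ")
  p <- as.numeric(pred); t <- as.numeric(target)
  if (min(p) < -1e-9 || max(p) > 1 + 1e-9)
    stop_cfg("soft_dice_loss: pred values must lie in [0, 1]")
  1 - 2 * sum(p * t) / (sum(p) + sum(t) + cfg$epsilon)
}

# Gradient of soft_dice_loss with respect to pred (same shape as pred).
soft_dice_grad <- function(pred, target, cfg = loss_config()) {
  p <- as.numeric(pred); t <- as.numeric(target)
  D <- sum(p) + sum(t) + cfg$epsilon
  S <- sum(p * t)
  g <- -2 * t / D + 2 * S / D^2
  if (!is.null(dim(pred))) dim(g) <- dim(pred)
  g
}

#' Count convolutional layers of a configuration
#'
#' Counting convention: the two 3x3x3 convolutions of every encoder and
#' decoder level plus the stride-2 up-convolutions, i.e. `5 * depth - 3`;
#' the final 1x1x1 sigmoid head is excluded unless `include_head`. Under this
#' convention the full-scale `depth = 5` network has 22 convolutional
#' layers.
#'
#' @param config a [net_config()].
#' @param include_head also count the 1x1x1 output convolution.
#' @return integer layer count.
#' @export
count_conv_layers <- function(config, include_head = FALSE) {
  stopifnot(inherits(config, "net_config"))
  2L * config$depth + 3L * (config$depth - 1L) + as.integer(include_head)
}

level_channels <- function(cfg, l) cfg$base_channels * 2L^(l - 1L)

he_mat <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

#' Build a segmentation model
#'
#' Initializes all parameters (He-normal weights, zero biases, unit group-norm
#' gains) for the configured topology. The model is a plain list of named
#' parameter arrays plus its configuration, updated in place by the training
#' loop.
#'
#' @param config a [net_config()].
#' @param seed integer seed for the weight initialization.
#' @return an object of class `seg_model`.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "net_config"))
  with_seed(seed, build_model_impl(config))
}

build_model_impl <- function(cfg) {
  P <- list()
  add_gn <- function(prefix, C) {
    P[[paste0(prefix, ".gamma")]] <<- rep(1, C)
    P[[paste0(prefix, ".beta")]] <<- rep(0, C)
  }
  for (l in seq_len(cfg$depth)) {
    cin <- if (l == 1L) cfg$in_channels else level_channels(cfg, l - 1L)
    cl <- level_channels(cfg, l)
    P[[sprintf("enc%d.conv1.W", l)]] <- he_mat(27L * cin, cl, 27L * cin)
    P[[sprintf("enc%d.conv1.b", l)]] <- rep(0, cl)
    add_gn(sprintf("enc%d.gn1", l), cl)
    P[[sprintf("enc%d.conv2.W", l)]] <- he_mat(27L * cl, cl, 27L * cl)
    P[[sprintf("enc%d.conv2.b", l)]] <- rep(0, cl)
    add_gn(sprintf("enc%d.gn2", l), cl)
  }
  for (l in rev(seq_len(cfg$depth - 1L))) {
    cg <- level_channels(cfg, l + 1L)   # coarse (gating) channels
    cl <- level_channels(cfg, l)
    P[[sprintf("dec%d.up.W", l)]] <- he_mat(8L * cg, cl, 8L * cg)
    P[[sprintf("dec%d.up.b", l)]] <- rep(0, cl)
    if (cfg$use_attention) {
      fint <- max(1L, cl %/% 2L)
      P[[sprintf("dec%d.att.Wx", l)]] <- he_mat(cl, fint, cl)
      P[[sprintf("dec%d.att.Wg", l)]] <- he_mat(cg, fint, cg)
      P[[sprintf("dec%d.att.bxg", l)]] <- rep(0, fint)
      P[[sprintf("dec%d.att.psi", l)]] <- he_mat(fint, 1L, fint)
      P[[sprintf("dec%d.att.bpsi", l)]] <- 0
    }
    P[[sprintf("dec%d.conv1.W", l)]] <- he_mat(27L * 2L * cl, cl, 27L * 2L * cl)
    P[[sprintf("dec%d.conv1.b", l)]] <- rep(0, cl)
    P[[sprintf("dec%d.conv2.W", l)]] <- he_mat(27L * cl, cl, 27L * cl)
    P[[sprintf("dec%d.conv2.b", l)]] <- rep(0, cl)
    if (!cfg$gn_encoder_only) {
      add_gn(sprintf("dec%d.gn1", l), cl)
      add_gn(sprintf("dec%d.gn2", l), cl)
    }
  }
  P[["head.W"]] <- he_mat(level_channels(cfg, 1L), 1L, level_channels(cfg, 1L))
  P[["head.b"]] <- 0
  structure(list(cfg = cfg, params = P), class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  n <- sum(vapply(x$params, length, 1L))
  cat(sprintf("<seg_model> depth %d, base %d channels, %s, %d parameters\n",
              x$cfg$depth, x$cfg$base_channels,
              if (x$cfg$use_attention) "CNN+AG" else "CNN", n))
  invisible(x)
}

# ---- group normalization ---------------------------------------------------

gn_eps <- 1e-5

gn_fw <- function(x, gamma, beta, groups) {
  C <- ncol(x); cg <- C %/% groups
  xhat <- x
  inv_std <- numeric(groups)
  for (g in seq_len(groups)) {
    cols <- ((g - 1L) * cg + 1L):(g * cg)
    blk <- x[, cols, drop = FALSE]
    mu <- mean(blk)
    v <- mean((blk - mu)^2)
    inv_std[g] <- 1 / sqrt(v + gn_eps)
    xhat[, cols] <- (blk - mu) * inv_std[g]
  }
  y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(y = y, xhat = xhat, inv_std = inv_std, gamma = gamma, groups = groups)
}

gn_bw <- function(dY, cache) {
  xhat <- cache$xhat; groups <- cache$groups
  C <- ncol(dY); cg <- C %/% groups
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, cache$gamma, `*`)
  dx <- dxhat
  for (g in seq_len(groups)) {
    cols <- ((g - 1L) * cg + 1L):(g * cg)
    dh <- dxhat[, cols, drop = FALSE]
    xh <- xhat[, cols, drop = FALSE]
    mu1 <- mean(dh)
    mu2 <- mean(dh * xh)
    dx[, cols] <- cache$inv_std[g] * (dh - mu1 - xh * mu2)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- attention gate ---------------------------------------------------------

# x: (Nf x Cx) fine feature map, g: (Ng x Cg) coarse gating signal. The
# gating signal is trilinearly resampled to x's grid, combined additively
# through the 1x1x1 maps Wx/Wg, passed through ReLU, reduced to one channel by
# psi, and squashed by a sigmoid into attention coefficients alpha in [0, 1]
# that scale x voxelwise.
ag_fw <- function(x, xdims, g, gdims, Wx, Wg, bxg, psi, bpsi) {
  if (ncol(x) != nrow(Wx)) stop_cfg("attention_gate: x channels (%d) do not match Wx (%d)", ncol(x), nrow(Wx))
  if (ncol(g) != nrow(Wg)) stop_cfg("attention_gate: g channels (%d) do not match Wg (%d)", ncol(g), nrow(Wg))
  g_up <- cpp_resample_trilinear(g, as.integer(gdims), as.integer(xdims))
  a <- sweep(x %*% Wx + g_up %*% Wg, 2L, bxg, `+`)
  h <- pmax(a, 0)
  q <- as.vector(h %*% psi) + bpsi
  alpha <- 1 / (1 + exp(-q))
  xg <- x * alpha
  list(xg = xg, alpha = alpha,
       cache = list(x = x, g_up = g_up, relu_mask = a > 0, h = h,
                    alpha = alpha, xdims = xdims, gdims = gdims))
}

ag_bw <- function(dxg, cache, Wx, Wg, psi) {
  x <- cache$x; alpha <- cache$alpha
  dalpha <- rowSums(dxg * x)
  dx <- dxg * alpha
  dq <- dalpha * alpha * (1 - alpha)
  dpsi <- crossprod(cache$h, dq)
  dbpsi <- sum(dq)
  dh <- tcrossprod(dq, as.vector(psi))
  da <- dh * cache$relu_mask
  dWx <- crossprod(x, da)
  dWg <- crossprod(cache$g_up, da)
  dbxg <- colSums(da)
  dx <- dx + tcrossprod(da, Wx)
  dg_up <- tcrossprod(da, Wg)
  dg <- cpp_resample_trilinear_adj(dg_up, as.integer(cache$gdims),
                                   as.integer(cache$xdims))
  list(dx = dx, dg = dg, dWx = dWx, dWg = dWg, dbxg = dbxg,
       dpsi = dpsi, dbpsi = dbpsi)
}

#' Additive attention gate
#'
#' Gates a fine-level feature map `x` with a coarser gating signal `g`:
#' `alpha = sigmoid(psi' ReLU(Wx' x + Wg' g_up + b_xg) + b_psi)`, where `g_up`
#' is `g` trilinearly resampled to `x`'s grid, and the gated output is
#' `x * alpha` voxelwise. All coefficients lie in \[0, 1\].
#'
#' @param x numeric 4D array `(nx, ny, nz, Cx)`, the fine feature map.
#' @param g numeric 4D array `(gx, gy, gz, Cg)`, the coarser gating signal
#'   (each spatial dim <= x's).
#' @param params list with `Wx` (Cx x F), `Wg` (Cg x F), `bxg` (length F),
#'   `psi` (F x 1), `bpsi` (scalar).
#' @return list with `gated` (array like `x`) and `alpha` (3D array of
#'   attention coefficients on `x`'s grid).
#' @export
attention_gate <- function(x, g, params) {
  if (length(dim(x)) != 4L || length(dim(g)) != 4L)
    stop_cfg("attention_gate: x and g must be 4D arrays (nx, ny, nz, C)")
  xd <- dim(x)[1:3]; gd <- dim(g)[1:3]
  if (any(gd > xd))
    stop_cfg("attention_gate: g spatial size must not exceed x's")
  xm <- matrix(x, prod(xd), dim(x)[4])
  gm <- matrix(g, prod(gd), dim(g)[4])
  r <- ag_fw(xm, xd, gm, gd, params$Wx, params$Wg, params$bxg,
             params$psi, params$bpsi)
  list(gated = array(r$xg, dim = dim(x)),
       alpha = array(r$alpha, dim = xd))
}

# ---- full network forward / backward ---------------------------------------

relu_fw <- function(x) list(y = pmax(x, 0), mask = x > 0)

conv_block_fw <- function(x, dims, P, prefix, cfg, use_gn) {
  cache <- list(x = x, dims = dims, use_gn = use_gn)
  y1 <- cpp_conv3d_fw(x, as.integer(dims), P[[paste0(prefix, ".conv1.W")]],
                      P[[paste0(prefix, ".conv1.b")]])
  if (use_gn) {
    cache$gn1 <- gn_fw(y1, P[[paste0(prefix, ".gn1.gamma")]],
                       P[[paste0(prefix, ".gn1.beta")]], cfg$gn_groups)
    y1 <- cache$gn1$y
  }
  r1 <- relu_fw(y1); cache$m1 <- r1$mask; cache$a1 <- r1$y
  y2 <- cpp_conv3d_fw(r1$y, as.integer(dims), P[[paste0(prefix, ".conv2.W")]],
                      P[[paste0(prefix, ".conv2.b")]])
  if (use_gn) {
    cache$gn2 <- gn_fw(y2, P[[paste0(prefix, ".gn2.gamma")]],
                       P[[paste0(prefix, ".gn2.beta")]], cfg$gn_groups)
    y2 <- cache$gn2$y
  }
  r2 <- relu_fw(y2); cache$m2 <- r2$mask
  list(out = r2$y, cache = cache)
}

conv_block_bw <- function(dY, cache, P, prefix, grads) {
  dy2 <- dY * cache$m2
  if (cache$use_gn) {
    g2 <- gn_bw(dy2, cache$gn2)
    grads[[paste0(prefix, ".gn2.gamma")]] <- g2$dgamma
    grads[[paste0(prefix, ".gn2.beta")]] <- g2$dbeta
    dy2 <- g2$dx
  }
  b2 <- cpp_conv3d_bw(cache$a1, as.integer(cache$dims),
                      P[[paste0(prefix, ".conv2.W")]], dy2)
  grads[[paste0(prefix, ".conv2.W")]] <- b2$dW
  grads[[paste0(prefix, ".conv2.b")]] <- as.vector(b2$db)
  dy1 <- b2$dX * cache$m1
  if (cache$use_gn) {
    g1 <- gn_bw(dy1, cache$gn1)
    grads[[paste0(prefix, ".gn1.gamma")]] <- g1$dgamma
    grads[[paste0(prefix, ".gn1.beta")]] <- g1$dbeta
    dy1 <- g1$dx
  }
  b1 <- cpp_conv3d_bw(cache$x, as.integer(cache$dims),
                      P[[paste0(prefix, ".conv1.W")]], dy1)
  grads[[paste0(prefix, ".conv1.W")]] <- b1$dW
  grads[[paste0(prefix, ".conv1.b")]] <- as.vector(b1$db)
  list(dx = b1$dX, grads = grads)
}

# Forward pass. x is a (Nvox x 1) matrix over grid `dims`. Returns the
# sigmoid probability map (Nvox vector) and, optionally, the cache needed for
# backpropagation.
net_forward <- function(model, x, dims, keep_cache = TRUE) {
  cfg <- model$cfg; P <- model$params
  div <- 2L^(cfg$depth - 1L)
  if (any(dims %% div != 0L))
    stop_cfg("net_forward: spatial dims (%s) must be divisible by 2^(depth-1) = %d",
             paste(dims, collapse = "x"), div)
  cache <- list(enc = vector("list", cfg$depth),
                pool = vector("list", cfg$depth - 1L),
                dec = vector("list", cfg$depth - 1L))
  skips <- vector("list", cfg$depth - 1L)
  cur <- x; cur_dims <- dims
  for (l in seq_len(cfg$depth)) {
    cb <- conv_block_fw(cur, cur_dims, P, sprintf("enc%d", l), cfg, TRUE)
    cache$enc[[l]] <- cb$cache
    if (l < cfg$depth) {
      skips[[l]] <- list(x = cb$out, dims = cur_dims)
      mp <- cpp_maxpool_fw(cb$out, as.integer(cur_dims))
      cache$pool[[l]] <- list(idx = mp$idx, n_in = nrow(cb$out))
      cur <- mp$out
      cur_dims <- cur_dims %/% 2L
    } else cur <- cb$out
  }
  for (l in rev(seq_len(cfg$depth - 1L))) {
    dc <- list(g_dims = cur_dims, skip_dims = skips[[l]]$dims)
    if (cfg$use_attention) {
      ag <- ag_fw(skips[[l]]$x, skips[[l]]$dims, cur, cur_dims,
                  P[[sprintf("dec%d.att.Wx", l)]],
                  P[[sprintf("dec%d.att.Wg", l)]],
                  P[[sprintf("dec%d.att.bxg", l)]],
                  P[[sprintf("dec%d.att.psi", l)]],
                  P[[sprintf("dec%d.att.bpsi", l)]])
      xg <- ag$xg
      dc$ag <- ag$cache
      dc$alpha <- ag$alpha
    } else xg <- skips[[l]]$x
    dc$g <- cur
    up_raw <- cpp_upconv_fw(cur, as.integer(cur_dims),
                            P[[sprintf("dec%d.up.W", l)]],
                            P[[sprintf("dec%d.up.b", l)]])
    ur <- relu_fw(up_raw)
    dc$up_mask <- ur$mask
    cat_in <- cbind(xg, ur$y)
    cb <- conv_block_fw(cat_in, skips[[l]]$dims, P, sprintf("dec%d", l), cfg,
                        !cfg$gn_encoder_only)
    dc$block <- cb$cache
    dc$cx <- ncol(xg)
    cache$dec[[l]] <- dc
    cur <- cb$out
    cur_dims <- skips[[l]]$dims
  }
  logits <- as.vector(cur %*% P[["head.W"]]) + P[["head.b"]]
  y <- 1 / (1 + exp(-logits))
  cache$head_in <- if (keep_cache) cur else NULL
  cache$y <- y
  list(y = y, cache = if (keep_cache) cache else NULL)
}

# Backward pass: dY is dLoss/dY over the probability map. Returns a named
# list of gradients aligned with model$params.
net_backward <- function(model, cache, dY) {
  cfg <- model$cfg; P <- model$params
  grads <- list()
  y <- cache$y
  dlogits <- dY * y * (1 - y)
  grads[["head.W"]] <- crossprod(cache$head_in, dlogits)
  grads[["head.b"]] <- sum(dlogits)
  dcur <- tcrossprod(dlogits, as.vector(P[["head.W"]]))
  dskip <- vector("list", cfg$depth - 1L)
  for (l in seq_len(cfg$depth - 1L)) {
    dc <- cache$dec[[l]]
    cb <- conv_block_bw(dcur, dc$block, P, sprintf("dec%d", l), grads)
    grads <- cb$grads
    cx <- dc$cx
    dxg <- cb$dx[, seq_len(cx), drop = FALSE]
    dup <- cb$dx[, cx + seq_len(ncol(cb$dx) - cx), drop = FALSE]
    dup <- dup * dc$up_mask
    ub <- cpp_upconv_bw(dc$g, as.integer(dc$g_dims),
                        P[[sprintf("dec%d.up.W", l)]], dup)
    grads[[sprintf("dec%d.up.W", l)]] <- ub$dW
    grads[[sprintf("dec%d.up.b", l)]] <- as.vector(ub$db)
    dg <- ub$dX
    if (cfg$use_attention) {
      ab <- ag_bw(dxg, dc$ag,
                  P[[sprintf("dec%d.att.Wx", l)]],
                  P[[sprintf("dec%d.att.Wg", l)]],
                  P[[sprintf("dec%d.att.psi", l)]])
      grads[[sprintf("dec%d.att.Wx", l)]] <- ab$dWx
      grads[[sprintf("dec%d.att.Wg", l)]] <- ab$dWg
      grads[[sprintf("dec%d.att.bxg", l)]] <- ab$dbxg
      grads[[sprintf("dec%d.att.psi", l)]] <- ab$dpsi
      grads[[sprintf("dec%d.att.bpsi", l)]] <- ab$dbpsi
      dskip[[l]] <- ab$dx
      dg <- dg + ab$dg
    } else dskip[[l]] <- dxg
    dcur <- dg
  }
  for (l in rev(seq_len(cfg$depth))) {
    if (l < cfg$depth) {
      dpool <- cpp_maxpool_bw(cache$pool[[l]]$idx, dcur,
                              cache$pool[[l]]$n_in)
      dcur <- dpool + dskip[[l]]
    }
    cb <- conv_block_bw(dcur, cache$enc[[l]], P, sprintf("enc%d", l), grads)
    grads <- cb$grads
    dcur <- cb$dx
  }
  grads
}

#' Save / load a segmentation model
#'
#' Weights are serialized with R's native `saveRDS`; a sidecar JSON carries
#' the `net_config` so a saved model is self-describing.
#'
#' @param model a `seg_model`.
#' @param path output path (`.rds`); the sidecar is `<path>.json`.
#' @return `load_model` returns the `seg_model`; `save_model` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "seg_model"))
  saveRDS(model, path)
  jsonlite::write_json(unclass(model$cfg), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "seg_model"))
  model
}
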