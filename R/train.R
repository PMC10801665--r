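#' Training configuration
#'
#' Mirrors the training recipe the package is built around: Adam at learning
#' rate 5e-4, batch size 1, soft Dice loss, up to 200 epochs, with in-plane
#' rotation / horizontal flip / vertical flip / scaling augmentation and a
#' central in-plane crop before the network.
#'
#' @param learning_rate Adam learning rate (> 0).
#' @param max_epochs maximum training epochs (>= 1).
#' @param batch_size samples per optimizer step (>= 1; the reference recipe
#'   uses 1).
#' @param augmentation named list of logical flags `rotation`, `hflip`,
#'   `vflip`, `scaling`.
#' @param rotation_range_deg maximum in-plane rotation magnitude, degrees.
#' @param scale_range length-2 isotropic in-plane scale factor range (> 0).
#' @param crop_size in-plane crop target fed to the network (a full-matrix
#'   512 scanner grid is cropped to 256 clinically; the test-scale default is
#'   32).
#' @param threshold probability threshold for binarizing predictions.
#' @param loss a [loss_config()].
#' @param seed integer seed governing shuffling and augmentation draws.
#' @return a validated `train_config`.
#' @export
train_config <- function(learning_rate = 5e-4, max_epochs = 200L,
                         batch_size = 1L,
                         augmentation = list(rotation = TRUE, hflip = TRUE,
                                             vflip = TRUE, scaling = TRUE),
                         rotation_range_deg = 15, scale_range = c(0.9, 1.1),
                         crop_size = c(32L, 32L), threshold = 0.5,
                         loss = loss_config(), seed = 1L) {
  cfg <- list(learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
              batch_size = as.integer(batch_size), augmentation = augmentation,
              rotation_range_deg = rotation_range_deg,
              scale_range = as.numeric(scale_range),
              crop_size = rep(as.integer(crop_size), length.out = 2L),
              threshold = threshold, loss = loss, seed = as.integer(seed))
  if (cfg$learning_rate <= 0) stop_cfg("train_config: learning_rate must be > 0")
  if (cfg$max_epochs < 1L) stop_cfg("train_config: max_epochs must be >= 1")
  if (cfg$batch_size < 1L) stop_cfg("train_config: batch_size must be >= 1")
  if (any(cfg$scale_range <= 0)) stop_cfg("train_config: scale_range bounds must be > 0")
  structure(cfg, class = "train_config")
}

# Map raw HU-like intensities into [0, 1] with a fixed window (-1000..3000),
# so air -> 0, soft tissue ~ 0.26, metal core -> 1.
normalize_intensities <- function(arr) {
  (pmin(pmax(arr, -1000), 3000) + 1000) / 4000
}

#' Jointly augment a volume and its needle mask
#'
#' Draws one in-plane spatial transform (rotation about the volume centre,
#' horizontal/vertical flips, isotropic scaling, as enabled in `cfg`) and
#' applies it identically to both inputs: bilinear resampling for the
#' intensity volume, nearest-neighbour for the mask so it stays binary. Grid
#' metadata (spacing, origin) is unchanged. With all flags off the inputs are
#' returned untouched.
#'
#' @param volume a [volume3d()] of intensities.
#' @param mask a [volume3d()] binary mask on the same grid.
#' @param cfg a [train_config()].
#' @param seed integer seed for the transform draw.
#' @return list `(volume, mask)` after the shared transform.
#' @export
augment_pair <- function(volume, mask, cfg, seed = 1L) {
  stopifnot(inherits(volume, "volume3d"), inherits(mask, "volume3d"))
  if (!same_grid(volume, mask)) stop_cfg("augment_pair: volume and mask grids differ")
  fl <- cfg$augmentation
  if (!isTRUE(fl$rotation) && !isTRUE(fl$hflip) && !isTRUE(fl$vflip) &&
      !isTRUE(fl$scaling))
    return(list(volume = volume, mask = mask))
  draw <- with_seed(seed, list(
    angle = if (isTRUE(fl$rotation))
      runif(1, -cfg$rotation_range_deg, cfg$rotation_range_deg) else 0,
    hflip = isTRUE(fl$hflip) && runif(1) < 0.5,
    vflip = isTRUE(fl$vflip) && runif(1) < 0.5,
    scale = if (isTRUE(fl$scaling))
      runif(1, cfg$scale_range[1], cfg$scale_range[2]) else 1))
  apply_inplane_transform(volume, mask, draw)
}

# Shared in-plane affine: output index -> input index about the grid centre.
# Flips are exact index reversals; rotation/scaling use inverse mapping.
apply_inplane_transform <- function(volume, mask, draw) {
  d <- dim(volume$data)
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  th <- -draw$angle * pi / 180   # inverse rotation
  s <- 1 / draw$scale
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]))
  xo <- g$i - cx; yo <- g$j - cy
  if (draw$hflip) xo <- -xo
  if (draw$vflip) yo <- -yo
  xi <- s * (cos(th) * xo - sin(th) * yo) + cx
  yi <- s * (sin(th) * xo + cos(th) * yo) + cy
  vol_out <- volume$data; mask_out <- mask$data
  i0 <- floor(xi); j0 <- floor(yi)
  fx <- xi - i0; fy <- yi - j0
  inb <- function(i, j) i >= 1 & i <= d[1] & j >= 1 & j <= d[2]
  gather <- function(slice, i, j, fill) {
    ok <- inb(i, j)
    out <- rep(fill, length(i))
    out[ok] <- slice[cbind(i[ok], j[ok])]
    out
  }
  ni <- round(xi); nj <- round(yi)
  for (k in seq_len(d[3])) {
    sl <- volume$data[, , k]
    v00 <- gather(sl, i0, j0, -1000); v10 <- gather(sl, i0 + 1, j0, -1000)
    v01 <- gather(sl, i0, j0 + 1, -1000); v11 <- gather(sl, i0 + 1, j0 + 1, -1000)
    vol_out[, , k] <- matrix((1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
                             (1 - fx) * fy * v01 + fx * fy * v11, d[1], d[2])
    msl <- mask$data[, , k]
    mask_out[, , k] <- matrix(gather(msl, ni, nj, 0), d[1], d[2])
  }
  list(volume = volume3d(vol_out, volume$spacing, volume$origin),
       mask = volume3d(mask_out, mask$spacing, mask$origin))
}

prepare_sample <- function(volume, mask, cfg) {
  v <- crop_center(volume, cfg$crop_size)
  m <- if (!is.null(mask)) crop_center(mask, cfg$crop_size) else NULL
  x <- normalize_intensities(v$data)
  list(x = matrix(x, prod(dim(x)), 1L), dims = dim(x),
       t = if (!is.null(m)) as.numeric(m$data > 0) else NULL)
}

#' Train a segmentation model
#'
#' Runs Adam on the soft Dice loss over the training set (batch size 1 per
#' the reference recipe; larger batches accumulate gradients), recording
#' per-epoch training loss, validation loss and hard validation Dice. The run
#' is a deterministic function of the model, data and `cfg$seed`.
#'
#' @param model a `seg_model` from [build_model()].
#' @param train_set list of samples, each `list(volume = volume3d, mask =
#'   volume3d)`; must be nonempty.
#' @param val_set like `train_set`; may be empty.
#' @param cfg a [train_config()].
#' @param verbose print one log line per epoch.
#' @return list `(model, history)`, with `history` a data.frame of one row
#'   per completed epoch: `epoch`, `train_loss`, `val_loss`, `val_dice`.
#' @export
train_model <- function(model, train_set, val_set = list(),
                        cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "seg_model"), length(train_set) >= 1L)
  with_seed(derive_seed(cfg$seed, "train"),
            train_model_impl(model, train_set, val_set, cfg, verbose))
}

train_model_impl <- function(model, train_set, val_set, cfg, verbose) {
  P <- model$params
  mstate <- lapply(P, function(p) p * 0)
  vstate <- mstate
  t_step <- 0L
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_dice = numeric())
  # crop once up front; augmentation then works on the cropped grid
  train_set <- lapply(train_set, function(s) list(
    volume = crop_center(s$volume, cfg$crop_size),
    mask = crop_center(s$mask, cfg$crop_size)))
  val_set <- lapply(val_set, function(s) list(
    volume = crop_center(s$volume, cfg$crop_size),
    mask = crop_center(s$mask, cfg$crop_size)))
  acc <- NULL; acc_n <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(length(train_set))
    losses <- numeric(0)
    for (si in ord) {
      smp <- train_set[[si]]
      aug <- augment_pair(smp$volume, smp$mask, cfg,
                          seed = sample.int(2147483646L, 1L))
      ps <- prepare_sample(aug$volume, aug$mask, cfg)
      fw <- net_forward(model_with(model, P), ps$x, ps$dims, keep_cache = TRUE)
      loss <- soft_dice_loss(fw$y, ps$t, cfg$loss)
      if (!is.finite(loss))
        stop_cfg("train_model: non-finite loss at epoch %d (sample %d)", epoch, si)
      losses <- c(losses, loss)
      dY <- soft_dice_grad(fw$y, ps$t, cfg$loss)
      grads <- net_backward(model_with(model, P), fw$cache, dY)
      if (is.null(acc)) acc <- grads
      else for (nm in names(grads)) acc[[nm]] <- acc[[nm]] + grads[[nm]]
      acc_n <- acc_n + 1L
      if (acc_n >= cfg$batch_size) {
        t_step <- t_step + 1L
        for (nm in names(P)) {
          gr <- acc[[nm]] / acc_n
          mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * gr
          vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * gr^2
          mhat <- mstate[[nm]] / (1 - b1^t_step)
          vhat <- vstate[[nm]] / (1 - b2^t_step)
          P[[nm]] <- P[[nm]] - cfg$learning_rate * mhat / (sqrt(vhat) + adam_eps)
        }
        acc <- NULL; acc_n <- 0L
      }
    }
    val <- evaluate_on(model_with(model, P), val_set, cfg)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = mean(losses),
      val_loss = val$loss, val_dice = val$dice))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  dice %.4f",
                      epoch, mean(losses), val$loss, val$dice))
  }
  list(model = model_with(model, P), history = history)
}

model_with <- function(model, P) { model$params <- P; model }

evaluate_on <- function(model, val_set, cfg) {
  if (length(val_set) == 0L) return(list(loss = NA_real_, dice = NA_real_))
  losses <- dices <- numeric(length(val_set))
  for (i in seq_along(val_set)) {
    ps <- prepare_sample(val_set[[i]]$volume, val_set[[i]]$mask, cfg)
    fw <- net_forward(model, ps$x, ps$dims, keep_cache = FALSE)
    losses[i] <- soft_dice_loss(fw$y, ps$t, cfg$loss)
    pred <- as.numeric(fw$y >= cfg$threshold)
    dices[i] <- if (sum(pred) + sum(ps$t) == 0) 1
    else 2 * sum(pred * ps$t) / (sum(pred) + sum(ps$t))
  }
  list(loss = mean(losses), dice = mean(dices))
}

#' Predict a probability map for a volume
#'
#' Normalizes intensities, zero-pads each axis up to the next multiple of
#' `2^(depth-1)`, runs the network, and unpads, so any grid compatible with
#' the physical data can be segmented.
#'
#' @param model a trained `seg_model`.
#' @param volume a [volume3d()] of raw intensities.
#' @return a [volume3d()] of probabilities in (0, 1).
#' @export
predict_prob <- function(model, volume) {
  stopifnot(inherits(model, "seg_model"), inherits(volume, "volume3d"))
  d <- dim(volume$data)
  div <- 2L^(model$cfg$depth - 1L)
  dp <- as.integer(ceiling(d / div) * div)
  arr <- array(0, dim = dp)
  arr[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <-
    normalize_intensities(volume$data)
  fw <- net_forward(model, matrix(arr, prod(dp), 1L), dp, keep_cache = FALSE)
  prob <- array(fw$y, dim = dp)[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
  dim(prob) <- d
  volume3d(prob, volume$spacing, volume$origin)
}

#' Predict a binary needle mask
#'
#' @param threshold probability cut (default 0.5); masks are monotone
#'   decreasing in the threshold.
#' @rdname predict_prob
#' @export
predict_mask <- function(model, volume, threshold = 0.5) {
  prob <- predict_prob(model, volume)
  volume3d((prob$data >= threshold) * 1.0, volume$spacing, volume$origin)
}
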