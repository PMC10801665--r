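test_that("soft Dice loss matches hand-computed limits", {
  m <- array(0, dim = c(10, 10, 10))
  m[sample.int(1000, 100)] <- 1
  expect_equal(soft_dice_loss(m, m), 1 - 200 / 200.0001, tolerance = 1e-12)
  expect_equal(soft_dice_loss(m * 0, m), 1)
  p <- array(0.5, dim = c(2, 2, 2))
  t <- array(c(1, 1, 1, 1, 0, 0, 0, 0), dim = c(2, 2, 2))
  expect_equal(soft_dice_loss(p, t), 1 - 4 / (8 + 1e-4), tolerance = 1e-12)
  # symmetry for binary arguments
  set.seed(4)
  a <- array(runif(64) < 0.3, dim = c(4, 4, 4)) * 1
  b <- array(runif(64) < 0.3, dim = c(4, 4, 4)) * 1
  expect_equal(soft_dice_loss(a, b), soft_dice_loss(b, a))
  expect_error(soft_dice_loss(a, b[1:2, , ]), "shapes differ")
  expect_error(loss_config(0), "epsilon")
})

test_that("attention gate saturates as the sigmoid dictates", {
  set.seed(5)
  x <- array(rnorm(4^3 * 4), dim = c(4, 4, 4, 4))
  g <- array(rnorm(2^3 * 8), dim = c(2, 2, 2, 8))
  params <- list(Wx = matrix(0, 4, 2), Wg = matrix(0, 8, 2),
                 bxg = c(0, 0), psi = matrix(0, 2, 1), bpsi = 0)
  out <- attention_gate(x, g, params)
  expect_equal(out$alpha, array(0.5, dim = c(4, 4, 4)))
  expect_equal(out$gated, x / 2)
  params$bpsi <- 20
  out2 <- attention_gate(x, g, params)
  expect_gt(min(out2$alpha), 1 - 1e-8)
  expect_equal(out2$gated, x, tolerance = 1e-7)
  bad <- params; bad$Wx <- matrix(0, 3, 2)
  expect_error(attention_gate(x, g, bad), "channels")
})

test_that("attention gate matches the per-voxel loop oracle", {
  set.seed(6)
  for (rep in 1:5) {
    x <- array(rnorm(4^3 * 3), dim = c(4, 4, 4, 3))
    g <- array(rnorm(2^3 * 5), dim = c(2, 2, 2, 5))
    params <- list(Wx = matrix(rnorm(3 * 2), 3, 2),
                   Wg = matrix(rnorm(5 * 2), 5, 2),
                   bxg = rnorm(2), psi = matrix(rnorm(2), 2, 1),
                   bpsi = rnorm(1))
    got <- attention_gate(x, g, params)
    want <- oracle_attention_gate(x, g, params)
    expect_equal(got$alpha, want$alpha, tolerance = 1e-10)
    expect_equal(got$gated, want$gated, tolerance = 1e-10)
  }
})

test_that("model topology follows the configuration", {
  cfg <- net_config(depth = 4, base_channels = 8, use_attention = FALSE)
  model <- build_model(cfg, seed = 1)
  dims <- c(32L, 32L, 32L)
  x <- matrix(runif(prod(dims)), prod(dims), 1)
  fw <- needletrace:::net_forward(model, x, dims, keep_cache = FALSE)
  expect_length(fw$y, prod(dims))
  expect_true(all(fw$y > 0 & fw$y < 1))

  ag_model <- build_model(net_config(depth = 4, base_channels = 8,
                                     use_attention = TRUE), seed = 1)
  n_gates <- sum(grepl("^dec[0-9]+\\.att\\.psi$", names(ag_model$params)))
  expect_equal(n_gates, 3)  # one per skip connection

  expect_error(needletrace:::net_forward(model, x[1:1000, , drop = FALSE],
                                         c(10L, 10L, 10L)),
               "divisible")
  expect_error(net_config(depth = 1), "depth")
  expect_error(net_config(base_channels = 6, gn_groups = 4), "gn_groups")
})

test_that("the full-scale topology counts 22 convolutional layers", {
  expect_equal(count_conv_layers(net_config(depth = 5)), 22)
  expect_equal(count_conv_layers(net_config(depth = 5), include_head = TRUE), 23)
  expect_equal(count_conv_layers(net_config(depth = 3)), 12)
})

test_that("loss gradients flow, finite and nonzero, through both variants", {
  set.seed(7)
  dims <- c(8L, 8L, 8L)
  x <- matrix(runif(prod(dims)), prod(dims), 1)
  t <- as.numeric(runif(prod(dims)) < 0.1)
  for (use_ag in c(TRUE, FALSE)) {
    model <- build_model(net_config(depth = 3, base_channels = 8,
                                    use_attention = use_ag), seed = 2)
    fw <- needletrace:::net_forward(model, x, dims)
    dY <- needletrace:::soft_dice_grad(fw$y, t)
    grads <- needletrace:::net_backward(model, fw$cache, dY)
    expect_setequal(names(grads), names(model$params))
    expect_true(all(vapply(grads, function(g) all(is.finite(g)), TRUE)))
    expect_gt(sum(vapply(grads, function(g) sum(abs(g)), 0)), 0)
  }
})

test_that("analytic gradients agree with central differences", {
  # spot-check one parameter of each kind (float kernels: loose tolerance)
  set.seed(8)
  dims <- c(8L, 8L, 8L)
  x <- matrix(runif(prod(dims)), prod(dims), 1)
  t <- as.numeric(runif(prod(dims)) < 0.1)
  model <- build_model(net_config(depth = 3, base_channels = 8), seed = 3)
  fw <- needletrace:::net_forward(model, x, dims)
  grads <- needletrace:::net_backward(model, fw$cache,
                                      needletrace:::soft_dice_grad(fw$y, t))
  for (nm in c("enc1.conv1.W", "dec1.conv1.W", "dec2.up.W", "enc2.gn1.gamma",
               "dec1.att.psi", "head.W")) {
    eps <- 1e-4
    m2 <- model
    m2$params[[nm]][1] <- m2$params[[nm]][1] + eps
    lp <- soft_dice_loss(needletrace:::net_forward(m2, x, dims, FALSE)$y, t)
    m2$params[[nm]][1] <- m2$params[[nm]][1] - 2 * eps
    lm_ <- soft_dice_loss(needletrace:::net_forward(m2, x, dims, FALSE)$y, t)
    fd <- (lp - lm_) / (2 * eps)
    an <- grads[[nm]][1]
    expect_lt(abs(fd - an), max(0.05 * abs(an), 2e-4))
  }
})

test_that("models round trip through save/load with a config sidecar", {
  model <- build_model(net_config(depth = 2, base_channels = 4), seed = 9)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(model, f)
  back <- load_model(f)
  expect_identical(back$params, model$params)
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$depth, 2)
  expect_equal(side$base_channels, 4)
})
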