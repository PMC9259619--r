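# Direct (loop-based) 2D convolution oracle for a single channel-set, same
# padding, used to validate the im2col+GEMM primitive independently.
conv_oracle <- function(x, wmat, b, relu) {
  d <- dim(x) # (H, W, Cin, N)
  cout <- ncol(wmat)
  out <- array(0, c(d[1], d[2], cout, d[4]))
  for (n in seq_len(d[4]))
    for (co in seq_len(cout)) {
      acc <- matrix(b[co], d[1], d[2])
      for (ci in seq_len(d[3]))
        for (kj in 1:3)
          for (ki in 1:3) {
            wv <- wmat[(ki - 1) + 3 * (kj - 1) + 9 * (ci - 1) + 1, co]
            if (wv == 0) next
            sh <- matrix(0, d[1], d[2])
            si <- (1:d[1]) + ki - 2; sj <- (1:d[2]) + kj - 2
            ok_i <- si >= 1 & si <= d[1]; ok_j <- sj >= 1 & sj <= d[2]
            sh[ok_i, ok_j] <- x[si[ok_i], sj[ok_j], ci, n]
            acc <- acc + wv * sh
          }
      if (relu) acc <- pmax(acc, 0)
      out[, , co, n] <- acc
    }
  out
}

test_that("convolution primitive matches a direct-sum oracle", {
  set.seed(41)
  x <- array(rnorm(10 * 8 * 3 * 2), c(10, 8, 3, 2))
  w <- matrix(rnorm(27 * 4), 27, 4)
  b <- rnorm(4)
  got <- lofimri:::cpp_conv2d_fwd(x, w, b, 3L, 3L, TRUE)
  expect_equal(got, conv_oracle(x, w, b, TRUE), tolerance = 1e-12)
  got2 <- lofimri:::cpp_conv2d_fwd(x, w, b, 3L, 3L, FALSE)
  expect_equal(got2, conv_oracle(x, w, b, FALSE), tolerance = 1e-12)
})

test_that("backpropagation gradients match central finite differences", {
  set.seed(42)
  cfg <- network_config(c(8L, 8L, 2L), depth = 2L, base_filters = 3L)
  m <- build_model(cfg, seed = 5)
  m$params$final$w[] <- rnorm(length(m$params$final$w), sd = 0.1)
  x <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  y <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  lg <- lofimri:::unet_loss_grad(m, x, y)
  eps <- 1e-6
  for (nm in names(m$params)) {
    w <- m$params[[nm]]$w
    for (j in sample(length(w), 4)) {
      m2 <- m
      m2$params[[nm]]$w[j] <- w[j] + eps
      up <- lofimri:::unet_loss_grad(m2, x, y)$loss
      m2$params[[nm]]$w[j] <- w[j] - eps
      dn <- lofimri:::unet_loss_grad(m2, x, y)$loss
      expect_equal(lg$grads[[nm]]$w[j], (up - dn) / (2 * eps),
                   tolerance = 1e-5)
    }
    bb <- m$params[[nm]]$b
    j <- sample(length(bb), 1)
    m2 <- m
    m2$params[[nm]]$b[j] <- bb[j] + eps
    up <- lofimri:::unet_loss_grad(m2, x, y)$loss
    m2$params[[nm]]$b[j] <- bb[j] - eps
    dn <- lofimri:::unet_loss_grad(m2, x, y)$loss
    expect_equal(lg$grads[[nm]]$b[j], (up - dn) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("architecture: four encoder sequences, 64->512 filters, 2-filter head", {
  cfg <- network_config(c(128L, 128L, 2L), depth = 4L, base_filters = 64L)
  m <- build_model(cfg, seed = 1)
  expect_identical(lofimri:::unet_filters(cfg), c(64L, 128L, 256L, 512L))
  # encoder conv shapes: 9*Cin rows, Cout columns
  expect_identical(dim(m$params$enc1_conv1$w), c(9L * 2L, 64L))
  expect_identical(dim(m$params$enc4_conv2$w), c(9L * 512L, 512L))
  # final 1x1 convolution maps 64 channels to 2 filters
  expect_identical(dim(m$params$final$w), c(64L, 2L))
  # parameter count is the deterministic sum over layer shapes
  count <- sum(vapply(m$params, function(p) length(p$w) + length(p$b),
                      numeric(1)))
  expect_identical(n_params(m), count)
  expect_error(network_config(c(100L, 100L, 2L), depth = 4L), "divisible")
  expect_error(network_config(c(128L, 128L, 3L)), "height, width, 2")
})

test_that("residual shortcut: zero final weights give the identity map", {
  m <- tiny_net(h = 16L)
  m$params$final$w[] <- 0
  m$params$final$b[] <- 0
  x <- array(rnorm(16 * 16 * 2 * 3), c(16, 16, 2, 3))
  expect_identical(unet_forward(m, x), x)
  # without the shortcut the same weights give zero output
  m_nores <- tiny_net(h = 16L, residual = FALSE)
  m_nores$params <- m$params
  m_nores$cfg$residual <- FALSE
  expect_true(all(unet_forward(m_nores, x) == 0))
})

test_that("initialization is bit-identical under one seed, differs across seeds", {
  a <- build_model(network_config(c(16L, 16L, 2L), 2L, 4L), seed = 9)
  b <- build_model(network_config(c(16L, 16L, 2L), 2L, 4L), seed = 9)
  expect_identical(a$params, b$params)
  c3 <- build_model(network_config(c(16L, 16L, 2L), 2L, 4L), seed = 10)
  expect_false(identical(a$params, c3$params))
})

test_that("output shape equals input shape for valid configurations", {
  for (setup in list(c(16L, 2L, 4L), c(32L, 3L, 2L), c(8L, 1L, 5L))) {
    m <- build_model(network_config(c(setup[1], setup[1], 2L), setup[2],
                                    setup[3]), seed = 2)
    x <- array(rnorm(setup[1]^2 * 2), c(setup[1], setup[1], 2, 1))
    expect_identical(dim(unet_forward(m, x)), dim(x))
  }
})

test_that("training: lr 0 freezes parameters; intensity doubling quadruples MSE", {
  m <- tiny_net(h = 16L)
  x <- array(rnorm(16 * 16 * 2 * 4), c(16, 16, 2, 4))
  pairs <- lapply(1:4, function(i)
    structure(list(input = x[, , , i], target = x[, , , i], slice_index = i,
                   scale = 1), class = "training_pair"))
  tcfg <- training_config(initial_lr = 1e-12, max_epochs = 1L, batch_size = 2L,
                          seed = 1)
  fit <- train_unet(m, pairs, pairs, tcfg)
  for (nm in names(m$params))
    expect_equal(fit$model$params[[nm]]$w, m$params[[nm]]$w, tolerance = 1e-9)
  # homogeneity of the squared-error loss under intensity scaling
  y <- array(rnorm(length(x)), dim(x))
  l1 <- mean((unet_forward(m, x) - y)^2)
  m0 <- m # fixed model, scaled data: residual path is nonlinear, so use
  # the zero-weight identity model for the exact homogeneity check
  m0$params$final$w[] <- 0; m0$params$final$b[] <- 0
  l_id <- mean((unet_forward(m0, x) - y)^2)
  l_id2 <- mean((unet_forward(m0, 2 * x) - 2 * y)^2)
  expect_equal(l_id2, 4 * l_id, tolerance = 1e-12)
  expect_true(is.finite(l1))
})

test_that("identity task: validation MSE falls below 1e-4 within 20 epochs", {
  set.seed(77)
  m <- build_model(network_config(c(32L, 32L, 2L), 2L, 8L), seed = 7)
  mk <- function(n, off) lapply(seq_len(n), function(i) {
    sl <- array(rnorm(32 * 32 * 2, sd = 0.5), c(32, 32, 2))
    structure(list(input = sl, target = sl, slice_index = i, scale = 1),
              class = "training_pair")
  })
  train <- mk(32); val <- mk(8)
  tcfg <- training_config(initial_lr = 1e-3, max_epochs = 20L,
                          batch_size = 8L, seed = 3)
  fit <- train_unet(m, train, val, tcfg)
  expect_lt(min(fit$history$val_loss), 1e-4)
  expect_lte(tail(fit$history$val_loss, 1), fit$history$val_loss[1])
})

test_that("training learns a non-trivial map (global intensity damping)", {
  set.seed(78)
  m <- build_model(network_config(c(32L, 32L, 2L), 2L, 8L), seed = 11)
  mk <- function(n) lapply(seq_len(n), function(i) {
    sl <- array(rnorm(32 * 32 * 2, sd = 0.5), c(32, 32, 2))
    structure(list(input = sl, target = 0.7 * sl, slice_index = i, scale = 1),
              class = "training_pair")
  })
  train <- mk(32); val <- mk(8)
  tcfg <- training_config(initial_lr = 1e-3, max_epochs = 25L,
                          batch_size = 8L, seed = 4)
  fit <- train_unet(m, train, val, tcfg)
  # initial (identity-started) val loss is E[(0.3 x)^2]; training must cut
  # it by well over half
  expect_lt(min(fit$history$val_loss), 0.4 * fit$history$val_loss[1])
})

test_that("training validates inputs and records history", {
  m <- tiny_net(h = 16L)
  p <- list(structure(list(input = array(0, c(16, 16, 2)),
                           target = array(0, c(16, 16, 2)),
                           slice_index = 1, scale = 1),
                      class = "training_pair"))
  expect_error(train_unet(m, list(), p, training_config()), "non-empty")
  tcfg <- training_config(max_epochs = 2L, batch_size = 1L, seed = 2)
  set.seed(1)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  pr <- list(structure(list(input = x, target = x * 0.9, slice_index = 1,
                            scale = 1), class = "training_pair"))
  fit <- train_unet(m, pr, pr, tcfg)
  expect_identical(nrow(fit$history), 2L)
  expect_named(fit$history, c("epoch", "train_loss", "val_loss", "lr"))
})

test_that("reconstruct assembles magnitude/phase and un-normalizes", {
  m <- tiny_net(h = 16L)
  m$params$final$w[] <- 0; m$params$final$b[] <- 0 # identity model
  v <- random_volume(c(16, 16, 8), seed = 13)
  rec <- reconstruct(m, v, scale = 2.5)
  expect_equal(rec$magnitude, Mod(v$data) * 2.5, tolerance = 1e-12)
  expect_equal(rec$phase, Arg(v$data), tolerance = 1e-12)
  expect_equal(rec$complex$data, v$data * 2.5, tolerance = 1e-12)
  # phase of a pure-real positive volume is zero
  pos <- complex_volume(array(1 + 0i, c(16, 16, 8)) *
                          array(runif(16 * 16 * 8, 0.1, 1), c(16, 16, 8)))
  expect_true(all(reconstruct(m, pos, 1)$phase == 0))
  # magnitude invariant under a global phase rotation of the input
  rot <- complex_volume(v$data * exp(0.7i))
  expect_equal(reconstruct(m, rot, 1)$magnitude, Mod(v$data),
               tolerance = 1e-12)
  expect_error(reconstruct(m, random_volume(c(8, 8, 8)), 1), "in-plane")
})

test_that("model checkpoints round-trip with their config sidecar", {
  m <- tiny_net(h = 16L)
  path <- file.path(withr::local_tempdir(), "ckpt.rds")
  save_model(m, path)
  expect_true(file.exists(sub("\\.rds$", "_config.json", path)))
  m2 <- load_model(path)
  expect_identical(m2$params, m$params)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  expect_identical(unet_forward(m, x), unet_forward(m2, x))
})
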