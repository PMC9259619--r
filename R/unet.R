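#' Residual U-net architecture configuration
#'
#' The model is built deterministically from this configuration: `depth`
#' encoder sequences of (conv 3x3, ReLU, conv 3x3, ReLU, max-pool 2x2), with
#' `base_filters * 2^(d-1)` filters at level `d`; a mirrored decoder of
#' (2x nearest-neighbour upsample, skip concatenation, conv 3x3, ReLU,
#' conv 3x3, ReLU); and a final 1x1 convolution with 2 filters mapping the
#' `base_filters`-channel tensor to real and imaginary outputs. When
#' `residual` is `TRUE` the network output is the final convolution's output
#' plus the input (identity shortcut), so the convolutional path learns the
#' correction to the zero-filled image.
#'
#' @param in_shape integer length-3 `(height, width, channels)`; channels
#'   must be 2 and the spatial dims divisible by `2^depth`.
#' @param depth number of encoder sequences (default 4).
#' @param base_filters filters at the first level (default 64).
#' @param residual logical; add the input-to-output identity shortcut.
#' @return An object of class `network_config`.
#' @export
network_config <- function(in_shape = c(128L, 128L, 2L), depth = 4L,
                           base_filters = 64L, residual = TRUE) {
  in_shape <- as.integer(in_shape); depth <- as.integer(depth)
  if (length(in_shape) != 3L || in_shape[3] != 2L)
    stop("`in_shape` must be (height, width, 2)", call. = FALSE)
  if (depth < 1L) stop("`depth` must be >= 1", call. = FALSE)
  if (any(in_shape[1:2] %% 2L^depth != 0L))
    stop(sprintf("spatial dims (%d x %d) must be divisible by 2^depth = %d",
                 in_shape[1], in_shape[2], 2L^depth), call. = FALSE)
  structure(list(in_shape = in_shape, depth = depth,
                 base_filters = as.integer(base_filters),
                 conv_kernel = c(3L, 3L), pool = c(2L, 2L),
                 residual = isTRUE(residual), final_filters = 2L),
            class = "network_config")
}

#' Training hyperparameters
#'
#' Mean-squared-error loss over both channels, RMSProp optimizer with an
#' adaptive (reduce-on-plateau) learning rate starting from `initial_lr`,
#' validation every epoch, and best-validation checkpointing.
#'
#' @param initial_lr initial learning rate (> 0).
#' @param max_epochs maximum number of epochs (>= 1; default 2000).
#' @param batch_size mini-batch size.
#' @param lr_factor,lr_patience reduce-on-plateau: multiply the learning rate
#'   by `lr_factor` after `lr_patience` epochs without validation improvement.
#' @param early_stop_patience stop after this many epochs without validation
#'   improvement (`Inf` disables).
#' @param rho,epsilon RMSProp decay and stabilizer.
#' @param min_lr floor for the learning-rate schedule.
#' @param seed master seed for initialization order and shuffling.
#' @return An object of class `training_config`.
#' @export
training_config <- function(initial_lr = 1e-3, max_epochs = 2000L,
                            batch_size = 8L, lr_factor = 0.5,
                            lr_patience = 5L, early_stop_patience = Inf,
                            rho = 0.9, epsilon = 1e-7, min_lr = 1e-6,
                            seed = 1L) {
  if (initial_lr <= 0) stop("`initial_lr` must be > 0", call. = FALSE)
  if (max_epochs < 1L) stop("`max_epochs` must be >= 1", call. = FALSE)
  structure(list(loss = "mse", optimizer = "rmsprop",
                 initial_lr = initial_lr, max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience),
                 early_stop_patience = early_stop_patience, rho = rho,
                 epsilon = epsilon, min_lr = min_lr,
                 seed = as.integer(seed)),
            class = "training_config")
}

unet_filters <- function(cfg)
  as.integer(cfg$base_filters * 2^(seq_len(cfg$depth) - 1))

he_uniform <- function(fan_in, n) {
  l <- sqrt(6 / fan_in)
  stats::runif(n, -l, l)
}

#' Build a residual U-net with seeded He-uniform initialization
#'
#' @param cfg a [network_config()].
#' @param seed integer seed for the weight initialization.
#' @return An object of class `unet_model` holding the configuration and a
#'   named list of parameter tensors.
#' @export
build_model <- function(cfg, seed = 1L) {
  if (!inherits(cfg, "network_config"))
    stop("`cfg` must be a network_config", call. = FALSE)
  f <- unet_filters(cfg)
  params <- with_seed(seed, {
    p <- list()
    conv <- function(cin, cout, k = 3L) {
      K <- k * k * cin
      list(w = matrix(he_uniform(K, K * cout), K, cout), b = numeric(cout),
           k = k)
    }
    cin <- cfg$in_shape[3]
    for (d in seq_len(cfg$depth)) {
      p[[sprintf("enc%d_conv1", d)]] <- conv(cin, f[d])
      p[[sprintf("enc%d_conv2", d)]] <- conv(f[d], f[d])
      cin <- f[d]
    }
    for (d in rev(seq_len(cfg$depth))) {
      f_up <- if (d == cfg$depth) f[d] else f[d + 1L]
      p[[sprintf("dec%d_conv1", d)]] <- conv(f_up + f[d], f[d])
      p[[sprintf("dec%d_conv2", d)]] <- conv(f[d], f[d])
    }
    p[["final"]] <- conv(f[1], cfg$final_filters, k = 1L)
    if (cfg$residual) p[["final"]]$w[] <- 0 # start at the identity map, so
    # a residual model begins exactly at the zero-filled baseline
    p
  })
  structure(list(cfg = cfg, params = params, seed = as.integer(seed)),
            class = "unet_model")
}

#' Number of trainable parameters
#' @param model a `unet_model`.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, function(p) length(p$w) + length(p$b), numeric(1)))
}

#' @export
print.unet_model <- function(x, ...) {
  f <- unet_filters(x$cfg)
  cat(sprintf("<unet_model> depth %d, filters %s, residual = %s, %d parameters\n",
              x$cfg$depth, paste(f, collapse = "->"), x$cfg$residual,
              n_params(x)))
  invisible(x)
}

concat_channels <- function(a, b) {
  d <- dim(a)
  out <- array(0, dim = c(d[1], d[2], d[3] + dim(b)[3], d[4]))
  out[, , seq_len(d[3]), ] <- a
  out[, , d[3] + seq_len(dim(b)[3]), ] <- b
  out
}

# Forward pass over a batch x (H, W, 2, N). With cache = TRUE returns the
# intermediates needed by unet_backward.
unet_forward_impl <- function(model, x, cache = FALSE) {
  p <- model$params
  cfg <- model$cfg
  cc <- list(x = x)
  h <- x
  skips <- vector("list", cfg$depth)
  for (d in seq_len(cfg$depth)) {
    n1 <- sprintf("enc%d_conv1", d); n2 <- sprintf("enc%d_conv2", d)
    cc[[paste0(n1, "_x")]] <- h
    h <- cpp_conv2d_fwd(h, p[[n1]]$w, p[[n1]]$b, 3L, 3L, TRUE)
    cc[[paste0(n1, "_y")]] <- h
    h <- cpp_conv2d_fwd(h, p[[n2]]$w, p[[n2]]$b, 3L, 3L, TRUE)
    cc[[paste0(n2, "_y")]] <- h
    skips[[d]] <- h
    mp <- cpp_maxpool_fwd(h)
    cc[[sprintf("pool%d_idx", d)]] <- mp$idx
    cc[[sprintf("pool%d_in", d)]] <- dim(h)[1:2]
    h <- mp$y
  }
  for (d in rev(seq_len(cfg$depth))) {
    h <- cpp_upsample_fwd(h)
    h <- concat_channels(h, skips[[d]])
    n1 <- sprintf("dec%d_conv1", d); n2 <- sprintf("dec%d_conv2", d)
    cc[[paste0(n1, "_x")]] <- h
    h <- cpp_conv2d_fwd(h, p[[n1]]$w, p[[n1]]$b, 3L, 3L, TRUE)
    cc[[paste0(n1, "_y")]] <- h
    h <- cpp_conv2d_fwd(h, p[[n2]]$w, p[[n2]]$b, 3L, 3L, TRUE)
    cc[[paste0(n2, "_y")]] <- h
  }
  cc[["final_x"]] <- h
  out <- cpp_conv2d_fwd(h, p$final$w, p$final$b, 1L, 1L, FALSE)
  cc[["final_y"]] <- out
  if (cfg$residual) out <- out + x
  if (cache) list(out = out, cache = cc) else out
}

#' Apply the network to a batch of 2-channel slices
#'
#' @param model a `unet_model`.
#' @param x array `(height, width, 2, n)` or a single `(height, width, 2)`
#'   slice.
#' @return array of the same shape.
#' @export
unet_forward <- function(model, x) {
  d <- dim(x)
  single <- length(d) == 3L
  if (single) dim(x) <- c(d, 1L)
  if (!identical(dim(x)[1:3], as.integer(model$cfg$in_shape)))
    stop(sprintf("input shape (%s) does not match the model in_shape (%s)",
                 paste(dim(x)[1:3], collapse = " x "),
                 paste(model$cfg$in_shape, collapse = " x ")), call. = FALSE)
  out <- unet_forward_impl(model, x, cache = FALSE)
  if (single) dim(out) <- d
  out
}

# Gradient of the MSE loss wrt every parameter; returns list(loss, grads).
unet_loss_grad <- function(model, x, target) {
  p <- model$params
  cfg <- model$cfg
  fw <- unet_forward_impl(model, x, cache = TRUE)
  resid <- fw$out - target
  loss <- mean(resid^2)
  dout <- 2 * resid / length(resid)
  cc <- fw$cache
  g <- list()
  bw <- cpp_conv2d_bwd(cc$final_x, p$final$w, dout, cc$final_y, 1L, 1L, FALSE)
  g$final <- list(w = bw$dw, b = bw$db)
  dh <- bw$dx
  for (d in seq_len(cfg$depth)) {
    n1 <- sprintf("dec%d_conv1", d); n2 <- sprintf("dec%d_conv2", d)
    bw2 <- cpp_conv2d_bwd(cc[[paste0(n1, "_y")]], p[[n2]]$w, dh,
                          cc[[paste0(n2, "_y")]], 3L, 3L, TRUE)
    g[[n2]] <- list(w = bw2$dw, b = bw2$db)
    bw1 <- cpp_conv2d_bwd(cc[[paste0(n1, "_x")]], p[[n1]]$w, bw2$dx,
                          cc[[paste0(n1, "_y")]], 3L, 3L, TRUE)
    g[[n1]] <- list(w = bw1$dw, b = bw1$db)
    dcat <- bw1$dx
    nup <- dim(dcat)[3] - unet_filters(cfg)[d]
    dskip <- dcat[, , nup + seq_len(unet_filters(cfg)[d]), , drop = FALSE]
    dup <- dcat[, , seq_len(nup), , drop = FALSE]
    dbelow <- cpp_upsample_bwd(dup)
    # gradient flowing into the skip joins the encoder path at this level
    g[[sprintf("skip%d", d)]] <- dskip
    dh <- dbelow
  }
  # encoder backward, deepest level first; dh currently holds the gradient
  # arriving below the deepest pool
  for (d in rev(seq_len(cfg$depth))) {
    n1 <- sprintf("enc%d_conv1", d); n2 <- sprintf("enc%d_conv2", d)
    hw <- cc[[sprintf("pool%d_in", d)]]
    dpool <- cpp_maxpool_bwd(cc[[sprintf("pool%d_idx", d)]], dh, hw[1], hw[2])
    dsum <- dpool + g[[sprintf("skip%d", d)]]
    g[[sprintf("skip%d", d)]] <- NULL
    bw2 <- cpp_conv2d_bwd(cc[[paste0(n1, "_y")]], p[[n2]]$w, dsum,
                          cc[[paste0(n2, "_y")]], 3L, 3L, TRUE)
    g[[n2]] <- list(w = bw2$dw, b = bw2$db)
    bw1 <- cpp_conv2d_bwd(cc[[paste0(n1, "_x")]], p[[n1]]$w, bw2$dx,
                          cc[[paste0(n1, "_y")]], 3L, 3L, TRUE)
    g[[n1]] <- list(w = bw1$dw, b = bw1$db)
    dh <- bw1$dx
  }
  list(loss = loss, grads = g)
}

stack_pairs <- function(pairs, what = c("input", "target")) {
  what <- match.arg(what)
  d <- dim(pairs[[1]][[what]])
  out <- array(0, dim = c(d, length(pairs)))
  for (i in seq_along(pairs)) out[, , , i] <- pairs[[i]][[what]]
  out
}

batch_mse <- function(model, x, target, batch = 16L) {
  n <- dim(x)[4]
  sse <- 0
  for (i0 in seq(1L, n, by = batch)) {
    i1 <- min(n, i0 + batch - 1L)
    out <- unet_forward_impl(model, x[, , , i0:i1, drop = FALSE])
    sse <- sse + sum((out - target[, , , i0:i1, drop = FALSE])^2)
  }
  sse / length(x)
}

#' Train a residual U-net on undersampled/fully-sampled pairs
#'
#' Minimizes the mean squared error over both channels with RMSProp,
#' validates every epoch, reduces the learning rate on validation plateaus
#' and returns the parameters achieving the best validation loss. Fully
#' seeded: shuffling derives from `tcfg$seed`.
#'
#' @param model a `unet_model` from [build_model()].
#' @param train_pairs,val_pairs non-empty lists of `training_pair` objects
#'   (from [make_training_pair()]).
#' @param tcfg a [training_config()].
#' @param verbose print one line per epoch.
#' @return list with `model` (best-validation parameters) and `history`
#'   (data.frame: epoch, train_loss, val_loss, lr).
#' @export
train_unet <- function(model, train_pairs, val_pairs, tcfg, verbose = FALSE) {
  if (length(train_pairs) == 0L || length(val_pairs) == 0L)
    stop("training and validation sets must be non-empty", call. = FALSE)
  if (!inherits(tcfg, "training_config"))
    stop("`tcfg` must be a training_config", call. = FALSE)
  xt <- stack_pairs(train_pairs, "input"); yt <- stack_pairs(train_pairs, "target")
  xv <- stack_pairs(val_pairs, "input"); yv <- stack_pairs(val_pairs, "target")
  if (!identical(dim(xt)[1:3], as.integer(model$cfg$in_shape)))
    stop("pair shape does not match the model in_shape", call. = FALSE)
  n <- dim(xt)[4]
  lr <- tcfg$initial_lr
  msq <- lapply(model$params, function(p)
    list(w = array(0, dim(p$w)), b = numeric(length(p$b))))
  best_val <- Inf
  best_params <- model$params
  stale <- 0L
  hist <- list()
  with_seed(tcfg$seed, {
    for (epoch in seq_len(tcfg$max_epochs)) {
      ord <- sample.int(n)
      tr_loss <- 0; nb <- 0L
      for (i0 in seq(1L, n, by = tcfg$batch_size)) {
        take <- ord[i0:min(n, i0 + tcfg$batch_size - 1L)]
        lg <- unet_loss_grad(model, xt[, , , take, drop = FALSE],
                             yt[, , , take, drop = FALSE])
        tr_loss <- tr_loss + lg$loss; nb <- nb + 1L
        if (!is.finite(lg$loss))
          stop(sprintf("divergence: non-finite training loss at epoch %d", epoch),
               call. = FALSE)
        for (nm in names(lg$grads)) {
          gw <- lg$grads[[nm]]$w; gb <- lg$grads[[nm]]$b
          msq[[nm]]$w <- tcfg$rho * msq[[nm]]$w + (1 - tcfg$rho) * gw^2
          msq[[nm]]$b <- tcfg$rho * msq[[nm]]$b + (1 - tcfg$rho) * gb^2
          model$params[[nm]]$w <- model$params[[nm]]$w -
            lr * gw / (sqrt(msq[[nm]]$w) + tcfg$epsilon)
          model$params[[nm]]$b <- model$params[[nm]]$b -
            lr * gb / (sqrt(msq[[nm]]$b) + tcfg$epsilon)
        }
      }
      val <- batch_mse(model, xv, yv)
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = tr_loss / nb,
                                   val_loss = val, lr = lr)
      if (verbose)
        message(sprintf("epoch %3d  train %.3e  val %.3e  lr %.2e",
                        epoch, tr_loss / nb, val, lr))
      if (val < best_val) {
        best_val <- val
        best_params <- model$params
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale %% tcfg$lr_patience == 0L)
          lr <- max(tcfg$min_lr, lr * tcfg$lr_factor)
        if (stale >= tcfg$early_stop_patience) break
      }
    }
  })
  model$params <- best_params
  list(model = model, history = do.call(rbind, hist))
}

#' Reconstruct a volume with a trained model
#'
#' Each slice of the normalized zero-filled volume is passed through the
#' network as 2 channels; the complex output is assembled and un-normalized.
#'
#' @param model a `unet_model`.
#' @param vol image-domain [complex_volume()], normalized by `scale` (i.e. the
#'   inverse FFT of the k-space divided by `scale`).
#' @param scale the normalization scale returned by [normalize_kspace()].
#' @return list with `magnitude` and `phase` (3D arrays; phase in (-pi, pi])
#'   and `complex` (un-normalized image-domain [complex_volume()]).
#' @export
reconstruct <- function(model, vol, scale = 1) {
  stopifnot_domain(vol, "image", "reconstruct")
  d <- dim(vol$data)
  if (!identical(d[1:2], as.integer(model$cfg$in_shape[1:2])))
    stop("volume in-plane shape does not match the model", call. = FALSE)
  x <- array(0, dim = c(d[1], d[2], 2L, d[3]))
  x[, , 1, ] <- Re(vol$data); x[, , 2, ] <- Im(vol$data)
  out <- unet_forward_impl(model, x)
  cx <- array(complex(real = out[, , 1, ], imaginary = out[, , 2, ]), dim = d)
  list(magnitude = Mod(cx) * scale, phase = Arg(cx),
       complex = complex_volume(cx * scale, "image", vol$voxel_size))
}

#' Save / load a model checkpoint with its configuration sidecar
#'
#' The parameters go into an RDS file, the architecture into a JSON sidecar.
#'
#' @param model a `unet_model`.
#' @param path checkpoint path (`.rds`).
#' @return `save_model`: invisibly, the paths written. `load_model`: the
#'   restored `unet_model`.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  side <- sub("\\.rds$", "_config.json", path)
  jsonlite::write_json(model$cfg[c("in_shape", "depth", "base_filters",
                                   "residual")],
                       side, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side))
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
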