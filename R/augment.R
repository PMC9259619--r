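transform_types <- c("shift", "flip_h", "flip_v", "shear", "zoom", "rotation")

#' Draw a random geometric transform specification
#'
#' Selects `n_ops` transformations (with replacement) uniformly from
#' \{shift, horizontal flip, vertical flip, shear, zoom, rotation\} and draws
#' their parameters uniformly within the augmentation ranges: shifts in
#' [-50, 50] pixels (integers), shear in [0, 45] degrees, zoom in
#' [0.75, 1.25], rotation in [0, 360) degrees. Unselected parameters stay at
#' their identity values. Deterministic given the seed.
#'
#' @param seed integer seed.
#' @param n_ops number of transformations composed per draw (default 2).
#' @return An object of class `transform_spec`.
#' @export
draw_transform <- function(seed, n_ops = 2L) {
  t <- with_seed(seed, {
    sel <- sample(transform_types, n_ops, replace = TRUE)
    spec <- list(shift_x = 0L, shift_y = 0L, flip_h = FALSE, flip_v = FALSE,
                 shear_deg = 0, zoom = 1, rotation_deg = 0,
                 selected_ops = sel, seed = as.integer(seed))
    for (op in sel) {
      switch(op,
        shift = {
          spec$shift_x <- sample(-50:50, 1)
          spec$shift_y <- sample(-50:50, 1)
        },
        flip_h = spec$flip_h <- TRUE,
        flip_v = spec$flip_v <- TRUE,
        shear = spec$shear_deg <- stats::runif(1, 0, 45),
        zoom = spec$zoom <- stats::runif(1, 0.75, 1.25),
        rotation = spec$rotation_deg <- stats::runif(1, 0, 360))
    }
    spec
  })
  structure(t, class = "transform_spec")
}

#' Explicit transform specification (identity by default)
#'
#' @param shift_x,shift_y integer shifts in pixels, in [-50, 50].
#' @param flip_h,flip_v logical flips along the first/second slice axis.
#' @param shear_deg shear angle in degrees, in [0, 45].
#' @param zoom zoom factor in [0.75, 1.25].
#' @param rotation_deg rotation in degrees, in [0, 360).
#' @return A `transform_spec`.
#' @export
transform_spec <- function(shift_x = 0L, shift_y = 0L, flip_h = FALSE,
                           flip_v = FALSE, shear_deg = 0, zoom = 1,
                           rotation_deg = 0) {
  if (abs(shift_x) > 50 || abs(shift_y) > 50)
    stop("shifts must lie in [-50, 50] pixels", call. = FALSE)
  if (shear_deg < 0 || shear_deg > 45)
    stop("`shear_deg` must lie in [0, 45]", call. = FALSE)
  if (zoom < 0.75 || zoom > 1.25)
    stop("`zoom` must lie in [0.75, 1.25]", call. = FALSE)
  if (rotation_deg < 0 || rotation_deg >= 360)
    stop("`rotation_deg` must lie in [0, 360)", call. = FALSE)
  structure(list(shift_x = as.integer(shift_x), shift_y = as.integer(shift_y),
                 flip_h = flip_h, flip_v = flip_v, shear_deg = shear_deg,
                 zoom = zoom, rotation_deg = rotation_deg,
                 selected_ops = character(0), seed = NA_integer_),
            class = "transform_spec")
}

# 3x3 affine matrix (homogeneous, output->input inverse map) for a slice of
# size nx x ny. Rotation/zoom/shear act about the slice center; cospi/sinpi
# make multiples of 90 degrees exact grid permutations.
transform_matrix <- function(t, nx, ny) {
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  center <- function(m) {
    tr1 <- diag(3); tr1[1:2, 3] <- c(cx, cy)
    tr2 <- diag(3); tr2[1:2, 3] <- c(-cx, -cy)
    tr1 %*% m %*% tr2
  }
  m <- diag(3)
  # forward maps composed left to right: shift, flips, shear, zoom, rotation
  sh <- diag(3); sh[1:2, 3] <- c(t$shift_x, t$shift_y)
  m <- sh %*% m
  if (t$flip_h) { f <- diag(c(-1, 1, 1)); f[1, 3] <- nx + 1; m <- f %*% m }
  if (t$flip_v) { f <- diag(c(1, -1, 1)); f[2, 3] <- ny + 1; m <- f %*% m }
  if (t$shear_deg != 0) {
    s <- diag(3); s[1, 2] <- tanpi(t$shear_deg / 180)
    m <- center(s) %*% m
  }
  if (t$zoom != 1) m <- center(diag(c(t$zoom, t$zoom, 1))) %*% m
  if (t$rotation_deg != 0) {
    a <- t$rotation_deg / 180
    r <- matrix(c(cospi(a), sinpi(a), 0, -sinpi(a), cospi(a), 0, 0, 0, 1), 3)
    m <- center(r) %*% m
  }
  solve(m) # inverse map: output pixel -> input coordinate
}

# Warp one real-valued slice by the inverse map `minv` using bilinear
# interpolation with constant-zero fill. Exact when source coordinates are
# integers (weights degenerate to 0/1), so flips, integer shifts and
# 90-degree rotations are interpolation-free.
warp_slice <- function(sl, minv) {
  nx <- nrow(sl); ny <- ncol(sl)
  gx <- rep(seq_len(nx), ny); gy <- rep(seq_len(ny), each = nx)
  sx <- minv[1, 1] * gx + minv[1, 2] * gy + minv[1, 3]
  sy <- minv[2, 1] * gx + minv[2, 2] * gy + minv[2, 3]
  # snap to grid when numerically integral, keeping exact cases exact
  sx <- ifelse(abs(sx - round(sx)) < 1e-9, round(sx), sx)
  sy <- ifelse(abs(sy - round(sy)) < 1e-9, round(sy), sy)
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  val <- function(xi, yi) {
    ok <- xi >= 1 & xi <= nx & yi >= 1 & yi <= ny
    v <- numeric(length(xi))
    v[ok] <- sl[cbind(xi[ok], yi[ok])]
    v
  }
  out <- (1 - fx) * (1 - fy) * val(x0, y0) +
    fx * (1 - fy) * val(x0 + 1L, y0) +
    (1 - fx) * fy * val(x0, y0 + 1L) +
    fx * fy * val(x0 + 1L, y0 + 1L)
  matrix(out, nx, ny)
}

#' Apply a geometric transform jointly to the real and imaginary parts
#'
#' The identical slice-wise geometric map (composed shift/flip/shear/zoom/
#' rotation about the slice center) is applied to the real part and to the
#' imaginary part with bilinear interpolation and constant-zero fill outside
#' the original support. Output shape equals input shape. The map is linear in
#' the pixel values, so transforming the complex volume commutes with taking
#' real/imaginary parts.
#'
#' @param vol image-domain [complex_volume()].
#' @param t a `transform_spec`.
#' @return transformed image-domain [complex_volume()].
#' @export
apply_joint <- function(vol, t) {
  stopifnot_domain(vol, "image", "apply_joint")
  if (!inherits(t, "transform_spec"))
    stop("`t` must be a transform_spec", call. = FALSE)
  d <- dim(vol$data)
  minv <- transform_matrix(t, d[1], d[2])
  if (max(abs(minv - diag(3))) == 0) return(vol)
  out <- array(0i, dim = d)
  for (z in seq_len(d[3])) {
    re <- warp_slice(Re(vol$data[, , z]), minv)
    im <- warp_slice(Im(vol$data[, , z]), minv)
    out[, , z] <- complex(real = re, imaginary = im)
  }
  complex_volume(out, "image", vol$voxel_size)
}

#' Build undersampled/fully-sampled training pairs from one volume
#'
#' Pipeline: joint geometric augmentation in image domain, centered FFT to
#' k-space, sampling-mask application on the input side only, normalization
#' of both sides by the fully sampled k-space standard deviation (shared
#' scale), inverse FFT, and a split into per-slice 2-channel (real,
#' imaginary) pairs. A pattern defined on a smaller acquired grid is embedded
#' centrally into the volume's phase-encode grid first.
#'
#' @param vol fully sampled image-domain [complex_volume()] (already
#'   zero-filled to the network in-plane size).
#' @param pattern a [sampling_pattern()].
#' @param t a `transform_spec` (identity by default).
#' @return A list of `training_pair` objects, one per slice, each with
#'   `input` and `target` (height x width x 2 arrays), `slice_index` and
#'   `scale`.
#' @export
make_training_pair <- function(vol, pattern, t = transform_spec()) {
  stopifnot_domain(vol, "image", "make_training_pair")
  aug <- apply_joint(vol, t)
  ksp <- fft_centered(aug)
  d <- dim(ksp$data)
  if (!identical(dim(pattern$mask), d[2:3])) {
    if (nrow(pattern$mask) <= d[2] && ncol(pattern$mask) <= d[3])
      pattern <- embed_pattern(pattern, d[2], d[3])
    else
      stop("pattern grid larger than the k-space phase-encode grid",
           call. = FALSE)
  }
  norm <- normalize_kspace(ksp)
  scale <- norm$scale
  ksp_in <- apply_mask(norm$kspace, pattern)
  img_in <- ifft_centered(ksp_in)
  img_tg <- ifft_centered(norm$kspace)
  lapply(seq_len(d[3]), function(z) {
    inp <- array(0, dim = c(d[1], d[2], 2))
    tgt <- array(0, dim = c(d[1], d[2], 2))
    inp[, , 1] <- Re(img_in$data[, , z]); inp[, , 2] <- Im(img_in$data[, , z])
    tgt[, , 1] <- Re(img_tg$data[, , z]); tgt[, , 2] <- Im(img_tg$data[, , z])
    structure(list(input = inp, target = tgt, slice_index = z, scale = scale),
              class = "training_pair")
  })
}
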