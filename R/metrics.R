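#' Evaluation-protocol configuration
#'
#' Parameters of the ROI-masked evaluation: SSIM sliding window and
#' stabilizing constants, dynamic-range rule (maximum of the reference within
#' the ROI), edge-detection kernels for the gradient-sharpness metric, the
#' ROI threshold/morphology, and the noise-only slice-exclusion cutoff.
#'
#' @param ssim_window odd window size (>= 3) for SSIM.
#' @param ssim_K1,ssim_K2 small positive stabilizing constants.
#' @param edge_kernels named list with `gx` and `gy` 3x3 matrices (default
#'   Sobel).
#' @param roi_threshold_fraction threshold as a fraction of the slice maximum.
#' @param morph_radius disc radius (pixels) for binary closing then opening.
#' @param min_signal_fraction a slice is excluded as noise-only when its ROI
#'   covers less than this fraction of the slice area.
#' @return An object of class `metric_config`.
#' @export
metric_config <- function(ssim_window = 7L, ssim_K1 = 0.01, ssim_K2 = 0.03,
                          edge_kernels = sobel_kernels(),
                          roi_threshold_fraction = 0.1, morph_radius = 2L,
                          min_signal_fraction = 0.02) {
  ssim_window <- as.integer(ssim_window)
  if (ssim_window < 3L || ssim_window %% 2L == 0L)
    stop("`ssim_window` must be odd and >= 3", call. = FALSE)
  if (ssim_K1 <= 0 || ssim_K2 <= 0)
    stop("`ssim_K1` and `ssim_K2` must be > 0", call. = FALSE)
  if (roi_threshold_fraction <= 0 || roi_threshold_fraction >= 1)
    stop("`roi_threshold_fraction` must lie in (0, 1)", call. = FALSE)
  structure(list(ssim_window = ssim_window, ssim_K1 = ssim_K1,
                 ssim_K2 = ssim_K2, edge_kernels = edge_kernels,
                 roi_threshold_fraction = roi_threshold_fraction,
                 morph_radius = as.integer(morph_radius),
                 min_signal_fraction = min_signal_fraction),
            class = "metric_config")
}

#' 3x3 Sobel derivative kernel pair
#' @return list with `gx` (horizontal) and `gy` (vertical) kernels.
#' @export
sobel_kernels <- function() {
  gx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  list(gx = gx, gy = t(gx))
}

#' ROI mask from a reference magnitude slice
#'
#' Thresholds the reference magnitude at `roi_threshold_fraction` times the
#' slice maximum, then applies a binary closing followed by a binary opening
#' with a disc of radius `morph_radius`; the opening removes isolated noisy
#' pixels. The mask derives from the reference only, never from a
#' reconstruction. An all-zero slice yields an empty mask (triggering
#' exclusion downstream, not an error).
#'
#' @param reference_magnitude nonnegative 2D slice.
#' @param cfg a [metric_config()].
#' @return An object of class `roi_mask` (logical `mask`, `threshold_used`,
#'   `morphology_radius`).
#' @export
compute_roi_mask <- function(reference_magnitude, cfg = metric_config()) {
  if (any(reference_magnitude < 0))
    stop("reference magnitude must be nonnegative", call. = FALSE)
  peak <- max(reference_magnitude)
  # Signal-free guard: estimate the noise scale from the lower quartile of
  # the magnitudes (Rayleigh q25 = sigma*sqrt(2*log(4/3))) and compare the
  # slice maximum against the extreme-value bound for pure complex noise,
  # sigma*sqrt(2*log(n)) plus slack. Below the bound the slice contains no
  # detectable signal and the mask is empty (relative thresholding alone
  # cannot reject a pure-noise slice).
  sigma_hat <- stats::quantile(reference_magnitude, 0.25, names = FALSE) /
    sqrt(2 * log(4 / 3))
  noise_max <- sigma_hat *
    (sqrt(2 * log(length(reference_magnitude))) + 1.5)
  if (peak <= noise_max || peak == 0) {
    return(structure(list(mask = matrix(FALSE, nrow(reference_magnitude),
                                        ncol(reference_magnitude)),
                          threshold_used = NA_real_,
                          morphology_radius = cfg$morph_radius),
                     class = "roi_mask"))
  }
  th <- cfg$roi_threshold_fraction * peak
  bin <- reference_magnitude >= th
  mode(bin) <- "integer"
  if (any(bin == 1L)) {
    brush <- EBImage::makeBrush(2L * cfg$morph_radius + 1L, shape = "disc")
    bin <- EBImage::opening(EBImage::closing(bin, brush), brush)
    bin <- as.matrix(bin) > 0
  } else bin <- bin > 0
  structure(list(mask = bin, threshold_used = th,
                 morphology_radius = cfg$morph_radius),
            class = "roi_mask")
}

as_roi <- function(roi) {
  if (inherits(roi, "roi_mask")) roi$mask
  else if (is.matrix(roi)) roi > 0
  else stop("`roi` must be an roi_mask or a logical matrix", call. = FALSE)
}

#' Peak signal-to-noise ratio over an ROI
#'
#' `20*log10(max(ref over roi) / rmse)` with the RMSE taken over ROI pixels.
#' Identical images return `Inf` (flagged and excluded from aggregates).
#'
#' @param ref,recon co-registered 2D slices.
#' @param roi an `roi_mask` or logical matrix; must be non-empty.
#' @return PSNR in dB.
#' @export
psnr <- function(ref, recon, roi) {
  m <- as_roi(roi)
  if (!any(m)) stop("empty ROI: slice should be excluded", call. = FALSE)
  err <- ref[m] - recon[m]
  mse <- mean(err^2)
  if (mse == 0) return(Inf)
  20 * log10(max(ref[m]) / sqrt(mse))
}

# Sliding-window sums over w x w windows whose centers fit the image, via a
# 2D integral image; out[i, j] is the sum over the window centered at
# (i + r, j + r), r = w %/% 2.
win_sum <- function(x, w) {
  n1 <- nrow(x); n2 <- ncol(x)
  cs <- rbind(0, apply(x, 2, cumsum))
  cs <- cbind(0, t(apply(cs, 1, cumsum))) # cs[i+1, j+1] = sum x[1:i, 1:j]
  r <- w %/% 2L
  ih <- (r + 1):(n1 - r); iw <- (r + 1):(n2 - r)
  cs[ih + r + 1, iw + r + 1] - cs[ih - r, iw + r + 1] -
    cs[ih + r + 1, iw - r] + cs[ih - r, iw - r]
}

#' Structural similarity index over an ROI
#'
#' Mean SSIM over sliding windows (stride 1) whose centers lie in the ROI and
#' which fit inside the image, with `C1 = (K1*L)^2`, `C2 = (K2*L)^2` and
#' dynamic range `L` equal to the maximum of the reference within the ROI.
#' Window moments (uniform weights, population variances) are computed over
#' the ROI pixels of the window only, so pixels outside the mask are never
#' read; on a full-image ROI this reduces to the standard uniform-window
#' SSIM. Returns `NA` when the ROI admits no window (exclusion signal).
#'
#' @param ref,recon co-registered 2D slices.
#' @param roi an `roi_mask` or logical matrix.
#' @param cfg a [metric_config()].
#' @return mean SSIM, or `NA_real_` when no window fits.
#' @export
ssim <- function(ref, recon, roi, cfg = metric_config()) {
  m <- as_roi(roi)
  if (!any(m)) stop("empty ROI: slice should be excluded", call. = FALSE)
  w <- cfg$ssim_window
  r <- w %/% 2L
  n1 <- nrow(ref); n2 <- ncol(ref)
  if (n1 < w || n2 < w) return(NA_real_)
  centers <- m[(r + 1):(n1 - r), (r + 1):(n2 - r), drop = FALSE]
  if (!any(centers)) return(NA_real_)
  mm <- m * 1
  P <- win_sum(mm, w)[centers]
  sA <- win_sum(ref * mm, w)[centers] / P
  sB <- win_sum(recon * mm, w)[centers] / P
  vA <- win_sum(ref^2 * mm, w)[centers] / P - sA^2
  vB <- win_sum(recon^2 * mm, w)[centers] / P - sB^2
  cAB <- win_sum(ref * recon * mm, w)[centers] / P - sA * sB
  L <- max(ref[m])
  C1 <- (cfg$ssim_K1 * L)^2; C2 <- (cfg$ssim_K2 * L)^2
  s <- ((2 * sA * sB + C1) * (2 * cAB + C2)) /
    ((sA^2 + sB^2 + C1) * (vA + vB + C2))
  mean(s)
}

#' Normalized root-mean-square error over an ROI
#'
#' RMSE over ROI pixels divided by the mean of the reference over the ROI.
#'
#' @param ref,recon co-registered 2D slices.
#' @param roi an `roi_mask` or logical matrix.
#' @return NRMSE (unitless).
#' @export
nrmse <- function(ref, recon, roi) {
  m <- as_roi(roi)
  if (!any(m)) stop("empty ROI: slice should be excluded", call. = FALSE)
  mu <- mean(ref[m])
  if (mu == 0)
    stop("degenerate input: reference mean over the ROI is zero", call. = FALSE)
  sqrt(mean((ref[m] - recon[m])^2)) / mu
}

# 3x3 cross-correlation with replicate (nearest-edge) padding, "same" size;
# replicate padding keeps constant images exactly gradient-free.
conv3x3 <- function(img, k) {
  n1 <- nrow(img); n2 <- ncol(img)
  pad <- img[c(1, 1:n1, n1), c(1, 1:n2, n2)]
  out <- matrix(0, n1, n2)
  for (i in 1:3)
    for (j in 1:3)
      out <- out + k[i, j] * pad[i:(i + n1 - 1), j:(j + n2 - 1)]
  out
}

#' Reference-free gradient sharpness of a magnitude slice
#'
#' Convolves the slice with the configured horizontal and vertical
#' edge-detection kernels (replicate padding at the image border) and reports
#' the mean gradient magnitude `sqrt(Gx^2 + Gy^2)` over the ROI. Being a
#' neighbourhood operator, the kernels at ROI-boundary pixels read adjacent
#' pixels just outside the mask; the average itself is ROI-restricted.
#' Defined for magnitude images only: on phase images wrap discontinuities
#' dominate the gradient, so negative values (impossible in a magnitude
#' image) are rejected.
#'
#' @param image nonnegative magnitude slice.
#' @param roi an `roi_mask` or logical matrix.
#' @param cfg a [metric_config()].
#' @return mean gradient magnitude (intensity per pixel).
#' @export
gradient_sharpness <- function(image, roi, cfg = metric_config()) {
  if (any(image < 0))
    stop("gradient sharpness is restricted to magnitude images (nonnegative); got negative values (phase input?)",
         call. = FALSE)
  m <- as_roi(roi)
  if (!any(m)) stop("empty ROI: slice should be excluded", call. = FALSE)
  gx <- conv3x3(image, cfg$edge_kernels$gx)
  gy <- conv3x3(image, cfg$edge_kernels$gy)
  mean(sqrt(gx^2 + gy^2)[m])
}

#' Indices of slices that contain signal
#'
#' A slice is excluded as noise-only when its ROI covers less than
#' `min_signal_fraction` of the slice area.
#'
#' @param roi_masks list of `roi_mask` objects, one per slice.
#' @param cfg a [metric_config()].
#' @return integer vector of kept slice indices.
#' @export
exclude_noise_slices <- function(roi_masks, cfg = metric_config()) {
  frac <- vapply(roi_masks, function(r) mean(as_roi(r)), numeric(1))
  which(frac >= cfg$min_signal_fraction)
}

#' Evaluate a reconstruction against a fully sampled reference
#'
#' Computes per-slice PSNR, SSIM and NRMSE on magnitude and on phase (the
#' argument of the complex data, wrapped in (-pi, pi], no unwrapping), plus
#' gradient sharpness on magnitude only. The ROI is derived from the
#' reference magnitude alone; noise-only slices are excluded; aggregates are
#' mean and standard deviation across kept slices (non-finite PSNR values are
#' flagged and dropped from aggregates). Phase PSNR is reported for table
#' parity but is advisory: wrapped-phase dynamic range makes NRMSE and SSIM
#' the appropriate phase metrics.
#'
#' @param reference fully sampled image-domain [complex_volume()].
#' @param reconstruction image-domain [complex_volume()] of the same shape.
#' @param cfg a [metric_config()].
#' @return An object of class `metric_report`: `per_slice` and `aggregate`
#'   data frames, `excluded_slices`, `roi_masks`, `config`.
#' @export
evaluate_pair <- function(reference, reconstruction, cfg = metric_config()) {
  if (!identical(dim(reference$data), dim(reconstruction$data)))
    stop("reference and reconstruction shapes differ", call. = FALSE)
  nz <- dim(reference$data)[3]
  rois <- lapply(seq_len(nz), function(z)
    compute_roi_mask(Mod(reference$data[, , z]), cfg))
  kept <- exclude_noise_slices(rois, cfg)
  rows <- list()
  for (z in kept) {
    roi <- rois[[z]]
    ref_m <- Mod(reference$data[, , z]); rec_m <- Mod(reconstruction$data[, , z])
    ref_p <- Arg(reference$data[, , z]); rec_p <- Arg(reconstruction$data[, , z])
    rows[[length(rows) + 1L]] <- data.frame(
      slice = z, channel = "magnitude",
      psnr = psnr(ref_m, rec_m, roi), ssim = ssim(ref_m, rec_m, roi, cfg),
      nrmse = nrmse(ref_m, rec_m, roi),
      gradient = gradient_sharpness(rec_m, roi, cfg))
    rows[[length(rows) + 1L]] <- data.frame(
      slice = z, channel = "phase",
      psnr = psnr(ref_p, rec_p, roi),
      ssim = ssim(ref_p, rec_p, roi, cfg),
      nrmse = nrmse(ref_p, rec_p, roi),
      gradient = NA_real_)
  }
  per_slice <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_slice, per_slice$channel), function(d) {
    data.frame(channel = d$channel[1],
               psnr_mean = mean(d$psnr[is.finite(d$psnr)]),
               psnr_sd = stats::sd(d$psnr[is.finite(d$psnr)]),
               ssim_mean = mean(d$ssim), ssim_sd = stats::sd(d$ssim),
               nrmse_mean = mean(d$nrmse), nrmse_sd = stats::sd(d$nrmse),
               gradient_mean = mean(d$gradient), gradient_sd = stats::sd(d$gradient),
               infinite_psnr = sum(!is.finite(d$psnr)))
  }))
  rownames(agg) <- NULL
  structure(list(per_slice = per_slice, aggregate = agg,
                 excluded_slices = setdiff(seq_len(nz), kept),
                 roi_masks = rois, config = cfg),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  print(x$aggregate, digits = 4)
  if (length(x$excluded_slices))
    cat("excluded (noise-only) slices:",
        paste(x$excluded_slices, collapse = ", "), "\n")
  invisible(x)
}

#' Write a metric report as CSV (per slice) and JSON (aggregate)
#'
#' @param report a `metric_report`.
#' @param prefix output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_metric_report <- function(report, prefix) {
  csv <- paste0(prefix, "_per_slice.csv")
  utils::write.csv(report$per_slice, csv, row.names = FALSE)
  js <- paste0(prefix, "_aggregate.json")
  jsonlite::write_json(list(aggregate = report$aggregate,
                            excluded_slices = report$excluded_slices),
                       js, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}

#' Export a report's ROI masks as bilevel PNG images for inspection
#'
#' @param report a `metric_report`.
#' @param prefix output path prefix; one file per slice.
#' @return Invisibly, the paths written.
#' @export
write_roi_png <- function(report, prefix) {
  paths <- character(0)
  for (z in seq_along(report$roi_masks)) {
    path <- sprintf("%s_roi_slice%02d.png", prefix, z)
    m <- report$roi_masks[[z]]$mask
    png::writePNG(matrix(as.numeric(m), nrow(m)), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
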