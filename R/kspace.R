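#' @useDynLib lofimri, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# fftshift/ifftshift along every axis of a 3D array. For axis length n the
# DC sample sits at 0-based index floor(n/2) after fftshift (the standard
# convention, exact inverse pair for odd and even n).
fftshift3 <- function(x, inverse = FALSE) {
  d <- dim(x)
  idx <- lapply(d, function(n) {
    s <- if (inverse) floor(n / 2) else ceiling(n / 2)
    ((seq_len(n) - 1L + s) %% n) + 1L
  })
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Centered unitary 3D Fourier transform (image to k-space)
#'
#' Orthonormal DFT over all three axes with fftshifted (centered) spectra:
#' `fft_centered` maps an image-domain volume to k-space such that Parseval's
#' identity holds exactly and the DC sample sits at 0-based index
#' `floor(n/2)` of each axis.
#'
#' @param vol image-domain `complex_volume`.
#' @return k-space `complex_volume`.
#' @export
fft_centered <- function(vol) {
  stopifnot_domain(vol, "image", "fft_centered")
  n <- prod(dim(vol$data))
  k <- fftshift3(stats::fft(fftshift3(vol$data, inverse = TRUE))) / sqrt(n)
  complex_volume(k, "kspace", vol$voxel_size)
}

#' Centered unitary 3D inverse Fourier transform (k-space to image)
#'
#' Exact inverse of [fft_centered()].
#'
#' @param vol k-space `complex_volume`.
#' @return image-domain `complex_volume`.
#' @export
ifft_centered <- function(vol) {
  stopifnot_domain(vol, "kspace", "ifft_centered")
  n <- prod(dim(vol$data))
  x <- fftshift3(stats::fft(fftshift3(vol$data, inverse = TRUE),
                            inverse = TRUE)) / sqrt(n)
  complex_volume(x, "image", vol$voxel_size)
}

# Per-axis zero-fill padding: low side gets floor(excess/2), high side the
# remainder (odd excess: one extra sample on the high-index side).
pad_split <- function(current, target) {
  excess <- target - current
  list(low = excess %/% 2L, high = excess - excess %/% 2L)
}

#' Zero-fill k-space to a larger matrix
#'
#' Centers the acquired k-space in the target grid, padding symmetrically with
#' zeros; an odd excess puts the extra zero line on the high-index side
#' (115 -> 128 adds 6 lines low, 7 high). Zero samples add no energy, so the
#' total power is unchanged and [crop_kspace()] recovers the input exactly.
#'
#' @param ksp k-space `complex_volume`.
#' @param target_shape integer length-3, componentwise >= `dim(ksp)`.
#' @return zero-filled k-space `complex_volume`.
#' @export
zero_fill <- function(ksp, target_shape) {
  stopifnot_domain(ksp, "kspace", "zero_fill")
  d <- dim(ksp$data)
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape < d))
    stop("`target_shape` must be componentwise >= the current shape (",
         paste(d, collapse = " x "), ")", call. = FALSE)
  out <- array(0i, dim = target_shape)
  lo <- integer(3)
  for (ax in 1:3) lo[ax] <- pad_split(d[ax], target_shape[ax])$low
  out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <-
    ksp$data
  complex_volume(out, "kspace", ksp$voxel_size)
}

#' Crop zero-filled k-space back to a smaller matrix
#'
#' Inverse of [zero_fill()]: extracts the centered block placed by the same
#' padding convention.
#'
#' @param ksp k-space `complex_volume`.
#' @param shape integer length-3, componentwise <= `dim(ksp)`.
#' @return cropped k-space `complex_volume`.
#' @export
crop_kspace <- function(ksp, shape) {
  stopifnot_domain(ksp, "kspace", "crop_kspace")
  d <- dim(ksp$data)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape > d))
    stop("`shape` must be componentwise <= the current shape", call. = FALSE)
  lo <- integer(3)
  for (ax in 1:3) lo[ax] <- pad_split(shape[ax], d[ax])$low
  out <- ksp$data[lo[1] + seq_len(shape[1]), lo[2] + seq_len(shape[2]),
                  lo[3] + seq_len(shape[3]), drop = FALSE]
  complex_volume(out, "kspace", ksp$voxel_size)
}

#' Normalize k-space by its complex standard deviation
#'
#' Divides every sample by the standard deviation of the complex samples
#' (square root of the mean squared modulus of deviations from the complex
#' mean), computed over the full grid including any zero-filled entries. The
#' scale is returned so reconstructions can be un-normalized.
#'
#' @param ksp k-space `complex_volume` with nonzero variance.
#' @return list with elements `kspace` (normalized volume) and `scale`.
#' @export
normalize_kspace <- function(ksp) {
  stopifnot_domain(ksp, "kspace", "normalize_kspace")
  s <- complex_sd(ksp$data)
  if (s == 0)
    stop("degenerate input: k-space has zero variance (constant samples)",
         call. = FALSE)
  list(kspace = complex_volume(ksp$data / s, "kspace", ksp$voxel_size),
       scale = s)
}

complex_sd <- function(x) sqrt(mean(Mod(x - mean(x))^2))

#' Apply a sampling pattern to k-space
#'
#' Sets samples where the pattern is 0 to exactly 0 and leaves sampled
#' positions untouched; the (ky, kz) mask is broadcast along the readout
#' (first) axis. The mask grid must match the k-space phase-encode dimensions
#' exactly; use [embed_pattern()] first when masking a zero-filled grid with a
#' pattern defined on the acquired grid.
#'
#' @param ksp k-space `complex_volume`.
#' @param pattern a [sampling_pattern()].
#' @return masked k-space `complex_volume`.
#' @export
apply_mask <- function(ksp, pattern) {
  stopifnot_domain(ksp, "kspace", "apply_mask")
  if (!inherits(pattern, "sampling_pattern"))
    stop("`pattern` must be a sampling_pattern", call. = FALSE)
  d <- dim(ksp$data)
  m <- pattern$mask
  if (!identical(dim(m), d[2:3]))
    stop(sprintf("pattern grid (%d x %d) does not match phase-encode dims (%d x %d)",
                 nrow(m), ncol(m), d[2], d[3]), call. = FALSE)
  keep <- aperm(array(m, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
  complex_volume(ksp$data * keep, "kspace", ksp$voxel_size)
}
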