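#' Complex-valued 3D MR volume
#'
#' The common currency of the package: a 3D array of complex samples indexed
#' (x, y, z) together with the domain it currently lives in (`"image"` or
#' `"kspace"`) and the voxel geometry in mm. The domain tag only changes
#' through [fft_centered()] / [ifft_centered()].
#'
#' @param data 3D complex (or numeric, coerced to complex) array.
#' @param domain `"image"` or `"kspace"`.
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @return An object of class `complex_volume`.
#' @export
complex_volume <- function(data, domain = c("image", "kspace"),
                           voxel_size = c(1.2, 1.2, 6.3)) {
  domain <- match.arg(domain)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 1L))
    stop("all dimensions of `data` must be >= 1", call. = FALSE)
  if (!is.complex(data)) {
    storage.mode(data) <- "double"
    data <- data + 0i
  }
  if (any(!is.finite(Re(data))) || any(!is.finite(Im(data))))
    stop("`data` contains non-finite values", call. = FALSE)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive lengths (mm)", call. = FALSE)
  structure(list(data = data, domain = domain,
                 voxel_size = as.numeric(voxel_size)),
            class = "complex_volume")
}

#' @export
dim.complex_volume <- function(x) dim(x$data)

#' @export
print.complex_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<complex_volume> %d x %d x %d, domain = %s, voxel = [%s] mm\n",
              d[1], d[2], d[3], x$domain,
              paste(format(x$voxel_size), collapse = " x ")))
  invisible(x)
}

stopifnot_domain <- function(vol, domain, op) {
  if (!inherits(vol, "complex_volume"))
    stop(sprintf("%s() expects a complex_volume", op), call. = FALSE)
  if (vol$domain != domain)
    stop(sprintf("%s() expects a %s-domain volume, got %s",
                 op, domain, vol$domain), call. = FALSE)
  invisible(TRUE)
}

#' Write a complex volume as paired real/imaginary NIfTI files
#'
#' Volumes are persisted as two NIfTI files with suffixes `_real.nii.gz` and
#' `_imag.nii.gz`; the voxel size is recorded in the header.
#'
#' @param vol a `complex_volume`.
#' @param prefix path prefix (without suffix).
#' @return Invisibly, the two file paths written.
#' @export
write_complex_nifti <- function(vol, prefix) {
  if (!inherits(vol, "complex_volume"))
    stop("`vol` must be a complex_volume", call. = FALSE)
  paths <- paste0(prefix, c("_real.nii.gz", "_imag.nii.gz"))
  re <- RNifti::asNifti(Re(vol$data))
  im <- RNifti::asNifti(Im(vol$data))
  RNifti::pixdim(re) <- vol$voxel_size
  RNifti::pixdim(im) <- vol$voxel_size
  RNifti::writeNifti(re, paths[1])
  RNifti::writeNifti(im, paths[2])
  invisible(paths)
}

#' Read a complex volume from paired real/imaginary NIfTI files
#'
#' @param prefix path prefix used by [write_complex_nifti()].
#' @param domain domain tag to assign (files carry no domain information).
#' @return A `complex_volume`.
#' @export
read_complex_nifti <- function(prefix, domain = "image") {
  paths <- paste0(prefix, c("_real.nii.gz", "_imag.nii.gz"))
  if (!all(file.exists(paths)))
    stop("missing NIfTI pair: ", paste(paths[!file.exists(paths)],
                                       collapse = ", "), call. = FALSE)
  re <- RNifti::readNifti(paths[1])
  im <- RNifti::readNifti(paths[2])
  vox <- RNifti::pixdim(re)
  data <- array(as.numeric(re) + 1i * as.numeric(im), dim = dim(re))
  complex_volume(data, domain = domain, voxel_size = vox[1:3])
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards: keeps the generators pure functions of their seed.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive an independent 32-bit sub-seed from a master seed and a stream label,
# so that phantom, mask, transform and split randomness are decoupled.
derive_seed <- function(master, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(master) * 48271 + h * 69621) %% 2147483587) + 1L
}
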