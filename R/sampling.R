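#' Variable-density Gaussian sampling pattern
#'
#' Binary indicator grid over the phase-encode plane (ky x kz) plus the
#' parameters that generated it. Constructed by [generate_gaussian_pattern()];
#' this low-level constructor validates an existing mask.
#'
#' @param mask binary matrix (ny x nz).
#' @param R target acceleration.
#' @param CL number of fully sampled central ky lines.
#' @param sigma_y,sigma_z Gaussian standard deviations as fractions of the
#'   respective axis lengths.
#' @param seed integer seed used for the random draw.
#' @return An object of class `sampling_pattern`.
#' @export
sampling_pattern <- function(mask, R, CL, sigma_y, sigma_z, seed) {
  mask <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  structure(list(mask = mask, R = R, CL = as.integer(CL),
                 sigma_y = sigma_y, sigma_z = sigma_z,
                 seed = as.integer(seed),
                 achieved_R = length(mask) / sum(mask)),
            class = "sampling_pattern")
}

#' @export
print.sampling_pattern <- function(x, ...) {
  cat(sprintf(
    "<sampling_pattern> %d x %d, R = %g (achieved %.4g), CL = %d, sigma = (%g, %g), seed = %d\n",
    nrow(x$mask), ncol(x$mask), x$R, x$achieved_R, x$CL,
    x$sigma_y, x$sigma_z, x$seed))
  invisible(x)
}

# 0-based indices of the CL ky lines nearest the grid center floor(ny/2);
# even-ny ties resolved toward the high-index side.
center_line_indices <- function(ny, CL) {
  if (CL == 0L) return(integer(0))
  i <- 0:(ny - 1L)
  c0 <- ny %/% 2L
  ord <- order(abs(i - c0), i < c0)
  sort(i[ord[seq_len(CL)]])
}

#' Generate a 2D Gaussian variable-density sampling pattern
#'
#' The `CL` ky lines nearest the k-space center are fully sampled across all
#' kz; the remaining budget of `floor(ny*nz/R) - CL*nz` points is drawn
#' without replacement from the unsampled grid positions with probability
#' proportional to a separable Gaussian centered on the k-space center, with
#' standard deviations `sigma_y*ny` and `sigma_z*nz` samples. The draw uses
#' Gumbel-top-k ordering of the Gaussian weights, so the ones count equals the
#' budget exactly and the pattern is a pure function of the seed. A sigma of 0
#' assigns zero density off the corresponding center axis, so the budget must
#' then be covered by the center lines alone.
#'
#' @param ny,nz phase-encode grid dimensions (default: the acquired
#'   115 x 9 grid).
#' @param R target acceleration (>= 1).
#' @param CL number of fully sampled central ky lines.
#' @param sigma_y,sigma_z Gaussian standard deviations as fractions of the
#'   axis lengths.
#' @param seed integer seed.
#' @return A [sampling_pattern()].
#' @export
generate_gaussian_pattern <- function(ny = 115L, nz = 9L, R, CL,
                                      sigma_y, sigma_z, seed = 1L) {
  ny <- as.integer(ny); nz <- as.integer(nz); CL <- as.integer(CL)
  if (R < 1) stop("`R` must be >= 1", call. = FALSE)
  if (CL < 0L) stop("`CL` must be >= 0", call. = FALSE)
  if (sigma_y < 0 || sigma_z < 0)
    stop("`sigma_y` and `sigma_z` must be >= 0", call. = FALSE)
  budget <- floor(ny * nz / R)
  if (CL * nz > budget)
    stop(sprintf("center lines (%d x %d = %d points) exceed the sampling budget floor(%d/%g) = %d",
                 CL, nz, CL * nz, ny * nz, R, budget), call. = FALSE)
  mask <- matrix(0L, ny, nz)
  cl <- center_line_indices(ny, CL)
  mask[cl + 1L, ] <- 1L
  remaining <- budget - CL * nz
  if (remaining > 0L) {
    cy <- ny %/% 2L
    cz <- nz %/% 2L
    dy <- (0:(ny - 1L)) - cy
    dz <- (0:(nz - 1L)) - cz
    logw_y <- if (sigma_y == 0) ifelse(dy == 0, 0, -Inf) else
      -dy^2 / (2 * (sigma_y * ny)^2)
    logw_z <- if (sigma_z == 0) ifelse(dz == 0, 0, -Inf) else
      -dz^2 / (2 * (sigma_z * nz)^2)
    logw <- outer(logw_y, logw_z, `+`)
    free <- which(mask == 0L & is.finite(logw))
    if (length(free) < remaining)
      stop("sampling density is zero on too many positions for the budget; raise CL or sigma",
           call. = FALSE)
    keys <- with_seed(seed, logw[free] - log(-log(stats::runif(length(free)))))
    # top-`remaining` Gumbel-perturbed weights = weighted draw w/o replacement
    take <- free[order(keys, decreasing = TRUE)[seq_len(remaining)]]
    mask[take] <- 1L
  }
  sampling_pattern(mask, R, CL, sigma_y, sigma_z, seed)
}

#' Summarize a sampling pattern
#'
#' @param p a [sampling_pattern()].
#' @return A list with `achieved_R`, `line_fraction` (sampled fraction per ky
#'   line), `n_full_lines` (count of fully sampled ky lines), and
#'   `center_of_mass` (mean 0-based (ky, kz) position of sampled points).
#' @export
pattern_summary <- function(p) {
  if (!inherits(p, "sampling_pattern"))
    stop("`p` must be a sampling_pattern", call. = FALSE)
  m <- p$mask
  frac <- rowMeans(m)
  pts <- which(m == 1L, arr.ind = TRUE) - 1L
  list(achieved_R = p$achieved_R,
       line_fraction = frac,
       n_full_lines = sum(frac == 1),
       center_of_mass = colMeans(pts))
}

#' Embed an acquired-grid pattern into a zero-filled grid
#'
#' Places the mask centrally in a larger (ky, kz) grid using the same padding
#' convention as [zero_fill()] (odd excess on the high-index side); the padded
#' lines are never sampled, so the acquired-grid budget is preserved.
#'
#' @param p a [sampling_pattern()].
#' @param ny,nz target grid dimensions.
#' @return A [sampling_pattern()] on the target grid. `achieved_R` is
#'   recomputed on the embedding grid.
#' @export
embed_pattern <- function(p, ny, nz = ncol(p$mask)) {
  ny <- as.integer(ny); nz <- as.integer(nz)
  if (ny < nrow(p$mask) || nz < ncol(p$mask))
    stop("target grid must be at least the pattern grid", call. = FALSE)
  out <- matrix(0L, ny, nz)
  lo_y <- pad_split(nrow(p$mask), ny)$low
  lo_z <- pad_split(ncol(p$mask), nz)$low
  out[lo_y + seq_len(nrow(p$mask)), lo_z + seq_len(ncol(p$mask))] <- p$mask
  sampling_pattern(out, p$R, p$CL, p$sigma_y, p$sigma_z, p$seed)
}

#' Write a sampling pattern to disk
#'
#' Persists the mask as a plain-text 0/1 grid and a bilevel PNG, plus a JSON
#' sidecar recording (R, CL, sigma_y, sigma_z, seed, achieved_R).
#'
#' @param p a [sampling_pattern()].
#' @param prefix output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_pattern <- function(p, prefix) {
  txt <- paste0(prefix, "_mask.txt")
  utils::write.table(p$mask, txt, row.names = FALSE, col.names = FALSE)
  pngf <- paste0(prefix, "_mask.png")
  png::writePNG(matrix(as.numeric(p$mask), nrow(p$mask)), pngf)
  side <- paste0(prefix, "_pattern.json")
  jsonlite::write_json(list(R = p$R, CL = p$CL, sigma_y = p$sigma_y,
                            sigma_z = p$sigma_z, seed = p$seed,
                            achieved_R = p$achieved_R),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(c(txt, pngf, side))
}

#' Read a sampling pattern written by [write_pattern()]
#'
#' @param prefix path prefix.
#' @return A [sampling_pattern()].
#' @export
read_pattern <- function(prefix) {
  mask <- as.matrix(utils::read.table(paste0(prefix, "_mask.txt")))
  dimnames(mask) <- NULL
  meta <- jsonlite::read_json(paste0(prefix, "_pattern.json"),
                              simplifyVector = TRUE)
  sampling_pattern(mask, meta$R, meta$CL, meta$sigma_y, meta$sigma_z,
                   meta$seed)
}
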