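# Brute-force oracles: direct elementwise/windowed evaluation of the metric
# definitions, independent of the vectorized implementations.
psnr_oracle <- function(ref, recon, mask) {
  e <- (ref - recon)[mask]
  20 * log10(max(ref[mask]) / sqrt(sum(e^2) / length(e)))
}
nrmse_oracle <- function(ref, recon, mask) {
  e <- (ref - recon)[mask]
  sqrt(sum(e^2) / length(e)) / (sum(ref[mask]) / sum(mask))
}
ssim_oracle <- function(ref, recon, mask, w = 7, K1 = 0.01, K2 = 0.03) {
  r <- w %/% 2
  L <- max(ref[mask])
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  vals <- c()
  for (i in (r + 1):(nrow(ref) - r))
    for (j in (r + 1):(ncol(ref) - r)) {
      if (!mask[i, j]) next
      inwin <- mask[(i - r):(i + r), (j - r):(j + r)]
      A <- ref[(i - r):(i + r), (j - r):(j + r)][inwin]
      B <- recon[(i - r):(i + r), (j - r):(j + r)][inwin]
      mA <- mean(A); mB <- mean(B)
      vA <- mean((A - mA)^2); vB <- mean((B - mB)^2)
      cAB <- mean((A - mA) * (B - mB))
      vals <- c(vals, (2 * mA * mB + C1) * (2 * cAB + C2) /
                        ((mA^2 + mB^2 + C1) * (vA + vB + C2)))
    }
  mean(vals)
}
grad_oracle <- function(img, mask, k) {
  n1 <- nrow(img); n2 <- ncol(img)
  gx <- matrix(0, n1, n2); gy <- gx
  clamp <- function(v, n) min(max(v, 1), n)
  for (i in 1:n1)
    for (j in 1:n2) {
      sx <- 0; sy <- 0
      for (a in -1:1)
        for (b in -1:1) {
          v <- img[clamp(i + a, n1), clamp(j + b, n2)] # replicate padding
          sx <- sx + k$gx[a + 2, b + 2] * v
          sy <- sy + k$gy[a + 2, b + 2] * v
        }
      gx[i, j] <- sx; gy[i, j] <- sy
    }
  mean(sqrt(gx^2 + gy^2)[mask])
}
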