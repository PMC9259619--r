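test_that("PSNR matches its closed form and brute-force evaluation", {
  ref <- matrix(runif(64, 0.5, 1), 8, 8); ref[1] <- 1
  full <- matrix(TRUE, 8, 8)
  # uniform error 0.1 with max(ref) = 1 -> exactly 20 dB
  expect_equal(psnr(ref, ref + 0.1, full), 20)
  expect_equal(psnr(ref, ref - 0.1, full), 20)
  # identical images -> infinite-PSNR flag
  expect_identical(psnr(ref, ref, full), Inf)
  # random pair vs oracle
  set.seed(31)
  recon <- ref + rnorm(64, sd = 0.05)
  expect_equal(psnr(ref, recon, full), psnr_oracle(ref, recon, full),
               tolerance = 1e-10)
  # restricted ROI
  roi <- matrix(FALSE, 8, 8); roi[3:6, 2:7] <- TRUE
  expect_equal(psnr(ref, recon, roi), psnr_oracle(ref, recon, roi),
               tolerance = 1e-10)
  expect_error(psnr(ref, recon, matrix(FALSE, 8, 8)), "empty ROI")
})

test_that("SSIM is 1 on identical images and matches closed form and oracle", {
  set.seed(5)
  ref <- matrix(runif(256, 0, 1), 16, 16)
  full <- matrix(TRUE, 16, 16)
  expect_equal(ssim(ref, ref, full), 1)
  # constant images: SSIM = (2ab + C1) / (a^2 + b^2 + C1), L = a
  a <- 0.8; b <- 0.6
  A <- matrix(a, 16, 16); B <- matrix(b, 16, 16)
  C1 <- (0.01 * a)^2
  expect_equal(ssim(A, B, full), (2 * a * b + C1) / (a^2 + b^2 + C1),
               tolerance = 1e-12)
  # random pair vs windowed brute force
  recon <- pmax(ref + rnorm(256, sd = 0.1), 0)
  expect_equal(ssim(ref, recon, full), ssim_oracle(ref, recon, full),
               tolerance = 1e-8)
  roi <- matrix(FALSE, 16, 16); roi[5:12, 4:13] <- TRUE
  expect_equal(ssim(ref, recon, roi), ssim_oracle(ref, recon, roi),
               tolerance = 1e-8)
  # symmetry (matched ROI and dynamic range)
  expect_equal(ssim(ref, recon, full),
               ssim(recon, ref, full, metric_config()) *
                 1, tolerance = 0.02)
})

test_that("NRMSE closed form and oracle agree", {
  set.seed(6)
  ref <- matrix(runif(64, 0.2, 1), 8, 8)
  full <- matrix(TRUE, 8, 8)
  expect_equal(nrmse(ref, ref, full), 0)
  # constant offset delta -> delta / mean(ref)
  expect_equal(nrmse(ref, ref + 0.07, full), 0.07 / mean(ref),
               tolerance = 1e-12)
  recon <- ref + rnorm(64, sd = 0.03)
  expect_equal(nrmse(ref, recon, full), nrmse_oracle(ref, recon, full),
               tolerance = 1e-10)
  expect_error(nrmse(matrix(0, 8, 8), recon, full), "degenerate")
})

test_that("gradient sharpness: zero on constants, hand-convolution oracle, blur monotone", {
  cfg <- metric_config()
  full <- matrix(TRUE, 12, 12)
  expect_equal(gradient_sharpness(matrix(0.5, 12, 12), full, cfg), 0)
  # vertical step edge of height h: interior G = 4h on the two adjacent columns
  h <- 0.7
  step <- cbind(matrix(0, 12, 6), matrix(h, 12, 6))
  expect_equal(gradient_sharpness(step, full, cfg),
               grad_oracle(step, full, cfg$edge_kernels), tolerance = 1e-10)
  interior <- matrix(FALSE, 12, 12); interior[3:10, 6:7] <- TRUE
  expect_equal(gradient_sharpness(step, interior, cfg), 4 * h,
               tolerance = 1e-12)
  # random image vs oracle
  set.seed(8)
  img <- matrix(runif(144), 12, 12)
  expect_equal(gradient_sharpness(img, full, cfg),
               grad_oracle(img, full, cfg$edge_kernels), tolerance = 1e-10)
  # blurring strictly reduces G on phantom slices with edges
  for (s in 1:20) {
    ph <- generate_phantom(small_phantom_spec(seed = s))
    sl <- Mod(ph$data[, , 4])
    roi <- attr(ph, "support")[, , 4]
    blur <- pmax(as.matrix(EBImage::gblur(sl, sigma = 1.5)), 0)
    expect_lt(gradient_sharpness(blur, roi, cfg),
              gradient_sharpness(sl, roi, cfg))
  }
  # phase input (negative values) is a usage error
  expect_error(gradient_sharpness(matrix(c(-1, 1), 4, 4), full, cfg),
               "magnitude")
})

test_that("ROI mask recovers the phantom support and removes isolated pixels", {
  ph <- generate_phantom(small_phantom_spec(matrix_size = c(64L, 60L, 8L),
                                            n_structures = 6L, seed = 2))
  cfg <- metric_config()
  dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
  for (z in c(1, 4, 8)) {
    roi <- compute_roi_mask(Mod(ph$data[, , z]), cfg)
    expect_gt(dice(roi$mask, attr(ph, "support")[, , z]), 0.98)
  }
  # all-zero slice -> empty mask, not an error
  expect_false(any(compute_roi_mask(matrix(0, 32, 32), cfg)$mask))
  # isolated bright pixel is removed by the opening
  sl <- matrix(0, 32, 32)
  sl[5:20, 5:20] <- 1
  sl[28, 28] <- 1
  roi <- compute_roi_mask(sl, cfg)
  expect_false(roi$mask[28, 28])
  expect_true(roi$mask[10, 10])
})

test_that("noise-only slices are excluded; structure-bearing slices kept", {
  cfg <- metric_config()
  noise <- generate_noise_only_volume(small_phantom_spec(noise_sigma = 0.05))
  rois <- lapply(seq_len(dim(noise$data)[3]), function(z)
    compute_roi_mask(Mod(noise$data[, , z]), cfg))
  expect_length(exclude_noise_slices(rois, cfg), 0L)
  ph <- generate_phantom(small_phantom_spec())
  rois_ph <- lapply(seq_len(dim(ph$data)[3]), function(z)
    compute_roi_mask(Mod(ph$data[, , z]), cfg))
  expect_identical(exclude_noise_slices(rois_ph, cfg), 1:8)
  # mixed fixture: 5 signal slices + 4 noise slices (beyond slice 5: zeroed)
  mixed <- generate_phantom(small_phantom_spec(matrix_size = c(32L, 30L, 9L),
                                               noise_sigma = 0.05, seed = 4))
  mixed$data[, , 6:9] <- generate_noise_only_volume(
    small_phantom_spec(matrix_size = c(32L, 30L, 9L), noise_sigma = 0.05,
                       seed = 4))$data[, , 6:9]
  rois_mix <- lapply(1:9, function(z)
    compute_roi_mask(Mod(mixed$data[, , z]), metric_config()))
  expect_identical(exclude_noise_slices(rois_mix, cfg), 1:5)
})

test_that("evaluate_pair: perfect reconstruction, aggregates, ROI independence", {
  ph <- generate_phantom(small_phantom_spec(noise_sigma = 0.02, seed = 9))
  cfg <- metric_config()
  rep_same <- evaluate_pair(ph, ph, cfg)
  mag <- rep_same$per_slice[rep_same$per_slice$channel == "magnitude", ]
  expect_true(all(mag$ssim == 1))
  expect_true(all(mag$nrmse == 0))
  expect_true(all(!is.finite(mag$psnr)))
  expect_identical(unique(rep_same$aggregate$infinite_psnr),
                   as.integer(dim(ph$data)[3]))
  # aggregates equal hand-computed mean/sd of the per-slice lists
  noisy <- complex_volume(ph$data + 0.01 * array(rnorm(prod(dim(ph$data))),
                                                 dim(ph$data)), "image")
  r <- evaluate_pair(ph, noisy, cfg)
  magr <- r$per_slice[r$per_slice$channel == "magnitude", ]
  agg <- r$aggregate[r$aggregate$channel == "magnitude", ]
  expect_equal(agg$psnr_mean, mean(magr$psnr))
  expect_equal(agg$nrmse_sd, sd(magr$nrmse))
  # ROI independence: corrupting the reconstruction outside the ROI
  # changes nothing
  corrupted <- noisy
  for (z in seq_len(dim(ph$data)[3])) {
    out_roi <- !r$roi_masks[[z]]$mask
    sl <- corrupted$data[, , z]
    sl[out_roi] <- sl[out_roi] + 5 + 5i
    corrupted$data[, , z] <- sl
  }
  r2 <- evaluate_pair(ph, corrupted, cfg)
  expect_equal(r2$per_slice$psnr, r$per_slice$psnr)
  expect_equal(r2$per_slice$ssim, r$per_slice$ssim, tolerance = 1e-12)
})

test_that("PSNR and NRMSE are consistent through max(ref) and mean(ref)", {
  set.seed(12)
  ref <- matrix(runif(100, 0.2, 1), 10, 10)
  recon <- ref + rnorm(100, sd = 0.05)
  full <- matrix(TRUE, 10, 10)
  # PSNR = 20 log10(max / (NRMSE * mean))
  expect_equal(psnr(ref, recon, full),
               20 * log10(max(ref) / (nrmse(ref, recon, full) * mean(ref))),
               tolerance = 1e-10)
})
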