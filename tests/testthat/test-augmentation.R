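test_that("transform draws are deterministic and cover all six types uniformly", {
  expect_identical(unclass(draw_transform(5)), unclass(draw_transform(5)))
  n <- 1e4
  sel <- unlist(lapply(seq_len(n), function(s) draw_transform(s, n_ops = 1)$selected_ops))
  tab <- table(sel)
  expect_setequal(names(tab), c("shift", "flip_h", "flip_v", "shear", "zoom",
                                "rotation"))
  # each type within 3 standard errors of 1/6
  se <- sqrt(1 / 6 * 5 / 6 / n)
  expect_true(all(abs(tab / n - 1 / 6) < 3 * se))
})

test_that("drawn rotation angles are uniform on [0, 360)", {
  n <- 1e4
  rot <- vapply(seq_len(n), function(s) draw_transform(s, n_ops = 2)$rotation_deg,
                numeric(1))
  rot <- rot[rot != 0] # slices where rotation was among the selected ops
  expect_gt(length(rot), 2000)
  ks <- suppressWarnings(ks.test(rot, "punif", 0, 360))
  # KS distance below the 1% critical value
  expect_lt(unname(ks$statistic), 1.63 / sqrt(length(rot)))
})

test_that("identity transform returns the volume exactly", {
  v <- generate_phantom(small_phantom_spec(noise_sigma = 0.02))
  out <- apply_joint(v, transform_spec())
  expect_identical(out$data, v$data)
})

test_that("flips are exact involutions", {
  v <- random_volume(c(17, 12, 8), seed = 2)
  th <- transform_spec(flip_h = TRUE)
  expect_identical(apply_joint(apply_joint(v, th), th)$data, v$data)
  tv <- transform_spec(flip_v = TRUE)
  expect_identical(apply_joint(apply_joint(v, tv), tv)$data, v$data)
  # a single flip actually reverses the axis
  expect_identical(apply_joint(v, th)$data[, , 1], v$data[17:1, , 1])
})

test_that("four 90-degree rotations recover a square slice via grid permutation", {
  v <- random_volume(c(16, 16, 8), seed = 3)
  t90 <- transform_spec(rotation_deg = 90)
  out <- v
  for (i in 1:4) out <- apply_joint(out, t90)
  expect_lt(max(Mod(out$data - v$data)), 1e-6)
  # oracle: a single 90-degree rotation equals the direct index permutation
  # out[i, j] = in[j, n + 1 - i]
  one <- apply_joint(v, t90)$data[, , 1]
  perm <- t(v$data[, 16:1, 1])
  expect_lt(max(Mod(one - perm)), 1e-6)
})

test_that("integer shifts move content exactly and fill with zeros", {
  v <- random_volume(c(12, 12, 8), seed = 4)
  out <- apply_joint(v, transform_spec(shift_x = 3))
  expect_identical(out$data[4:12, , 1], v$data[1:9, , 1])
  expect_true(all(out$data[1:3, , 1] == 0i))
})

test_that("the joint map is linear: transform commutes with Re/Im", {
  v <- random_volume(c(24, 20, 8), seed = 6)
  t <- draw_transform(17)
  out <- apply_joint(v, t)
  re_only <- complex_volume(array(Re(v$data) + 0i, dim(v$data)))
  expect_lt(max(abs(Re(out$data) - Re(apply_joint(re_only, t)$data))), 1e-12)
})

test_that("transform parameters respect their documented ranges", {
  specs <- lapply(1:500, draw_transform)
  expect_true(all(vapply(specs, function(s) abs(s$shift_x) <= 50, logical(1))))
  expect_true(all(vapply(specs, function(s) s$shear_deg >= 0 && s$shear_deg <= 45, logical(1))))
  expect_true(all(vapply(specs, function(s) s$zoom >= 0.75 && s$zoom <= 1.25, logical(1))))
  expect_true(all(vapply(specs, function(s) s$rotation_deg >= 0 && s$rotation_deg < 360, logical(1))))
  expect_error(transform_spec(zoom = 0.5), "zoom")
  expect_error(transform_spec(shift_x = 60), "-50")
})

test_that("make_training_pair: all-ones mask + identity gives input == target", {
  v <- generate_phantom(small_phantom_spec(matrix_size = c(32L, 30L, 9L),
                                           noise_sigma = 0.02))
  net_v <- ifft_centered(zero_fill(fft_centered(v), c(32L, 32L, 9L)))
  ones <- sampling_pattern(matrix(1L, 32, 9), 1, 0, 0.1, 0.1, 1)
  pairs <- make_training_pair(net_v, ones)
  expect_length(pairs, 9L)
  for (p in pairs) {
    expect_lt(max(abs(p$input - p$target)), 1e-10)
    expect_identical(dim(p$input), c(32L, 32L, 2L))
  }
  expect_identical(vapply(pairs, `[[`, integer(1), "slice_index"), 1:9)
})

test_that("pairs share one scale and un-normalize back to the augmented volume", {
  v <- generate_phantom(small_phantom_spec(matrix_size = c(32L, 30L, 9L),
                                           noise_sigma = 0.02))
  net_v <- ifft_centered(zero_fill(fft_centered(v), c(32L, 32L, 9L)))
  pat <- generate_gaussian_pattern(30, 9, R = 3, CL = 3, sigma_y = 0.15,
                                   sigma_z = 0.25, seed = 5)
  t <- draw_transform(9)
  pairs <- make_training_pair(net_v, pat, t)
  scales <- vapply(pairs, `[[`, numeric(1), "scale")
  expect_true(all(scales == scales[1]))
  # round trip: targets, re-assembled and un-normalized, equal the augmented volume
  aug <- apply_joint(net_v, t)
  rebuilt <- array(0i, dim(aug$data))
  for (p in pairs)
    rebuilt[, , p$slice_index] <-
      complex(real = p$target[, , 1], imaginary = p$target[, , 2]) * p$scale
  expect_lt(max(Mod(rebuilt - aug$data)), 1e-10)
})

test_that("k-space-domain input to apply_joint is a usage error", {
  k <- fft_centered(random_volume(c(8, 8, 8)))
  expect_error(apply_joint(k, transform_spec()), "image")
})
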