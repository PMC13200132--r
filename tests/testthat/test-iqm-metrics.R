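test_that("SSIM satisfies identity, symmetry and the zero-variance closed form", {
  set.seed(42)
  a <- norm_img(matrix(runif(64 * 64), 64, 64))
  expect_equal(ssim(a, a), 1)

  c1 <- norm_img(matrix(0.25, 32, 32))
  c2 <- norm_img(matrix(0.75, 32, 32))
  closed <- (2 * 0.25 * 0.75 + 1e-4) / (0.25^2 + 0.75^2 + 1e-4)
  expect_equal(ssim(c1, c2), closed, tolerance = 1e-6)

  b <- norm_img(pmin(pmax(a$pixels + matrix(rnorm(64 * 64, 0, 0.05), 64, 64), 0), 1))
  expect_equal(ssim(a, b), ssim(b, a))
  expect_gt(ssim(a, b), closed)
  expect_lt(ssim(a, b), 1)

  expect_error(ssim(a, c1), "dimensions")
})

test_that("SSIM agrees with the scikit-image reference implementation", {
  # oracle value frozen from skimage structural_similarity(gaussian_weights=
  # TRUE, sigma=1.5, use_sample_covariance=FALSE, data_range=1) on the same
  # seeded fixture
  set.seed(42)
  m1 <- matrix(runif(64 * 64), 64, 64)
  m2 <- pmin(pmax(m1 + matrix(rnorm(64 * 64, 0, 0.05), 64, 64), 0), 1)
  expect_equal(ssim(norm_img(m1), norm_img(m2)), 0.9851706893, tolerance = 1e-8)
})

test_that("MS-SSIM handles identity, blur tolerance and small images", {
  img <- generate_phantom(phantom_spec(edge_sigma = 0.5, noise_sd = 0))
  expect_equal(ms_ssim(img, img), 1)

  blurred <- norm_img(orbitsharp:::gaussian_blur(img$pixels, 4))
  expect_gte(ms_ssim(img, blurred), ssim(img, blurred))

  small <- norm_img(matrix(runif(64 * 64), 64, 64))
  expect_warning(v <- ms_ssim(small, small), "3")
  expect_equal(v, 1)
})

test_that("PSNR and SNR match closed forms and report Inf for identity", {
  ref <- norm_img(matrix(0.5, 32, 32))
  test <- norm_img(matrix(0.6, 32, 32))
  expect_equal(psnr(ref, test), 20)          # MSE 0.01, peak 1
  expect_equal(snr_ref(ref, test), 10 * log10(0.25 / 0.01))
  expect_identical(psnr(ref, ref), Inf)
  expect_identical(snr_ref(ref, ref), Inf)

  # difference RMS 0.05 against signal RMS 0.5 -> 20 dB
  test2 <- norm_img(matrix(0.55, 32, 32))
  expect_equal(snr_ref(ref, test2), 20)
})

test_that("blur percentage anchors at 0 and 100 and grows with blur", {
  img <- generate_phantom(phantom_spec(edge_sigma = 1, noise_sd = 0.02, seed = 3))
  expect_identical(blur_percentage(img, img), 0)
  expect_identical(blur_percentage(img, norm_img(matrix(0.5, 256, 256))), 100)

  sig <- c(0, 0.5, 1, 2, 4)
  vals <- vapply(sig, function(s) {
    t <- if (s == 0) img else norm_img(orbitsharp:::gaussian_blur(img$pixels, s))
    blur_percentage(img, t)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  flat16 <- norm_img(matrix(0.2, 16, 16))
  expect_warning(blur_percentage(flat16, norm_img(matrix(runif(256), 16, 16))),
                 "undefined")
})

test_that("perceptual blur metric orders content by blur and handles constants", {
  cb <- checkerboard_image(64)
  cb_blur <- norm_img(orbitsharp:::gaussian_blur(cb$pixels, 1))
  expect_lt(perceptual_blur_metric(cb), 0.2)   # sharpest possible content
  expect_lt(perceptual_blur_metric(cb), perceptual_blur_metric(cb_blur))

  expect_warning(v <- perceptual_blur_metric(norm_img(matrix(0.3, 16, 16))), "constant")
  expect_identical(v, 1)

  sig <- c(0.5, 1, 2, 3)
  vals <- vapply(sig, function(s)
    perceptual_blur_metric(generate_phantom(phantom_spec(edge_sigma = s, noise_sd = 0))),
    numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("PSI decreases with blur, favors the sharper arm, flags edge-free input", {
  p1 <- psi(generate_phantom(phantom_spec(edge_sigma = 0.5, noise_sd = 0)))
  p2 <- psi(generate_phantom(phantom_spec(edge_sigma = 2, noise_sd = 0)))
  expect_true(p1$valid && p2$valid)
  expect_gt(p1$value, p2$value)
  expect_gte(p2$value, 0)

  cr <- generate_phantom(phantom_spec(edge_sigma = 1.6, noise_sd = 0.03, seed = 21))
  dlr <- generate_phantom(phantom_spec(edge_sigma = 0.9, noise_sd = 0.012,
                                       contrast_scale = 0.95, seed = 22))
  expect_gt(psi(dlr)$value, psi(cr)$value)

  expect_false(psi(norm_img(matrix(0.4, 64, 64)))$valid)
})

test_that("external metrics can be registered and retrieved by name", {
  register_metric("mad_diff", function(ref, test) mean(abs(ref$pixels - test$pixels)),
                  reference = TRUE)
  tab <- list_metrics()
  expect_true("mad_diff" %in% tab$name)
  fn <- orbitsharp:::get_registered_metric("mad_diff")
  a <- norm_img(matrix(0.2, 8, 8)); b <- norm_img(matrix(0.5, 8, 8))
  expect_equal(fn$fn(a, b), 0.3)
  expect_error(orbitsharp:::get_registered_metric("no_such"), "no registered")
})
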