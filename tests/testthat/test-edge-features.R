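test_that("steepness on a unit step is exactly the central-difference value 0.5", {
  img <- step_image(32, 32, 16)
  em <- detect_edges(img, "sobel")
  st <- edge_steepness(img, em)
  expect_true(st$valid)
  expect_true(all(st$values == 0.5))
  expect_equal(st$mean, 0.5)
})

test_that("steepness equals an exhaustive window-max search", {
  # independent oracle: per-pixel loop over the clipped window
  brute_steepness <- function(mag, mask, win) {
    r <- (win - 1) %/% 2
    px <- which(mask, arr.ind = TRUE)
    apply(px, 1, function(p) {
      rows <- max(1, p[1] - r):min(nrow(mag), p[1] + r)
      cols <- max(1, p[2] - r):min(ncol(mag), p[2] + r)
      max(mag[rows, cols])
    })
  }
  set.seed(7)
  for (i in 1:25) {
    img <- norm_img(matrix(runif(32 * 32), 32, 32))
    mask <- matrix(runif(32 * 32) < 0.05, 32, 32)
    if (!any(mask)) next
    em <- manual_edge_map(mask)
    for (win in c(3L, 5L)) {
      got <- edge_steepness(img, em, win)
      mag <- compute_gradient(img)$magnitude
      expect_equal(got$values, unname(brute_steepness(mag, mask, win)))
    }
  }
})

test_that("blurring strictly lowers mean steepness", {
  img <- generate_phantom(phantom_spec(edge_sigma = 0.5, noise_sd = 0))
  blur <- generate_phantom(phantom_spec(edge_sigma = 2, noise_sd = 0))
  em <- detect_edges(img, "sobel")
  expect_gt(edge_steepness(img, em)$mean,
            edge_steepness(blur, detect_edges(blur, "sobel"))$mean)
})

test_that("profiles follow the gradient direction and reject border pixels", {
  img <- step_image(32, 32, 16)
  g <- compute_gradient(img)
  # bilinear sampling of a step is monotone; the cubic adds ringing by design
  p <- extract_edge_profile(img, c(10, 16), g, interp = "bilinear")
  expect_true(p$valid)
  expect_true(all(diff(p$samples) >= -1e-9))    # monotone rise 0 -> 1
  expect_equal(p$samples[1], 0, tolerance = 1e-9)
  expect_equal(p$samples[length(p$samples)], 1, tolerance = 1e-9)
  expect_equal(length(p$samples) %% 2, 1)

  # 45-degree step: direction within 5 degrees of the diagonal
  m45 <- norm_img(outer(1:64, 1:64, function(r, c) as.numeric(r + c > 65)))
  g45 <- compute_gradient(m45)
  p45 <- extract_edge_profile(m45, c(32, 33), g45)
  ang <- acos(abs(sum(p45$direction * c(sqrt(2) / 2, sqrt(2) / 2)))) * 180 / pi
  expect_lt(ang, 5)

  # profile support would leave the image: invalid
  near <- extract_edge_profile(img, c(10, 16), g, half_length = 20)
  expect_false(near$valid)
  # zero gradient: invalid
  expect_false(extract_edge_profile(img, c(10, 5), g)$valid)
})

test_that("10-90 width matches closed forms on steps and erf edges", {
  img <- step_image(32, 32, 16)
  g <- compute_gradient(img)
  # linear 1-px transition under bilinear sampling: 10-90 span = 0.8 px
  p <- extract_edge_profile(img, c(10, 16), g, interp = "bilinear")
  expect_equal(edge_width(p), 0.8, tolerance = 1e-9)

  # erf edge, sigma = 1.5: width = 2.5631 * 1.5 within 3%
  f <- summarize_edge_features(erf_image(1.5), "sobel")
  expect_equal(f$mean_width_px, 2.5631 * 1.5, tolerance = 0.03)

  # constant profile: contrast below floor -> invalid
  flatp <- structure(list(samples = rep(0.5, 41), spacing = 0.25,
                          center_index = 21L, direction = c(1, 0),
                          valid = TRUE), class = "edge_profile")
  expect_true(is.na(edge_width(flatp)))
})

test_that("width calibration holds within 3% for sigma in [1, 3] at any orientation", {
  for (th in c(0, 30) * pi / 180)
    for (sg in c(1, 1.5, 2, 3)) {
      f <- summarize_edge_features(erf_image(sg, th), "sobel", half_length = 13)
      expect_gt(f$n_valid_widths, 0)
      ratio <- f$mean_width_px / (2.5631 * sg)
      expect_gt(ratio, 0.97)
      expect_lt(ratio, 1.03)
    }
})

test_that("edge contrast reflects the local intensity range", {
  img <- step_image(32, 32, 16)
  em <- detect_edges(img, "sobel")
  expect_equal(edge_contrast(img, em)$mean, 1.0)     # noise-free unit step

  # two-region phantom 0.2 / 0.7 with hard edge: window straddles both
  two <- norm_img(cbind(matrix(0.2, 32, 16), matrix(0.7, 32, 16)))
  em2 <- detect_edges(two, "sobel")
  expect_equal(edge_contrast(two, em2)$mean, 0.5, tolerance = 1e-9)

  # strong blur narrows the local range seen by a small window
  two_blur <- norm_img(orbitsharp:::gaussian_blur(two$pixels, 3))
  em3 <- detect_edges(two_blur, "sobel")
  expect_lt(edge_contrast(two_blur, em3, neighborhood = 3L)$mean, 0.5)
})

test_that("summarize_edge_features plumbs detectors and flags empty maps", {
  img <- generate_phantom(phantom_spec(edge_sigma = 1, noise_sd = 0.01, seed = 5))
  res <- lapply(c("roberts", "sobel", "canny"),
                function(d) summarize_edge_features(img, d))
  for (r in res) {
    expect_s3_class(r, "edge_feature_result")
    expect_true(r$valid)
    expect_lte(r$n_valid_widths, r$n_edge_pixels)
    expect_gt(r$mean_steepness, 0)
    expect_gt(r$mean_width_px, 0)
    expect_true(r$mean_contrast >= 0 && r$mean_contrast <= 1)
  }
  expect_setequal(vapply(res, `[[`, "", "detector"),
                  c("roberts", "sobel", "canny"))

  none <- summarize_edge_features(norm_img(matrix(0.3, 32, 32)), "sobel")
  expect_false(none$valid)
  expect_identical(none$n_edge_pixels, 0L)
})

test_that("paired CR-like/DLR-like phantoms separate in steepness and width", {
  cr <- generate_phantom(phantom_spec(edge_sigma = 1.6, noise_sd = 0.03, seed = 8))
  dlr <- generate_phantom(phantom_spec(edge_sigma = 0.9, noise_sd = 0.012,
                                       contrast_scale = 0.95, seed = 9))
  for (d in c("roberts", "sobel", "canny")) {
    fc <- summarize_edge_features(cr, d)
    fd <- summarize_edge_features(dlr, d)
    expect_gt(fd$mean_steepness, fc$mean_steepness, label = d)
    expect_lt(fd$mean_width_px, fc$mean_width_px, label = d)
  }
})

test_that("steepness and width are stable under 30-degree rotation", {
  # odd canvas puts the edge through pixel centers (generic phase; the
  # half-pixel phase is the worst case for axis-aligned discrete gradients)
  f0 <- summarize_edge_features(erf_image(1.5, 0, n = 97), "sobel")
  f30 <- summarize_edge_features(erf_image(1.5, 30 * pi / 180, n = 97), "sobel")
  expect_lt(abs(f30$mean_width_px / f0$mean_width_px - 1), 0.05)
  expect_lt(abs(f30$mean_steepness / f0$mean_steepness - 1), 0.05)
})
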