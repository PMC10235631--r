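test_that("flat_field_correct preserves constants, mean, and restores texture", {
  const <- gray_image(matrix(0.4, 32, 32))
  expect_equal(flat_field_correct(const, 5)$pixels, const$pixels,
               tolerance = 1e-12)

  # texture + low-frequency ramp: correction raises correlation with texture
  set.seed(21)
  n <- 128
  tex <- matrix(runif(n * n, 0.3, 0.5), n)
  ramp <- matrix(rep(seq(0, 0.4, length.out = n), each = n), n)
  img <- gray_image(pmin(tex + ramp, 1))
  corr <- flat_field_correct(img, 20)
  expect_gt(cor(as.vector(corr$pixels), as.vector(tex)),
            cor(as.vector(img$pixels), as.vector(tex)))
  expect_lt(abs(mean(corr$pixels) - mean(img$pixels)) / mean(img$pixels), 0.01)

  expect_error(flat_field_correct(gray_image(matrix(0, 32, 32)), 5),
               "degenerate background")
  expect_error(flat_field_correct(img, -1), "positive")
})

test_that("reduce_haze is identity at amount 0, fixes constants, restores contrast", {
  img <- rand_gray(48, seed = 3)
  expect_identical(reduce_haze(img, 0)$pixels, img$pixels)

  const <- gray_image(matrix(0.6, 32, 32))
  for (a in c(0.05, 0.5, 1)) {
    expect_equal(reduce_haze(const, a)$pixels, const$pixels, tolerance = 1e-9)
  }

  # texture under an additive flat veil: dehazing must not reduce variance
  set.seed(9)
  tex <- matrix(runif(64 * 64, 0, 0.4), 64)
  hazy <- gray_image(tex + 0.5)
  out <- reduce_haze(hazy, 0.05)
  expect_gte(var(as.vector(out$pixels)), var(as.vector(hazy$pixels)))

  expect_error(reduce_haze(img, 1.5), "\\[0, 1\\]")
})

test_that("stretch_window maps quantiles, is affine-invariant and flags degenerate input", {
  img <- rand_gray(64, seed = 5)
  # already spanning [0, 1] with clip = 0 -> unchanged
  spans <- stretch_window(gray_image((img$pixels - min(img$pixels)) /
                                       diff(range(img$pixels))), 0)
  expect_equal(spans$pixels, (img$pixels - min(img$pixels)) /
                 diff(range(img$pixels)), tolerance = 1e-12)

  out <- stretch_window(img, 0.001)
  n <- length(img$pixels)
  expect_lte(sum(out$pixels == 1), ceiling(0.001 * n) + 1)
  expect_gte(sum(out$pixels >= 1 - 1e-9), floor(0.001 * n))

  # affine invariance: a*I + b gives the same output (exact)
  aff <- gray_image(0.5 * img$pixels + 0.2)
  expect_equal(stretch_window(aff, 0.01)$pixels,
               stretch_window(img, 0.01)$pixels, tolerance = 1e-12)

  expect_warning(z <- stretch_window(gray_image(matrix(0.3, 16, 16)), 0.01),
                 "degenerate")
  expect_true(all(z$pixels == 0))
  expect_error(stretch_window(img, 0.5), "0.5")
})

test_that("windowing and flat-field are stable under re-application", {
  # exact fixed points: clip = 0 after one application
  img <- rand_gray(64, seed = 6)
  once <- stretch_window(img, 0)
  expect_equal(stretch_window(once, 0)$pixels, once$pixels, tolerance = 1e-6)
  # constant image is an exact fixed point of flat-field correction
  const <- gray_image(matrix(0.5, 32, 32))
  expect_equal(flat_field_correct(flat_field_correct(const, 6), 6)$pixels,
               flat_field_correct(const, 6)$pixels, tolerance = 1e-6)
  # on smooth texture a second pass moves pixels only marginally (the
  # operator is not an exact projection; see the methods vignette)
  smooth <- gray_image(0.4 + 0.2 * blob_texture(rand_gray(96, seed = 8),
                                                0.05, 0.5, 8)$pixels)
  f1 <- flat_field_correct(smooth, 12)
  f2 <- flat_field_correct(f1, 12)
  expect_lt(max(abs(f2$pixels - f1$pixels)), 2e-2)
})

test_that("estimate_sod fits the calibration line", {
  # exact line through two points
  est <- estimate_sod(cbind(c(1000, 1100), c(900, 990)), 1050)
  expect_equal(as.numeric(est), 945, tolerance = 1e-9)
  # exact line through many points: zero residual at any query
  sid <- seq(900, 1200, by = 50)
  est2 <- estimate_sod(cbind(sid, 0.85 * sid + 30), 1111)
  expect_equal(as.numeric(est2), 0.85 * 1111 + 30, tolerance = 1e-9)
  # OLS slope recovery from noisy pairs
  set.seed(14)
  sid <- runif(40, 900, 1300)
  sod <- 0.9 * sid + 10 + rnorm(40, sd = 5)
  est3 <- estimate_sod(cbind(sid, sod), 1000)
  fit <- lm(sod ~ sid)
  ci <- confint(fit)["sid", ]
  expect_gte(attr(est3, "a"), ci[1])
  expect_lte(attr(est3, "a"), ci[2])
  expect_true(ci[1] <= 0.9 && 0.9 <= ci[2])
  expect_error(estimate_sod(cbind(c(1000, 1000), c(900, 910)), 1000),
               "rank-deficient")
})

test_that("normalize_magnification resamples to the target spacing", {
  img <- rand_gray(64, seed = 2)
  img$spacing_mm <- 0.1
  # magnification 1, target = detector spacing -> unchanged
  cal1 <- geometry_calibration(1000, 1000)
  out1 <- normalize_magnification(img, cal1, 0.1)
  expect_equal(out1$pixels, img$pixels)
  expect_equal(out1$spacing_mm, 0.1)
  # magnification 2 -> linear dimensions halve
  cal2 <- geometry_calibration(1000, 500)
  out2 <- normalize_magnification(img, cal2, 0.1)
  expect_equal(dim(out2$pixels), c(32L, 32L))
  # round-trip on a smooth fixture keeps correlation > 0.95
  smooth <- gray_image(0.5 + 0.4 * outer(sin(seq(0, 3, length.out = 64)),
                                         cos(seq(0, 2, length.out = 64))))
  down <- normalize_magnification(smooth, cal2, 0.1)
  up <- bilinear_resize_for_test(down$pixels, 64, 64)
  expect_gt(cor(as.vector(up), as.vector(smooth$pixels)), 0.95)
  expect_error(geometry_calibration(1000, 1200), "sod")
})

test_that("roi_from_corners implements the central-2/3 diagonal construction", {
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  roi <- roi_from_corners(sq)
  expected <- rbind(c(5 / 3, 5 / 3), c(25 / 3, 5 / 3),
                    c(25 / 3, 25 / 3), c(5 / 3, 25 / 3))
  # compare as cyclically aligned point sets
  expect_equal(sort_rows(roi$vertices), sort_rows(expected), tolerance = 1e-12)
  expect_equal(abs(polygon_area_for_test(roi$vertices)), 400 / 9,
               tolerance = 1e-12)

  # centroid of the ROI equals the outer centroid for any parallelogram
  par <- rbind(c(1, 2), c(7, 3), c(9, 8), c(3, 7))
  roi2 <- roi_from_corners(par)
  expect_equal(colMeans(roi2$vertices), colMeans(par), tolerance = 1e-12,
               ignore_attr = TRUE)

  # similarity equivariance: rotate + scale corners -> ROI transforms alike
  th <- 0.7; sc <- 2.3
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  tr <- function(m) sc * m %*% t(rot) + matrix(c(5, -3), nrow(m), 2, byrow = TRUE)
  roi_t <- roi_from_corners(tr(sq))
  expect_equal(sort_rows(roi_t$vertices), sort_rows(tr(roi$vertices)),
               tolerance = 1e-9)

  expect_error(roi_from_corners(rbind(c(0, 0), c(1, 1), c(2, 2), c(3, 3))),
               "degenerate|collinear")
})

test_that("roi_mask rasterization matches the polygon area within 2%", {
  scale <- 10
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)) * scale
  roi <- roi_from_corners(sq)
  mask <- roi_mask(roi, 110, 110)
  expect_lt(abs(sum(mask) - (400 / 9) * scale^2) / ((400 / 9) * scale^2), 0.02)
})

test_that("ROI corner JSON round-trips", {
  path <- withr::local_tempfile(fileext = ".json")
  corners <- rbind(c(3, 4), c(20, 5), c(22, 19), c(2, 18))
  jsonlite::write_json(list(corners = corners), path)
  expect_equal(read_roi_corners(path), corners, ignore_attr = TRUE)
})
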