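test_that("dbc masses: constants, bounds, and a hand-enumerated toy grid", {
  const <- gray_image(matrix(0.25, 32, 32))
  g <- dbc_mass_grid(const, 4)
  expect_true(all(g$mass == 1))

  img <- rand_gray(32, seed = 44)
  g2 <- dbc_mass_grid(img, 5, c(2, 3))
  expect_true(all(g2$mass >= 1))

  # 16x16 two-level toy image, r = 4, offset (0,0): hand enumeration
  px <- matrix(0, 16, 16)
  px[1:8, 1:8] <- 1          # one all-bright quadrant
  px[9:16, 9:16] <- matrix(c(0, 1), 8, 8)  # striped quadrant
  toy <- gray_image(px)
  g3 <- dbc_mass_grid(toy, 4)
  h <- 256 * 4 / 16
  # boxes in the bright quadrant: max = min = 255 -> mass 1; boxes in the
  # striped quadrant and nowhere else span 0..255 -> floor(255/64) + 1 = 4
  q <- quantize_256(toy)
  expected <- c()
  for (by in c(1, 5, 9, 13)) {
    for (bx in c(1, 5, 9, 13)) {
      box <- q[by:(by + 3), bx:(bx + 3)]
      expected <- c(expected, floor(max(box) / h) - floor(min(box) / h) + 1)
    }
  }
  expect_equal(sort(g3$mass), sort(expected))
  expect_true(all(g3$mass %in% c(1, 4)))

  expect_error(dbc_mass_grid(img, 1), "2 <= r")
  expect_error(dbc_mass_grid(img, 4, c(4, 0)), "offset")
})

test_that("single-offset lacunarity follows the moment form", {
  expect_equal(lacunarity_single_offset(rep(3, 50)), 1)
  expect_equal(lacunarity_single_offset(c(1, 3, 1, 3)), 1.25)
  # moment form equals the probability (Q(M, r)) form
  set.seed(5)
  m <- sample(1:6, 100, replace = TRUE)
  q <- table(m) / length(m)
  vals <- as.numeric(names(q))
  expect_equal(lacunarity_single_offset(m),
               sum(vals^2 * q) / sum(vals * q)^2, tolerance = 1e-12)
})

test_that("mean lacunarity: constants, heterogeneity, and oracle equivalence", {
  const <- gray_image(matrix(0.6, 24, 24))
  for (r in c(2, 3)) {
    ml <- mean_lacunarity(const, r)
    expect_equal(ml$mean_lac, 1)
    expect_equal(ml$n_offsets, r^2)
    expect_equal(ml$mean_lac, mean(ml$per_offset))
  }

  # heterogeneous image (flat half + textured half) exceeds the constant
  # baseline; note a perfectly periodic checkerboard does NOT: every box
  # then holds the same mass at every offset, so its lacunarity is exactly 1
  px <- matrix(0.5, 16, 16)
  px[, 9:16] <- (outer(1:16, 9:16, "+") %% 2)
  hetero <- gray_image(px)
  expect_gt(mean_lacunarity(hetero, 2)$mean_lac,
            mean_lacunarity(gray_image(matrix(0.5, 16, 16)), 2)$mean_lac)
  checker <- gray_image((outer(1:16, 1:16, "+") %% 2))
  expect_equal(mean_lacunarity(checker, 2)$mean_lac, 1)

  # oracle: full double-loop over the 9 offsets and all boxes, 16x16
  img <- rand_gray(16, seed = 321)
  expect_equal(mean_lacunarity(img, 3)$mean_lac,
               oracle_mean_lacunarity(img, 3), tolerance = 1e-12)
  img2 <- rand_gray(20, seed = 99)
  expect_equal(mean_lacunarity(img2, 4)$mean_lac,
               oracle_mean_lacunarity(img2, 4), tolerance = 1e-12)
})

test_that("lacunarity >= 1 always; gray shift by whole levels leaves it unchanged", {
  for (seed in 1:5) {
    img <- rand_gray(24, seed = seed)
    expect_gte(mean_lacunarity(img, 3)$mean_lac, 1)
  }
  set.seed(8)
  base <- matrix(runif(24 * 24, 0, 0.5), 24)
  base_q <- round(base * 255) / 255          # align to the gray grid
  img <- gray_image(base_q)
  shifted <- gray_image(base_q + 64 / 255)   # shift by 64 whole levels
  expect_equal(mean_lacunarity(shifted, 3)$mean_lac,
               mean_lacunarity(img, 3)$mean_lac, tolerance = 1e-12)
})

test_that("ROI masking skips boxes that straddle the boundary", {
  img <- rand_gray(32, seed = 12)
  mask <- matrix(FALSE, 32, 32)
  mask[5:28, 5:28] <- TRUE
  g <- dbc_mass_grid(img, 4, c(0, 0), mask)
  # only boxes entirely inside rows/cols 5..28 survive
  expect_equal(g$n_boxes, 36L)
})
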