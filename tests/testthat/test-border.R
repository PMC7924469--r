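test_that("Gaussian smoothing is unit-sum, symmetric and separable", {
  img <- matrix(7, 16, 16)
  expect_equal(gaussian_smooth(img, 1.4), img, tolerance = 1e-12)
  imp <- matrix(0, 21, 21)
  imp[11, 11] <- 1
  sm <- gaussian_smooth(imp, 1.5)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_equal(sm, sm[21:1, ], tolerance = 1e-12)
  expect_equal(sm, t(sm), tolerance = 1e-12)
  # separable pass equals brute-force 2-D convolution with the outer kernel
  set.seed(3)
  patch <- matrix(stats::rnorm(81), 9, 9)
  h <- ceiling(4 * 0.8)
  k1 <- exp(-((-h):h)^2 / (2 * 0.8^2))
  k1 <- k1 / sum(k1)
  expect_equal(gaussian_smooth(patch, 0.8),
               conv2d_bruteforce(patch, outer(k1, k1)), tolerance = 1e-10)
  expect_error(gaussian_smooth(patch, 0), "sigma")
})

test_that("the 2x2 gradient matches hand-evaluated patches", {
  f <- gradient_2x2(rbind(c(0, 1), c(0, 1)))
  expect_equal(f$rx[1, 1], 1)
  expect_equal(f$ry[1, 1], 0)
  expect_equal(f$magnitude[1, 1], 1)
  expect_equal(f$direction[1, 1], 0)
  f <- gradient_2x2(rbind(c(0, 0), c(1, 1)))
  expect_equal(f$rx[1, 1], 0)
  expect_equal(f$ry[1, 1], -1)
  expect_equal(f$magnitude[1, 1], 1)
  expect_equal(abs(f$direction[1, 1]), pi / 2)
  f <- gradient_2x2(matrix(5, 4, 4))
  expect_true(all(f$magnitude == 0))
})

test_that("non-maximum suppression keeps ridge peaks and drops plateaus", {
  # vertical edge: magnitude ridge with a peak column, direction 0 (along x)
  m <- matrix(0, 5, 5)
  m[, 2] <- 1
  m[, 3] <- 3
  m[, 4] <- 1
  field <- list(magnitude = m, rx = matrix(1, 5, 5), ry = matrix(0, 5, 5))
  thin <- nonmax_suppress(field)
  expect_true(all(thin[, 3] == 3))
  expect_true(all(thin[, c(1, 2, 4, 5)] == 0))
  # constant plateau: fully suppressed under strict inequality
  field <- list(magnitude = matrix(2, 5, 5), rx = matrix(1, 5, 5),
                ry = matrix(0, 5, 5))
  expect_true(all(nonmax_suppress(field) == 0))
  # isolated impulse survives every sector comparison
  m <- matrix(0, 5, 5)
  m[3, 3] <- 4
  field <- list(magnitude = m, rx = matrix(0, 5, 5), ry = matrix(1, 5, 5))
  expect_equal(nonmax_suppress(field)[3, 3], 4)
})

test_that("hysteresis linking matches a flood-fill oracle", {
  # all above high: everything kept
  m <- matrix(5, 4, 4)
  expect_true(all(hysteresis_link(m, 1, 4) == 1))
  # mid-band segment detached from any strong pixel is suppressed
  m <- matrix(0, 5, 7)
  m[2, 2:3] <- 2
  m[4, 5:6] <- c(5, 2)
  out <- hysteresis_link(m, 1, 4)
  expect_equal(sum(out[2, ]), 0)
  expect_equal(out[4, 5:6], c(1L, 1L))
  # strong-mid-mid chain fully retained
  m <- matrix(0, 3, 5)
  m[2, 2:4] <- c(5, 2, 2)
  expect_equal(hysteresis_link(m, 1, 4)[2, 2:4], c(1L, 1L, 1L))
  # random fields against the breadth-first oracle; also idempotence
  set.seed(11)
  for (i in 1:5) {
    m <- matrix(stats::runif(400, 0, 10) * stats::rbinom(400, 1, 0.4), 20, 20)
    out <- hysteresis_link(m, 2, 6)
    expect_equal(out, hysteresis_bruteforce(m, 2, 6))
    expect_equal(hysteresis_link(out * 10, 2, 6), out)
  }
  expect_error(hysteresis_link(m, 5, 5), "thresholds")
})

test_that("the traced disc border has the expected circumference", {
  les <- make_regular_lesion(size = 160, axes = c(50, 50), noise_sd = 0, seed = 1)
  tr <- canny_border(les$mask)
  expect_true(tr$closed)
  expect_lt(abs(tr$perimeter - 2 * pi * 50) / (2 * pi * 50), 0.15)
  # consecutive trace points are 8-neighbors, and the loop closes
  steps <- abs(diff(tr$coords))
  expect_true(all(steps <= 1))
  expect_true(all(abs(tr$coords[1, ] - tr$coords[nrow(tr$coords), ]) <= 1))
  # every border pixel touches both foreground and background of the mask
  on_boundary <- vapply(seq_len(nrow(tr$coords)), function(i) {
    r <- tr$coords[i, 1]
    cc <- tr$coords[i, 2]
    nb <- les$mask[max(1, r - 2):min(160, r + 2), max(1, cc - 2):min(160, cc + 2)]
    any(nb == 1) && any(nb == 0)
  }, logical(1))
  expect_true(all(on_boundary))
})

test_that("rough borders are longer than smooth ones at matched area", {
  irr <- make_irregular_lesion(size = 256, base_radius = 60, roughness = 0.4,
                               noise_sd = 0, seed = 6)
  r_eq <- sqrt(sum(irr$mask) / pi)
  disc <- make_regular_lesion(size = 256, axes = c(r_eq, r_eq), noise_sd = 0,
                              seed = 1)
  expect_gt(canny_border(irr$mask)$perimeter, canny_border(disc$mask)$perimeter)
  expect_error(canny_border(matrix(0, 32, 32)), "empty")
})

test_that("mask boundary tracing agrees with the morphological boundary", {
  les <- make_irregular_lesion(size = 128, base_radius = 30, roughness = 0.3,
                               noise_sd = 0, seed = 2)
  tr <- trace_mask_boundary(les$mask)
  # morphological inner boundary: foreground pixels with a background 4-neighbor
  m <- les$mask
  inner <- m == 1 & (dermoborder:::shift_mat(m, 1, 0) == 0 |
                     dermoborder:::shift_mat(m, -1, 0) == 0 |
                     dermoborder:::shift_mat(m, 0, 1) == 0 |
                     dermoborder:::shift_mat(m, 0, -1) == 0)
  traced <- matrix(FALSE, 128, 128)
  traced[tr$coords] <- TRUE
  # every traced pixel is within 1 pixel of the inner boundary and vice versa
  near <- function(a, b) {
    grow <- b
    for (dr in -1:1) for (dc in -1:1) {
      grow <- grow | dermoborder:::shift_mat(b, dr, dc)
    }
    all(!a | grow)
  }
  expect_true(near(traced, inner))
  expect_true(near(inner, traced))
})
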