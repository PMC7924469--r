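test_that("grayscale conversion uses ITU-R 601 luminance weights", {
  expect_equal(to_grayscale(matrix(42, 3, 3)), matrix(42, 3, 3))
  rgb <- array(0, dim = c(2, 2, 3))
  rgb[, , 1] <- 255
  expect_equal(to_grayscale(rgb)[1, 1], 76L) # 0.299 * 255 rounded
  gray_triple <- array(99, dim = c(2, 2, 3))
  expect_equal(to_grayscale(gray_triple), matrix(99L, 2, 2))
  expect_error(to_grayscale(array(1, dim = c(2, 2, 4))), "matrix")
})

test_that("fuzzy c-means separates a two-valued image crisply", {
  img <- matrix(rep(c(0, 255), each = 32), 8, 8)
  part <- fcm_cluster(img, c = 2)
  expect_equal(sort(part$centroids), c(0, 255), tolerance = 1)
  flat <- matrix(part$memberships, 64, 2)
  expect_true(all(apply(flat, 1, max) >= 0.99))
})

test_that("memberships sum to one and the objective never increases", {
  les <- make_regular_lesion(size = 128, axes = c(30, 20), noise_sd = 10, seed = 2)
  part <- fcm_cluster(les$image, c = 2)
  sums <- apply(part$memberships, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
  expect_true(all(diff(part$objective_trace) <= 1e-8))
  # independent recomputation: Eq.-style direct summation over all pixels,
  # memberships rebuilt from the recorded centroid trajectory
  J_oracle <- vapply(part$centroid_trace, function(v) {
    vals <- as.vector(les$image)
    u <- matrix(0, length(vals), 2)
    for (j in seq_along(vals)) {
      d2 <- (vals[j] - v)^2
      if (any(d2 == 0)) {
        u[j, which.min(d2)] <- 1
      } else {
        for (i in 1:2) u[j, i] <- 1 / sum((d2[i] / d2)^(1 / (2 - 1)))
      }
    }
    sum(u^2 * outer(vals, v, function(x, vi) (x - vi)^2))
  }, numeric(1))
  expect_equal(J_oracle, part$objective_trace, tolerance = 1e-8)
  expect_true(all(diff(J_oracle) <= 1e-8))
})

test_that("the membership update matches a hand evaluation", {
  # equidistant point between centroids 0 and 10 splits 0.5/0.5 at m = 2
  u <- fcm_memberships(c(0, 5, 10), c(0, 10), m = 2)
  expect_equal(u[2, ], c(0.5, 0.5))
  expect_equal(u[1, ], c(1, 0))
  expect_equal(u[3, ], c(0, 1))
  expect_equal(rowSums(u), rep(1, 3))
})

test_that("degenerate images are rejected by clustering", {
  expect_error(fcm_cluster(matrix(7, 8, 8), c = 2), "degenerate")
})

test_that("the S-function follows its piecewise definition", {
  expect_equal(s_membership(0, 0, 0.5, 1), 0)
  expect_equal(s_membership(1, 0, 0.5, 1), 1)
  expect_equal(s_membership(0.5, 0, 0.5, 1), 0.5) # crossover
  expect_equal(s_membership(0.75, 0, 0.5, 1), 0.875)
  g <- seq(-0.2, 1.2, by = 0.01)
  expect_true(all(diff(s_membership(g, 0, 0.5, 1)) >= 0))
  expect_error(s_membership(0.5, 1, 0.5, 0), "knots")
})

test_that("type-II bounds bracket the membership", {
  expect_equal(type2_bounds(0), list(lower = 0, upper = 0))
  expect_equal(type2_bounds(1), list(lower = 1, upper = 1))
  b <- type2_bounds(0.81, alpha = 2)
  expect_equal(b$lower, 0.6561)
  expect_equal(b$upper, 0.9)
  mu <- seq(0, 1, by = 0.001)
  b <- type2_bounds(mu, alpha = 2)
  expect_true(all(b$lower <= mu + 1e-12 & mu <= b$upper + 1e-12))
  # the uncertainty band is widest at mid-range memberships
  width <- b$upper - b$lower
  peak <- mu[which.max(width)]
  expect_gt(peak, 0.2)
  expect_lt(peak, 0.8)
  expect_error(type2_bounds(0.5, alpha = 3), "range")
  expect_error(type2_bounds(0.5, alpha = 1), "range")
})

test_that("ultrafuzziness is zero for crisp memberships and matches a loop", {
  img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  crisp <- as.numeric(0:255 >= 128)
  expect_equal(ultrafuzziness(img, crisp), 0)
  # all mass at one level with membership 0.5: sqrt(0.5) - 0.25
  one <- matrix(7L, 4, 4)
  mu <- as.numeric(0:255 >= 128)
  mu[8] <- 0.5
  expect_equal(ultrafuzziness(one, mu), sqrt(0.5) - 0.25, tolerance = 1e-12)
  set.seed(42)
  for (i in 1:5) {
    img <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
    mu <- stats::runif(256)
    expect_equal(ultrafuzziness(img, mu),
                 ultrafuzziness_bruteforce(img, mu, 2), tolerance = 1e-12)
  }
})

test_that("the ambiguity threshold lands between the modes of a bimodal image", {
  img <- matrix(c(rep(64L, 128), rep(192L, 128)), 16, 16)
  scan <- ambiguity_threshold(img)
  expect_gte(scan$tau, 96)
  expect_lte(scan$tau, 160)
  expect_equal(scan$profile$gamma[scan$profile$g == scan$tau],
               max(scan$profile$gamma))
  expect_true(all(scan$profile$gamma >= 0 & scan$profile$gamma <= 1))
  # histogram-only computation: invariant to transposition
  expect_equal(ambiguity_threshold(t(img))$tau, scan$tau)
  expect_error(ambiguity_threshold(matrix(5L, 8, 8)), "constant")
})

test_that("gradual focusing resolves the worked weak-pixel neighborhood", {
  # 3x3 window: center pixel ambiguous, 6 of 8 neighbors in cluster B (2)
  mem1 <- matrix(0.1, 3, 3) # cluster 1 membership low -> most pixels cluster B
  mem1[1, 1] <- 0.9 # two pixels in cluster A
  mem1[1, 2] <- 0.9
  mem1[2, 2] <- 0.55 # weak pixel, argmax would be cluster A
  part <- toy_partition(mem1)
  out <- gradual_focus_defuzzify(part, tau = 0.7, window = 3)
  expect_equal(out[2, 2], 2L) # majority of neighbors wins
  # tied neighborhood: pixel keeps its own highest-membership cluster
  mem1 <- matrix(c(0.9, 0.9, 0.1, 0.9, 0.55, 0.1, 0.9, 0.1, 0.1), 3, 3)
  part <- toy_partition(mem1)
  expect_equal(sum(mem1[-5] > 0.5), 4) # 4 vs 4 assigned neighbors
  out <- gradual_focus_defuzzify(part, tau = 0.7, window = 3)
  expect_equal(out[2, 2], 1L) # keeps argmax cluster (A)
})

test_that("tau = 0 reduces to plain argmax and tau = 1 still terminates", {
  set.seed(9)
  mem1 <- matrix(stats::runif(64), 8, 8)
  part <- toy_partition(mem1)
  plain <- gradual_focus_defuzzify(part, tau = 0)
  expect_equal(unname(plain), ifelse(mem1 >= 0.5, 1L, 2L),
               ignore_attr = TRUE)
  expect_equal(attr(plain, "weak"), 0L)
  # all pixels weak: falls back to argmax seeding, never loops forever
  mem1 <- matrix(stats::runif(64, 0.4, 0.6), 8, 8)
  part <- toy_partition(mem1)
  all_weak <- gradual_focus_defuzzify(part, tau = 1)
  expect_equal(unname(all_weak), ifelse(mem1 >= 0.5, 1L, 2L),
               ignore_attr = TRUE)
})

test_that("edge-preserving smoothing removes speckle but not edges", {
  step <- cbind(matrix(0, 16, 8), matrix(100, 16, 8))
  sm <- smooth_edges(step, 1)
  # step edge location: maximum column-difference unchanged within 1 px
  edge_before <- which.max(abs(diff(step[8, ])))
  edge_after <- which.max(abs(diff(sm[8, ])))
  expect_lte(abs(edge_before - edge_after), 1)
  speck <- matrix(0, 9, 9)
  speck[5, 5] <- 255
  expect_equal(smooth_edges(speck, 1), matrix(0, 9, 9))
  expect_identical(smooth_edges(speck, 0), speck)
})

test_that("lesion extraction recovers ground truth and its symmetries", {
  les <- make_regular_lesion(size = 256, axes = c(60, 40), contrast = 120,
                             noise_sd = 8, seed = 1)
  mask <- extract_lesion_mask(les$image)
  expect_gt(jaccard_index(mask, les$mask), 95)
  expect_equal(jaccard_index(mask, mask), 100)
  # inverted contrast with the selection rule flipped gives the same mask
  inv <- 255 - les$image
  mask_inv <- extract_lesion_mask(inv, lesion = "lighter")
  expect_gt(jaccard_index(mask_inv, mask), 99)
})

test_that("fuzzy c-means agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  les <- make_regular_lesion(size = 128, axes = c(30, 20), noise_sd = 10, seed = 4)
  part <- fcm_cluster(les$image, c = 2)
  ref <- e1071::cmeans(matrix(as.vector(les$image)), centers = 2, m = 2,
                       method = "cmeans")
  expect_equal(sort(part$centroids), sort(as.vector(ref$centers)),
               tolerance = 0.01)
})
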