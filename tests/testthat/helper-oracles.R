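# Independent brute-force oracles used across the suite.

# Direct evaluation of the FCM objective over every pixel.
fcm_objective_bruteforce <- function(image, centroids, memberships, m) {
  vals <- as.vector(image)
  total <- 0
  for (k in seq_along(centroids)) {
    u <- as.vector(memberships[, , k])
    total <- total + sum(u^m * (vals - centroids[k])^2)
  }
  total
}

# Direct per-level loop for the ultrafuzziness sum.
ultrafuzziness_bruteforce <- function(image, mu, alpha) {
  g <- as.vector(image)
  total <- 0
  for (lvl in 0:(length(mu) - 1)) {
    h <- sum(g == lvl)
    total <- total + h * (mu[lvl + 1]^(1 / alpha) - mu[lvl + 1]^alpha)
  }
  total / length(g)
}

# Full 2-D convolution with edge replication, straight quadruple loop.
conv2d_bruteforce <- function(image, kernel) {
  kr <- (nrow(kernel) - 1) / 2
  kc <- (ncol(kernel) - 1) / 2
  out <- matrix(0, nrow(image), ncol(image))
  for (i in seq_len(nrow(image))) {
    for (j in seq_len(ncol(image))) {
      acc <- 0
      for (a in -kr:kr) {
        for (b in -kc:kc) {
          ii <- min(max(i + a, 1), nrow(image))
          jj <- min(max(j + b, 1), ncol(image))
          acc <- acc + kernel[a + kr + 1, b + kc + 1] * image[ii, jj]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Breadth-first flood-fill reading of hysteresis linking: candidates are
# pixels > low; seeds are pixels > high; an edge is any candidate reachable
# from a seed through 8-connected candidates.
hysteresis_bruteforce <- function(thinned, low, high) {
  cand <- thinned > low
  out <- matrix(FALSE, nrow(thinned), ncol(thinned))
  queue <- which(thinned > high)
  out[queue] <- TRUE
  nr <- nrow(thinned)
  nc <- ncol(thinned)
  while (length(queue) > 0) {
    idx <- queue[1]
    queue <- queue[-1]
    r <- (idx - 1) %% nr + 1
    cc <- (idx - 1) %/% nr + 1
    for (dr in -1:1) {
      for (dc in -1:1) {
        r2 <- r + dr
        c2 <- cc + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        i2 <- (c2 - 1) * nr + r2
        if (cand[i2] && !out[i2]) {
          out[i2] <- TRUE
          queue <- c(queue, i2)
        }
      }
    }
  }
  matrix(as.integer(out), nr, nc)
}

# A hand-built two-cluster fuzzy partition for defuzzification tests:
# membership matrices are supplied directly.
toy_partition <- function(mem_cluster1) {
  A <- array(0, dim = c(nrow(mem_cluster1), ncol(mem_cluster1), 2))
  A[, , 1] <- mem_cluster1
  A[, , 2] <- 1 - mem_cluster1
  list(memberships = A, centroids = c(0, 255), fuzzifier = 2)
}

# border map (1-pixel boundary) of a mask or lesion, for CNN inputs in tests
mask_border_map <- function(mask) {
  if (is.list(mask)) mask <- mask$mask
  tr <- trace_mask_boundary(mask)
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[tr$coords] <- 1L
  out
}
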