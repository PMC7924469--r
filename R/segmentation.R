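#' Convert an RGB image to grayscale
#'
#' Luminance-weighted (ITU-R 601: 0.299 R + 0.587 G + 0.114 B) conversion of a
#' 3-channel array to a single-channel matrix in `[0, 255]`. Single-channel
#' inputs pass through unchanged.
#'
#' @param x Numeric matrix (grayscale) or H x W x 3 array (RGB), values in
#'   `[0, 255]`.
#' @return Integer-valued grayscale matrix.
#' @export
to_grayscale <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  if (length(d) == 3L && d[3L] == 3L) {
    g <- 0.299 * x[, , 1L] + 0.587 * x[, , 2L] + 0.114 * x[, , 3L]
    return(matrix(as.integer(round(g)), d[1L], d[2L]))
  }
  abort("input must be a matrix or an H x W x 3 array")
}

#' Fuzzy c-means clustering of image intensities
#'
#' Partitions the pixels of a grayscale image into `c` clusters by alternating
#' the membership and centroid updates that minimize the weighted
#' within-cluster distance objective
#' \deqn{J = \sum_j \sum_i u_{ij}^m \| x_j - v_i \|^2 .}
#' Because the feature is scalar intensity, the updates are computed over the
#' distinct gray values weighted by their histogram counts — algebraically
#' identical to iterating over every pixel, and much faster. Iteration stops
#' when the centroids are identical between iterations (the classic stop rule)
#' or the largest centroid change falls below `tol`.
#'
#' Centroids are initialized at the `(i - 0.5)/c` quantiles of the intensity
#' distribution, which is deterministic and spreads the starting centroids
#' across the observed gray range.
#'
#' @param image Numeric matrix of gray levels.
#' @param c Number of clusters (>= 2).
#' @param m Fuzzifier (> 1); larger values give softer memberships.
#' @param tol Convergence tolerance on the centroid update.
#' @param max_iter Iteration cap.
#' @return An `fcm_partition`: list with `centroids`, per-pixel `memberships`
#'   (H x W x c array summing to 1 over clusters), `objective` (final J),
#'   `objective_trace`, `iterations`, and the fuzzifier `m`.
#' @examples
#' img <- rbind(matrix(40, 8, 16), matrix(200, 8, 16))
#' fcm_cluster(img, c = 2)$centroids
#' @export
fcm_cluster <- function(image, c = 2, m = 2, tol = 1e-5, max_iter = 300) {
  if (!is.matrix(image)) abort("image must be a matrix")
  if (c < 2) abort("c must be at least 2")
  if (m <= 1) abort("the fuzzifier m must be greater than 1")
  vals <- as.vector(image)
  uv <- sort(unique(vals))
  if (length(uv) < c) {
    abort(sprintf("degenerate clustering: image has %d distinct gray values, need >= %d",
                  length(uv), c))
  }
  w <- tabulate(match(vals, uv), length(uv))
  v <- as.numeric(stats::quantile(vals, probs = (seq_len(c) - 0.5) / c, names = FALSE))
  if (anyDuplicated(v)) {
    # quantile collapse on near-constant images: spread over the range instead
    v <- seq(min(uv), max(uv), length.out = c + 2L)[2:(c + 1L)]
  }
  memberships_from <- function(v) fcm_memberships(uv, v, m)
  Jtrace <- numeric(0)
  vtrace <- list()
  for (it in seq_len(max_iter)) {
    u <- memberships_from(v)
    um <- u^m
    # J at the current (memberships, centroids) pair; non-increasing across
    # iterations by the alternating-optimization argument
    d2 <- outer(uv, v, function(x, vi) (x - vi)^2)
    Jtrace <- c(Jtrace, sum(w * rowSums(um * d2)))
    vtrace[[it]] <- v
    v_new <- colSums(um * w * uv) / colSums(um * w)
    if (identical(v_new, v) || max(abs(v_new - v)) < tol) {
      v <- v_new
      break
    }
    v <- v_new
  }
  u <- memberships_from(v)
  idx <- match(vals, uv)
  A <- array(0, dim = c(nrow(image), ncol(image), c))
  for (k in seq_len(c)) A[, , k] <- matrix(u[idx, k], nrow(image), ncol(image))
  structure(
    list(centroids = v, memberships = A, fuzzifier = m,
         objective = Jtrace[length(Jtrace)], objective_trace = Jtrace,
         centroid_trace = vtrace, iterations = it, dim = dim(image)),
    class = "fcm_partition"
  )
}

#' @export
print.fcm_partition <- function(x, ...) {
  cat(sprintf("<fcm_partition> %d clusters, centroids: %s, J = %.4g (%d iterations)\n",
              length(x$centroids), paste(signif(x$centroids, 5), collapse = ", "),
              x$objective, x$iterations))
  invisible(x)
}

#' Fuzzy memberships for fixed centroids
#'
#' The membership update of fuzzy c-means on its own:
#' `u_ij = 1 / sum_k (d_ij / d_kj)^(2/(m-1))` with Euclidean distances to the
#' given centroids. A point coinciding with a centroid gets a crisp
#' membership. Rows sum to 1.
#'
#' @param x Numeric vector of data points (gray values).
#' @param centroids Numeric vector of cluster centers.
#' @param m Fuzzifier (> 1).
#' @return A `length(x)` x `length(centroids)` membership matrix.
#' @examples
#' fcm_memberships(5, c(0, 10)) # equidistant: 0.5 / 0.5
#' @export
fcm_memberships <- function(x, centroids, m = 2) {
  if (m <= 1) abort("the fuzzifier m must be greater than 1")
  d2 <- outer(x, centroids, function(xi, vi) (xi - vi)^2)
  u <- d2^(-1 / (m - 1))
  zero <- d2 == 0
  if (any(zero)) {
    rows <- which(rowSums(zero) > 0)
    u[rows, ] <- 0
    u[zero] <- 1
  }
  u / rowSums(u)
}

#' S-function membership
#'
#' The piecewise-quadratic monotone membership function with knots
#' `a < b < c`:
#' 0 below `a`, `((g-a)/(b-a))^2 / 2` on `(a, b]`,
#' `1 - ((g-c)/(c-b))^2 / 2` on `(b, c]`, and 1 above `c`.
#' `b` is the crossover point where the membership equals 1/2.
#'
#' @param g Gray value(s), any numeric vector.
#' @param a,b,c Knots with `a < b < c`.
#' @return Membership value(s) in `[0, 1]`.
#' @examples
#' s_membership(c(0, 0.5, 0.75, 1), 0, 0.5, 1)
#' @export
s_membership <- function(g, a, b, c) {
  if (!(a < b && b < c)) abort("S-function knots must satisfy a < b < c")
  out <- numeric(length(g))
  mid1 <- g > a & g <= b
  mid2 <- g > b & g <= c
  out[mid1] <- 0.5 * ((g[mid1] - a) / (b - a))^2
  out[mid2] <- 1 - 0.5 * ((g[mid2] - c) / (c - b))^2
  out[g > c] <- 1
  out
}

#' Type-II fuzzy membership bounds
#'
#' Lower and upper membership degrees bracketing an initial membership:
#' `mu^alpha` and `mu^(1/alpha)`. The band between them is the footprint of
#' uncertainty. The exponent is restricted to `(1, 2]`, the range recommended
#' for image data; the default is 2.
#'
#' @param mu Membership value(s) in `[0, 1]`.
#' @param alpha Exponent in `(1, 2]`.
#' @return List with components `lower` and `upper`.
#' @examples
#' type2_bounds(0.81, alpha = 2)
#' @export
type2_bounds <- function(mu, alpha = 2) {
  if (alpha <= 1 || alpha > 2) {
    abort("alpha must lie in (1, 2], the range recommended for image data")
  }
  if (any(mu < 0 | mu > 1)) abort("mu must lie in [0, 1]")
  list(lower = mu^alpha, upper = mu^(1 / alpha))
}

#' Ultrafuzziness of a membership profile
#'
#' Histogram-weighted average width of the footprint of uncertainty:
#' \deqn{\tilde\gamma = \frac{1}{MN} \sum_g h(g) [\mu_U(g) - \mu_L(g)] .}
#' Crisp memberships (0/1 everywhere) give 0; the maximum over threshold
#' positions marks the most ambiguous gray level.
#'
#' @param image Integer-valued matrix with gray levels in `[0, L-1]`.
#' @param mu Membership per gray level: numeric vector of length `L` giving
#'   the membership of levels `0 .. L-1`.
#' @param alpha Type-II exponent passed to [type2_bounds()].
#' @return Scalar in `[0, 1]`.
#' @export
ultrafuzziness <- function(image, mu, alpha = 2) {
  L <- length(mu)
  g <- as.vector(image)
  if (any(g < 0 | g > L - 1)) abort("image gray levels must lie in [0, L-1]")
  h <- tabulate(g + 1L, L)
  b <- type2_bounds(mu, alpha)
  sum(h * (b$upper - b$lower)) / length(g)
}

#' Ambiguity threshold by maximum ultrafuzziness
#'
#' Slides an S-function membership profile along the gray range (crossover at
#' each candidate position `g`, knots at `g - bandwidth` and `g + bandwidth`,
#' clipped to the range ends), evaluates the ultrafuzziness at each position,
#' and returns the position with the maximum — the gray level where the image
#' is most ambiguous, used as the threshold `tau`. Ties take the lowest
#' position.
#'
#' @param image Integer-valued matrix with gray levels in `[0, L-1]`.
#' @param alpha Type-II exponent.
#' @param bandwidth Half-width of the S-function support in gray levels.
#' @param L Number of gray levels.
#' @return An `ultrafuzziness_scan`: list with `profile` (tibble of `g`,
#'   `gamma`), the maximizing position `g_pos`, and `tau = g_pos`.
#' @examples
#' img <- rbind(matrix(64L, 8, 16), matrix(192L, 8, 16))
#' ambiguity_threshold(img)$tau
#' @export
ambiguity_threshold <- function(image, alpha = 2, bandwidth = (L - 1) / 2, L = 256) {
  g <- as.vector(image)
  if (length(unique(g)) < 2L) {
    abort("constant image: ultrafuzziness has no meaningful maximum")
  }
  h <- tabulate(g + 1L, L)
  positions <- 1:(L - 2L)
  levels <- 0:(L - 1L)
  gamma <- vapply(positions, function(p) {
    a <- max(0, p - bandwidth)
    cc <- min(L - 1, p + bandwidth)
    mu <- s_membership(levels, a, p, cc)
    b <- type2_bounds(mu, alpha)
    sum(h * (b$upper - b$lower)) / length(g)
  }, numeric(1))
  g_pos <- positions[which.max(gamma)]
  structure(
    list(profile = tibble::tibble(g = positions, gamma = gamma),
         g_pos = g_pos, tau = g_pos, alpha = alpha, bandwidth = bandwidth),
    class = "ultrafuzziness_scan"
  )
}

#' @export
print.ultrafuzziness_scan <- function(x, ...) {
  cat(sprintf("<ultrafuzziness_scan> tau = %d (max gamma = %.4f, alpha = %g, bandwidth = %g)\n",
              x$tau, max(x$profile$gamma), x$alpha, x$bandwidth))
  invisible(x)
}

#' Gradual-focusing defuzzification
#'
#' Converts a fuzzy partition into a crisp cluster assignment in two steps.
#' Pixels whose maximum membership reaches `tau` take their highest-membership
#' cluster immediately (the coarse image structure). The remaining "weak"
#' (ambiguous) pixels are swept in raster order and each is assigned to the
#' majority cluster among the already-assigned pixels in its window; on a
#' frequency tie the pixel keeps the cluster it had the highest membership for.
#' Sweeps repeat until the weak set is empty; if a sweep resolves nothing
#' (no weak pixel has an assigned neighbor), the remaining pixels fall back to
#' their highest-membership cluster, so the procedure always terminates.
#'
#' @param partition An [fcm_cluster()] result (or any list with a `memberships`
#'   H x W x c array).
#' @param tau Membership threshold in `[0, 1]` separating weak from confident
#'   pixels.
#' @param window Odd window side length (>= 3) for the neighborhood majority.
#' @return Integer matrix of cluster assignments (1-based), with attribute
#'   `weak` giving the initial number of ambiguous pixels.
#' @export
gradual_focus_defuzzify <- function(partition, tau, window = 3) {
  A <- partition$memberships
  if (is.null(A)) abort("partition must carry a memberships array")
  if (window < 3 || !is_odd(as.integer(window))) abort("window must be odd and >= 3")
  if (tau < 0 || tau > 1) abort("tau must lie in [0, 1]")
  nr <- dim(A)[1L]
  nc <- dim(A)[2L]
  k <- dim(A)[3L]
  flat <- matrix(A, nr * nc, k)
  argmax <- max.col(flat, ties.method = "first")
  maxmem <- flat[cbind(seq_len(nr * nc), argmax)]
  assign <- matrix(argmax, nr, nc)
  weak <- matrix(maxmem < tau, nr, nc)
  n_weak0 <- sum(weak)
  rad <- (window - 1L) %/% 2L
  while (any(weak)) {
    ord <- which(t(weak)) # raster order: row-major
    coords <- cbind((ord - 1L) %/% nc + 1L, (ord - 1L) %% nc + 1L)
    resolved_any <- FALSE
    for (i in seq_len(nrow(coords))) {
      r <- coords[i, 1L]
      cc <- coords[i, 2L]
      rs <- max(1L, r - rad):min(nr, r + rad)
      cs <- max(1L, cc - rad):min(nc, cc + rad)
      nb_assign <- assign[rs, cs][!weak[rs, cs]]
      if (length(nb_assign) == 0L) next
      counts <- tabulate(nb_assign, k)
      top <- which(counts == max(counts))
      assign[r, cc] <- if (length(top) == 1L) top else assign[r, cc]
      weak[r, cc] <- FALSE
      resolved_any <- TRUE
    }
    if (!resolved_any) {
      weak[] <- FALSE # isolated ambiguity: keep highest-membership clusters
    }
  }
  structure(assign, weak = n_weak0)
}

#' Edge-preserving smoothing
#'
#' Attenuates texture and salt-and-pepper detail below the given scale while
#' leaving step edges in place (within one pixel), via iterated 3x3 median
#' filtering; `scale` is the number of passes and `scale = 0` is the identity.
#' Binary masks stay binary.
#'
#' @param x Numeric matrix (image or mask).
#' @param scale Non-negative integer smoothing scale.
#' @return Smoothed matrix of the same size.
#' @export
smooth_edges <- function(x, scale = 1) {
  if (scale < 0) abort("scale must be non-negative")
  scale <- as.integer(scale)
  if (scale == 0L) return(x)
  median3(x, passes = scale)
}

#' Extract a lesion mask from a grayscale image
#'
#' The full segmentation stage: fuzzy c-means with `c = 2` (lesion vs. skin),
#' ambiguity threshold from the type-II ultrafuzziness scan, gradual-focusing
#' defuzzification of the ambiguous pixels, selection of the lesion cluster
#' (the darker centroid by default — lesions are pigmented), cleanup to the
#' largest 8-connected component with holes filled, and edge-preserving
#' smoothing.
#'
#' The threshold scan runs by default on the lesion-cluster membership map
#' rescaled to `[0, 255]`, so the resulting gray-level position divided by 255
#' is directly a membership threshold; `threshold_on = "image"` scans the raw
#' gray image instead and rescales the position the same way.
#'
#' @param image Grayscale matrix or RGB array (converted via [to_grayscale()]).
#' @param c,m,tol,max_iter Fuzzy c-means parameters, see [fcm_cluster()].
#' @param alpha,bandwidth Ultrafuzziness scan parameters, see
#'   [ambiguity_threshold()].
#' @param window Defuzzification window, see [gradual_focus_defuzzify()].
#' @param smoothing_scale Passes of edge-preserving smoothing of the final mask.
#' @param lesion Which intensity cluster is the lesion: `"darker"` (default)
#'   or `"lighter"`.
#' @param threshold_on Run the ambiguity scan on the `"membership"` map
#'   (default) or the raw `"image"`.
#' @return Binary integer matrix (1 = lesion) of class `lesion_mask`, with
#'   attributes `centroids`, `tau` (membership threshold actually applied) and
#'   `scan` (the [ambiguity_threshold()] result).
#' @examples
#' les <- make_regular_lesion(size = 128, axes = c(30, 20), seed = 1)
#' mask <- extract_lesion_mask(les$image)
#' jaccard_index(mask, les$mask)
#' @export
extract_lesion_mask <- function(image, c = 2, m = 2, tol = 1e-5, max_iter = 300,
                                alpha = 2, bandwidth = 127.5, window = 3,
                                smoothing_scale = 1,
                                lesion = c("darker", "lighter"),
                                threshold_on = c("membership", "image")) {
  lesion <- match.arg(lesion)
  threshold_on <- match.arg(threshold_on)
  image <- to_grayscale(image)
  part <- fcm_cluster(image, c = c, m = m, tol = tol, max_iter = max_iter)
  k_les <- if (lesion == "darker") which.min(part$centroids) else which.max(part$centroids)
  scan_img <- if (threshold_on == "membership") {
    matrix(as.integer(round(part$memberships[, , k_les] * 255)),
           nrow(image), ncol(image))
  } else {
    matrix(as.integer(round(image)), nrow(image), ncol(image))
  }
  scan <- ambiguity_threshold(scan_img, alpha = alpha, bandwidth = bandwidth)
  tau <- scan$tau / 255
  assign <- gradual_focus_defuzzify(part, tau = tau, window = window)
  bin <- matrix(as.integer(assign == k_les), nrow(image), ncol(image))
  if (sum(bin) == 0L) abort("no lesion found: segmentation foreground is empty")
  bin <- fill_holes(largest_component(bin))
  bin <- as_binary_mask(smooth_edges(bin, smoothing_scale) > 0.5)
  if (sum(bin) == 0L) abort("no lesion found: foreground vanished during cleanup")
  structure(bin, class = c("lesion_mask", class(bin)),
            centroids = part$centroids, tau = tau, scan = scan)
}
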