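#' Count boxes covering a border
#'
#' Number of `eps x eps` grid cells containing at least one border pixel, with
#' the grid anchored at the border's bounding-box origin (optionally shifted).
#'
#' @param trace A `border_trace` or an n x 2 matrix of (row, col) coordinates.
#' @param eps Box side length in pixels (>= 1).
#' @param shift Grid shift `c(row, col)` in `[0, eps)`, for offset-searched
#'   counts.
#' @return Integer count `N(eps)`.
#' @examples
#' line <- cbind(1, 1:16)
#' box_count(line, 4)
#' @export
box_count <- function(trace, eps, shift = c(0, 0)) {
  coords <- trace_coords(trace)
  if (eps < 1) abort("eps must be at least 1")
  r <- coords[, 1L] - min(coords[, 1L]) + shift[1L]
  cc <- coords[, 2L] - min(coords[, 2L]) + shift[2L]
  cells <- unique(floor(r / eps) * 2^26 + floor(cc / eps))
  length(cells)
}

trace_coords <- function(trace) {
  if (inherits(trace, "border_trace")) trace <- trace$coords
  if (!is.matrix(trace) || ncol(trace) != 2L || nrow(trace) == 0L) {
    abort("trace must be a border_trace or a nonempty n x 2 coordinate matrix")
  }
  trace
}

#' Box-counting fractal dimension of a border
#'
#' Covers the border with grids of dyadic box sizes `eps = 1, 2, 4, ...` up to
#' half the longest bounding-box side and fits the least-squares slope of
#' `log N(eps)` against `log(1/eps)`; the slope is the box-counting dimension.
#' Scales where a single box suffices carry no information and are excluded
#' from the fit. A smooth line yields a dimension near 1; space-filling
#' borders approach 2. Values outside `[1, 2]` (possible on tiny or degenerate
#' inputs) trigger a warning but are not clamped.
#'
#' @param trace A `border_trace` or n x 2 coordinate matrix spanning at least
#'   8 pixels.
#' @param offsets If > 1, take for each scale the smallest count over this
#'   many diagonal grid shifts (closer to the minimal covering); default is
#'   the single anchored grid.
#' @return The fitted dimension `D` (scalar), with the per-scale counts as a
#'   `boxcount_curve` tibble in attribute `curve`.
#' @examples
#' fractal_dimension(koch_border(4, length = 243))
#' @export
fractal_dimension <- function(trace, offsets = 1) {
  coords <- trace_coords(trace)
  span <- max(diff(range(coords[, 1L])), diff(range(coords[, 2L]))) + 1
  if (span < 8) abort("trace too small: border must span at least 8 pixels")
  kmax <- floor(log2(span / 2))
  eps <- 2^(0:kmax)
  n <- vapply(eps, function(e) {
    if (offsets > 1) {
      shifts <- seq(0, e - 1, length.out = offsets)
      min(vapply(shifts, function(s) box_count(coords, e, shift = c(s, s)),
                 numeric(1)))
    } else {
      box_count(coords, e)
    }
  }, numeric(1))
  keep <- n > 1
  if (sum(keep) < 2L) abort("not enough informative scales to fit a dimension")
  fit <- stats::lm(log(n[keep]) ~ log(1 / eps[keep]))
  d <- unname(stats::coef(fit)[2L])
  if (d < 1 - 1e-8 || d > 2 + 1e-8) {
    warn(sprintf("estimated fractal dimension %.3f lies outside [1, 2]", d))
  }
  curve <- structure(tibble::tibble(eps = eps, n = n, used = keep),
                     dimension = d, class = c("boxcount_curve", class(tibble::tibble())))
  structure(d, curve = curve)
}

#' Zernike radial polynomial
#'
#' The radial factor `R_nm(rho)` of the Zernike basis, evaluated by its exact
#' finite sum
#' \deqn{R_{nm}(\rho) = \sum_{a=0}^{(n-|m|)/2} (-1)^a
#'   \frac{(n-a)!}{a!\,(\frac{n+|m|}{2}-a)!\,(\frac{n-|m|}{2}-a)!}\,
#'   \rho^{\,n-2a} .}
#' Defined for `0 <= |m| <= n` with `n - |m|` even; `R_nn(rho) = rho^n` and
#' `R_nm(1) = 1`.
#'
#' @param n Polynomial order (non-negative integer).
#' @param m Repetition, `|m| <= n`, `n - |m|` even.
#' @param rho Radius value(s) in `[0, 1]`.
#' @return Numeric vector of the same length as `rho`.
#' @examples
#' zernike_radial(2, 0, 0.5) # 2 * 0.25 - 1
#' @export
zernike_radial <- function(n, m, rho) {
  m <- abs(m)
  if (m > n) abort("need |m| <= n")
  if ((n - m) %% 2 != 0) abort("n - |m| must be even for a Zernike polynomial")
  if (any(rho < 0 | rho > 1)) abort("rho must lie in [0, 1]")
  out <- numeric(length(rho))
  for (a in 0:((n - m) / 2)) {
    coef <- (-1)^a * factorial(n - a) /
      (factorial(a) * factorial((n + m) / 2 - a) * factorial((n - m) / 2 - a))
    out <- out + coef * rho^(n - 2 * a)
  }
  out
}

# ordered (n, m) pairs at a given maximum order: n ascending, m >= 0 ascending,
# n - m even. Order 8 gives the 25 pairs of the lesion descriptor.
zernike_pairs <- function(order) {
  do.call(rbind, lapply(0:order, function(n) {
    m <- seq(n %% 2, n, by = 2)
    cbind(n = n, m = m)
  }))
}

#' Zernike moment magnitudes of a lesion mask
#'
#' Projects the mask onto the orthogonal Zernike basis on the unit disc and
#' returns the moment magnitudes, which are invariant to rotation (and, via
#' the centroid mapping, to translation). The mask is mapped to the unit disc
#' centered at its centroid and scaled by the largest centroid-to-foreground
#' distance, and its intensity is normalized to unit mass, so the order-0
#' magnitude is always `1/pi = 0.3183` for a nonzero mask. Moments are
#' \deqn{Z_{nm} = \frac{n+1}{\pi} \sum_{x} \sum_{y} V_{nm}^*(x, y) f(x, y),}
#' computed for all pairs with `m >= 0`, `n - m` even, `n <= order`; order 8
#' yields the 25-value shape block of the irregularity descriptor.
#'
#' @param mask Binary matrix (1 = lesion), nonempty.
#' @param order Maximum polynomial order (default 8).
#' @return Named numeric vector of magnitudes `ZM1..ZMk` ordered by
#'   (n ascending, m ascending); 25 values at order 8.
#' @examples
#' les <- make_regular_lesion(size = 128, axes = c(30, 20), noise_sd = 0, seed = 1)
#' round(zernike_vector(les$mask)[1], 4)
#' @export
zernike_vector <- function(mask, order = 8) {
  mask <- as_binary_mask(mask)
  fg <- which(mask > 0, arr.ind = TRUE)
  if (nrow(fg) == 0L) abort("mask is empty")
  ctr <- colMeans(fg)
  y <- ctr[1L] - fg[, 1L] # rows grow downward; flip so y points up
  x <- fg[, 2L] - ctr[2L]
  r <- sqrt(x^2 + y^2)
  radius <- max(r, 1e-9)
  rho <- pmin(r / radius, 1)
  theta <- atan2(y, x)
  f <- 1 / nrow(fg) # unit total mass
  pairs <- zernike_pairs(order)
  mags <- vapply(seq_len(nrow(pairs)), function(i) {
    n <- pairs[i, "n"]
    m <- pairs[i, "m"]
    rad <- zernike_radial(n, m, rho)
    z <- (n + 1) / pi * sum(rad * exp(-1i * m * theta) * f)
    Mod(z)
  }, numeric(1))
  stats::setNames(mags, paste0("ZM", seq_len(nrow(pairs))))
}

#' Convexity of a lesion mask
#'
#' The ratio of the convex-hull perimeter to the lesion perimeter. Both
#' perimeters are measured identically — as the 8-connected arc length
#' (diagonal steps sqrt(2)) of a traced rasterized boundary — so the
#' discretization bias cancels: a convex shape evaluates to 1 (within a small
#' tolerance) and indented, irregular borders fall below 1.
#'
#' @param mask Binary matrix (1 = lesion), nonempty.
#' @return Scalar convexity, ~1 for convex shapes, < 1 otherwise.
#' @examples
#' les <- make_regular_lesion(size = 128, axes = c(30, 30), noise_sd = 0, seed = 1)
#' convexity(les$mask)
#' @export
convexity <- function(mask) {
  mask <- as_binary_mask(mask)
  if (sum(mask) == 0L) abort("mask is empty")
  mask_perim <- trace_mask_boundary(mask)$perimeter
  hull <- convex_hull_mask(mask)
  hull_perim <- trace_mask_boundary(hull)$perimeter
  hull_perim / mask_perim
}

# rasterized filled convex hull of a mask's foreground
convex_hull_mask <- function(mask) {
  fg <- which(mask > 0, arr.ind = TRUE)
  hull_idx <- grDevices::chull(fg[, 2L], fg[, 1L])
  hx <- fg[hull_idx, 2L] # col
  hy <- fg[hull_idx, 1L] # row
  out <- matrix(0L, nrow(mask), ncol(mask))
  rows <- min(hy):max(hy)
  nv <- length(hx)
  for (r in rows) {
    xs <- numeric(0)
    for (i in seq_len(nv)) {
      j <- if (i == nv) 1L else i + 1L
      y1 <- hy[i]; y2 <- hy[j]
      if (y1 == y2) {
        if (y1 == r) xs <- c(xs, hx[i], hx[j])
        next
      }
      t <- (r - y1) / (y2 - y1)
      if (t >= 0 && t <= 1) xs <- c(xs, hx[i] + t * (hx[j] - hx[i]))
    }
    if (length(xs) == 0L) next
    out[r, max(1L, floor(min(xs))):min(ncol(mask), ceiling(max(xs)))] <- 1L
  }
  # hull must contain the mask despite rounding
  out[mask > 0] <- 1L
  out
}

#' The 27-value border irregularity descriptor
#'
#' Concatenates the box-counting fractal dimension of the border trace, the
#' convexity of the mask, and the 25 Zernike moment magnitudes of the mask,
#' in that fixed order: `FD, C, ZM1..ZM25`.
#'
#' @param mask Binary lesion mask.
#' @param trace Border trace of the same lesion; when `NULL`, the mask's own
#'   traced boundary is used.
#' @param order Zernike order (8 gives the standard 27-value descriptor).
#' @return Named numeric vector of length `2 + #moments` (27 at order 8).
#' @examples
#' les <- make_irregular_lesion(size = 128, base_radius = 30, seed = 3)
#' length(irregularity_vector(les$mask))
#' @export
irregularity_vector <- function(mask, trace = NULL, order = 8) {
  mask <- as_binary_mask(mask)
  if (is.null(trace)) trace <- trace_mask_boundary(mask)
  c(FD = as.numeric(fractal_dimension(trace)),
    C = convexity(mask),
    zernike_vector(mask, order = order))
}

#' Irregularity features for a set of lesions
#'
#' Tidy dataset-level wrapper: segment nothing, assume masks are available
#' (ground truth or segmented), and compute the 27-value descriptor per
#' sample.
#'
#' @param samples List of `synthetic_lesion` objects, or a data frame / tibble
#'   with list-columns `mask` (binary matrices) and optionally `trace`,
#'   plus `id` and `label` columns.
#' @param order Zernike order.
#' @return A tibble with columns `id`, `FD`, `C`, `ZM1..ZM25`, `label`
#'   (if available) — one row per lesion, matching the descriptor layout.
#' @examples
#' ds <- make_dataset(2, 2, seed = 1, size = 128)
#' lesion_features(ds)
#' @export
lesion_features <- function(samples, order = 8) {
  if (inherits(samples, "synthetic_lesion")) samples <- list(samples)
  if (is.data.frame(samples)) {
    samples <- purrr::pmap(samples, function(...) list(...))
  }
  rows <- purrr::map(samples, function(s) {
    v <- irregularity_vector(s$mask, trace = s$trace %||% NULL, order = order)
    out <- tibble::as_tibble_row(as.list(v))
    out$id <- s$id %||% NA_character_
    out$label <- s$label %||% NA_integer_
    out
  })
  dplyr::bind_rows(rows) |>
    dplyr::relocate("id")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
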