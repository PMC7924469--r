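#' Border trace objects
#'
#' An ordered walk along a lesion border: an n x 2 integer matrix of
#' `(row, col)` coordinates in which consecutive points are 8-neighbors,
#' together with its polygonal arc length (diagonal steps count sqrt(2)) and
#' whether the walk closes back on its start.
#'
#' @param coords n x 2 matrix of (row, col) coordinates.
#' @param closed Whether the trace forms a closed loop.
#' @param edge_map Optional binary edge image the trace was extracted from.
#' @param segments Optional construction metadata (e.g., Koch segment count).
#' @return A `border_trace` list with `coords`, `closed`, `perimeter`.
#' @keywords internal
new_border_trace <- function(coords, closed, edge_map = NULL, segments = NULL) {
  structure(
    list(coords = coords, closed = closed,
         perimeter = trace_arclength(coords, closed = closed),
         edge_map = edge_map),
    segments = segments,
    class = "border_trace"
  )
}

#' @export
print.border_trace <- function(x, ...) {
  cat(sprintf("<border_trace> %d points, %s, perimeter = %.1f px\n",
              nrow(x$coords), if (x$closed) "closed" else "open", x$perimeter))
  invisible(x)
}

#' Separable Gaussian smoothing
#'
#' Applies a 1-D Gaussian kernel along rows and then columns (the separable
#' factorization of the 2-D Gaussian). The kernel is truncated at four
#' standard deviations and renormalized to unit sum, so constant regions are
#' preserved exactly. Image borders are handled by edge replication.
#'
#' @param image Numeric matrix.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return Smoothed matrix of the same size.
#' @export
gaussian_smooth <- function(image, sigma) {
  if (sigma <= 0) abort("sigma must be positive")
  h <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-h):h)^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- matrix(0, nrow(image), ncol(image))
  for (i in seq_along(k)) out <- out + k[i] * shift_mat(image, 0L, i - h - 1L)
  out2 <- matrix(0, nrow(image), ncol(image))
  for (i in seq_along(k)) out2 <- out2 + k[i] * shift_mat(out, i - h - 1L, 0L)
  out2
}

#' Image gradient from a 2x2 stencil
#'
#' Derivatives from the four samples `S1..S4` at `(x, y)`, `(x, y+1)`,
#' `(x+1, y)`, `(x+1, y+1)` (row, column indexing):
#' `Rx = (-S1 + S2 - S3 + S4)/2` (column direction) and
#' `Ry = (S1 + S2 - S3 - S4)/2` (opposite row direction, i.e. positive when
#' intensity decreases downward). Magnitude is `sqrt(Rx^2 + Ry^2)`; direction
#' uses the quadrant-aware arctangent `atan2(Ry, Rx)`, which also handles
#' `Rx = 0`. The last row/column are padded by edge replication.
#'
#' @param image Numeric matrix (>= 2 x 2).
#' @return A `gradient_field` list with `magnitude`, `direction` (radians),
#'   `rx`, `ry`.
#' @examples
#' gradient_2x2(rbind(c(0, 1), c(0, 1)))$magnitude
#' @export
gradient_2x2 <- function(image) {
  if (nrow(image) < 2L || ncol(image) < 2L) abort("image must be at least 2 x 2")
  s1 <- image
  s2 <- shift_mat(image, 0L, 1L)
  s3 <- shift_mat(image, 1L, 0L)
  s4 <- shift_mat(image, 1L, 1L)
  rx <- (-s1 + s2 - s3 + s4) / 2
  ry <- (s1 + s2 - s3 - s4) / 2
  structure(
    list(magnitude = sqrt(rx^2 + ry^2), direction = atan2(ry, rx),
         rx = rx, ry = ry),
    class = "gradient_field"
  )
}

#' Non-maximum suppression
#'
#' Thins the gradient magnitude to one-pixel-wide ridges: a pixel survives only
#' if its magnitude strictly exceeds both neighbors along the gradient
#' direction, with directions quantized to the four sectors 0, 45, 90 and 135
#' degrees. Strict comparison suppresses constant plateaus.
#'
#' @param field A [gradient_2x2()] result.
#' @return Matrix of magnitudes with non-maximal pixels set to 0.
#' @export
nonmax_suppress <- function(field) {
  m <- field$magnitude
  ang <- (atan2(field$ry, field$rx) * 180 / pi) %% 180
  sector <- integer(length(ang))
  sector[(ang >= 157.5) | (ang < 22.5)] <- 0L
  sector[ang >= 22.5 & ang < 67.5] <- 45L
  sector[ang >= 67.5 & ang < 112.5] <- 90L
  sector[ang >= 112.5 & ang < 157.5] <- 135L
  sector <- matrix(sector, nrow(m), ncol(m))
  # neighbor offsets (row, col) along the gradient for each sector; ry points
  # against the row axis, so 45 degrees pairs (-1,+1) with (+1,-1)
  keep <- matrix(FALSE, nrow(m), ncol(m))
  sector_offsets <- list(
    `0` = list(c(0L, 1L), c(0L, -1L)),
    `45` = list(c(-1L, 1L), c(1L, -1L)),
    `90` = list(c(-1L, 0L), c(1L, 0L)),
    `135` = list(c(-1L, -1L), c(1L, 1L))
  )
  for (s in names(sector_offsets)) {
    o <- sector_offsets[[s]]
    n1 <- shift_mat(m, o[[1L]][1L], o[[1L]][2L])
    n2 <- shift_mat(m, o[[2L]][1L], o[[2L]][2L])
    keep <- keep | (sector == as.integer(s) & m > n1 & m > n2)
  }
  out <- m
  out[!keep] <- 0
  out
}

#' Hysteresis edge linking
#'
#' Double-threshold linking: pixels with magnitude above `high` are edges;
#' pixels in `(low, high]` become edges only when 8-connected — possibly
#' through other mid-band pixels — to an above-`high` pixel; pixels at or
#' below `low` are never edges.
#'
#' @param thinned Non-maximum-suppressed magnitude matrix.
#' @param low,high Thresholds with `0 <= low < high`.
#' @return Binary integer matrix of edge pixels.
#' @export
hysteresis_link <- function(thinned, low, high) {
  if (low < 0 || low >= high) abort("thresholds must satisfy 0 <= low < high")
  cand <- thinned > low
  strong <- thinned > high
  if (!any(strong)) return(matrix(0L, nrow(thinned), ncol(thinned)))
  lab <- label8(cand)
  keep_labels <- unique(lab[strong])
  matrix(as.integer(cand & (lab %in% keep_labels)), nrow(thinned), ncol(thinned))
}

#' Detect and trace the lesion border
#'
#' The four-step Canny detector — Gaussian smoothing, 2x2 gradient,
#' non-maximum suppression, hysteresis linking — followed by extraction of the
#' longest closed 8-connected contour, returned as an ordered border trace.
#'
#' When thresholds are not given, `high` defaults to the 90th percentile of
#' the nonzero thinned magnitudes and `low` to `0.4 * high`, a rule that
#' adapts to both intensity images and binary masks.
#'
#' @param x Numeric matrix: a segmented lesion mask (binary) or smoothed
#'   grayscale image.
#' @param sigma Gaussian smoothing standard deviation.
#' @param low,high Hysteresis thresholds; `NULL` for the percentile defaults.
#' @return A `border_trace` with the ordered closed contour, its `perimeter`,
#'   and the binary `edge_map`.
#' @examples
#' les <- make_regular_lesion(size = 128, axes = c(30, 30), noise_sd = 0, seed = 1)
#' tr <- canny_border(les$mask)
#' tr$perimeter / (2 * pi * 30)
#' @export
canny_border <- function(x, sigma = 1.4, low = NULL, high = NULL) {
  if (sum(x != 0) == 0L) abort("empty input: no lesion foreground to trace")
  sm <- gaussian_smooth(x, sigma)
  field <- gradient_2x2(sm)
  thin <- nonmax_suppress(field)
  nz <- thin[thin > 0]
  if (length(nz) == 0L) abort("no gradient ridges survive non-maximum suppression")
  if (is.null(high)) high <- as.numeric(stats::quantile(nz, 0.9))
  if (is.null(low)) low <- 0.4 * high
  edges <- hysteresis_link(thin, low, high)
  n_edge <- sum(edges)
  if (n_edge < 8L) {
    abort(sprintf("no closed contour found (only %d edge pixels)", n_edge))
  }
  lab <- label8(edges)
  best <- NULL
  for (l in seq_len(min(3L, max(lab)))) {
    comp <- matrix(0L, nrow(edges), ncol(edges))
    comp[lab == l] <- 1L
    if (sum(comp) < 8L) next
    tr <- moore_trace(comp)
    if (nrow(tr) < 8L) next
    gap <- max(abs(tr[1L, ] - tr[nrow(tr), ]))
    if (gap <= 1L && (is.null(best) || nrow(tr) > nrow(best))) best <- tr
  }
  if (is.null(best)) {
    abort(sprintf("no closed contour found (%d edge pixels, none forming a loop)",
                  n_edge))
  }
  new_border_trace(best, closed = TRUE, edge_map = edges)
}

#' Trace the boundary of a binary mask
#'
#' Orders the outer boundary pixels of a filled mask into a closed
#' 8-connected loop (Moore neighbor tracing). This is the geometric boundary
#' of the mask itself, used for perimeter measurements; [canny_border()]
#' extracts the border from image gradients instead.
#'
#' @param mask Binary matrix (1 = lesion).
#' @return A closed `border_trace`.
#' @export
trace_mask_boundary <- function(mask) {
  mask <- as_binary_mask(mask)
  if (sum(mask) == 0L) abort("cannot trace an empty mask")
  new_border_trace(moore_trace(mask), closed = TRUE)
}
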