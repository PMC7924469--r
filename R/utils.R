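# Internal raster helpers shared across modules.
# Conventions: images are numeric matrices indexed [row, col], origin top-left,
# 0-based coordinates only at the file I/O surface; masks use 1 = lesion.

#' @importFrom rlang abort warn
NULL

# Shift a matrix by (dr, dc) with edge replication.
shift_mat <- function(x, dr, dc) {
  nr <- nrow(x)
  nc <- ncol(x)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  x[ri, ci, drop = FALSE]
}

# 8-connected component labels of a binary matrix. Returns an integer matrix
# (0 = background) with components numbered in decreasing size order.
label8 <- function(mask) {
  stopifnot(is.matrix(mask))
  fg <- which(mask > 0)
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (length(fg) == 0L) return(out)
  nr <- nrow(mask)
  idx <- matrix(0L, nrow(mask), ncol(mask))
  idx[fg] <- seq_along(fg)
  edges <- NULL
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  r <- (fg - 1L) %% nr + 1L
  cc <- (fg - 1L) %/% nr + 1L
  for (o in offs) {
    r2 <- r + o[1L]
    c2 <- cc + o[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    nb <- idx[cbind(r2[ok], c2[ok])]
    keep <- nb > 0L
    if (any(keep)) {
      edges <- rbind(edges, cbind(idx[fg[ok]][keep], nb[keep]))
    }
  }
  g <- igraph::graph_from_edgelist(
    rbind(edges, cbind(seq_along(fg), seq_along(fg))),
    directed = FALSE
  )
  comp <- igraph::components(g)$membership
  sizes <- sort(table(comp), decreasing = TRUE)
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))] <- seq_along(sizes)
  out[fg] <- relabel[comp]
  out
}

# Keep the largest 8-connected foreground component.
largest_component <- function(mask) {
  lab <- label8(mask)
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[lab == 1L] <- 1L
  out
}

# Fill interior holes of a binary mask.
fill_holes <- function(mask) {
  img <- EBImage::fillHull(EBImage::Image(mask > 0))
  matrix(as.integer(img > 0), nrow(mask), ncol(mask))
}

# Moore-neighbor boundary trace of a binary region. Returns an n x 2 matrix of
# (row, col) coordinates walking the outer boundary; the trace is closed (last
# point 8-adjacent to the first). Works on thin structures (one-pixel-wide
# rings/curves, which are traversed along both sides) as well as filled
# regions. Stops on Jacob's criterion (re-entering the start pixel from the
# same direction as the first visit).
moore_trace <- function(mask) {
  fg <- which(mask > 0)
  if (length(fg) == 0L) abort("cannot trace an empty mask")
  nr <- nrow(mask)
  nc <- ncol(mask)
  at <- function(r, c) {
    r >= 1L && r <= nr && c >= 1L && c <= nc && mask[r, c] > 0
  }
  # start: left-most column, top-most row within it (its W and N neighbors are
  # background by construction, so "came from the west" is valid)
  cc <- (fg[1L] - 1L) %/% nr + 1L
  start <- c(which(mask[, cc] > 0)[1L], cc)
  if (length(fg) == 1L) return(matrix(start, ncol = 2L))
  # directions 0..7 clockwise from west: W NW N NE E SE S SW; offsets (row,col)
  off <- matrix(c(0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L,
                  0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L),
                ncol = 2L, byrow = TRUE)
  cap <- length(fg) * 4L + 8L
  path <- matrix(0L, cap, 2L)
  path[1L, ] <- start
  np <- 1L
  cur <- start
  back <- 0L  # direction from cur to the pixel we came from
  second <- NULL
  repeat {
    nxt <- NULL
    for (k in 1:8) {
      d <- (back + k) %% 8L
      r2 <- cur[1L] + off[d + 1L, 1L]
      c2 <- cur[2L] + off[d + 1L, 2L]
      if (at(r2, c2)) {
        nxt <- c(r2, c2)
        break
      }
    }
    if (is.null(nxt)) break
    # stop when about to repeat the opening move from the start pixel
    if (np > 1L && all(cur == start) && all(nxt == second)) break
    if (is.null(second)) second <- nxt
    np <- np + 1L
    if (np > cap) break
    path[np, ] <- nxt
    back <- (d + 4L) %% 8L
    cur <- nxt
  }
  # drop trailing duplicate of the start pixel, if present
  if (np > 1L && all(path[np, ] == start)) np <- np - 1L
  path[seq_len(np), , drop = FALSE]
}

# Arc length of an ordered trace (diagonal steps sqrt(2)), closing the loop
# when `closed` is TRUE.
trace_arclength <- function(coords, closed = TRUE) {
  if (nrow(coords) < 2L) return(0)
  d <- diff(coords)
  len <- sum(sqrt(rowSums(d^2)))
  if (closed) {
    len <- len + sqrt(sum((coords[1L, ] - coords[nrow(coords), ])^2))
  }
  len
}

# Rasterize a polyline (n x 2 matrix of row,col, possibly fractional) into an
# 8-connected pixel chain by dense sampling of each segment.
rasterize_polyline <- function(pts) {
  segs <- lapply(seq_len(nrow(pts) - 1L), function(i) {
    p <- pts[i, ]
    q <- pts[i + 1L, ]
    n <- max(2L, ceiling(max(abs(q - p)) * 3))
    t <- seq(0, 1, length.out = n)
    cbind(p[1L] + t * (q[1L] - p[1L]), p[2L] + t * (q[2L] - p[2L]))
  })
  xy <- round(do.call(rbind, segs))
  xy[!duplicated(xy), , drop = FALSE]
}

# Bilinear / nearest-neighbor resize (EBImage expects [col, row] ordering, so
# transpose around the call).
resize_image <- function(x, size, mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  if (nrow(x) == size && ncol(x) == size) return(x)
  img <- EBImage::Image(t(x))
  out <- EBImage::resize(img, w = size, h = size,
                         filter = if (mode == "bilinear") "bilinear" else "none")
  t(EBImage::imageData(out))
}

# 3x3 median filter passes with edge replication (used by smooth_edges).
# Vectorized median-of-9 via a sorting network (Paeth).
median3 <- function(x, passes = 1L) {
  for (pass in seq_len(passes)) {
    p <- vector("list", 9L)
    i <- 1L
    for (dr in -1:1) for (dc in -1:1) {
      p[[i]] <- shift_mat(x, dr, dc)
      i <- i + 1L
    }
    swap <- function(a, b) {
      lo <- pmin(p[[a]], p[[b]])
      p[[b]] <<- pmax(p[[a]], p[[b]])
      p[[a]] <<- lo
    }
    swap(2, 3); swap(5, 6); swap(8, 9)
    swap(1, 2); swap(4, 5); swap(7, 8)
    swap(2, 3); swap(5, 6); swap(8, 9)
    p[[4]] <- pmax(p[[1]], p[[4]])
    p[[6]] <- pmin(p[[6]], p[[9]])
    swap(5, 8)
    p[[7]] <- pmax(p[[4]], p[[7]])
    p[[5]] <- pmax(p[[2]], p[[5]])
    p[[3]] <- pmin(p[[3]], p[[6]])
    p[[5]] <- pmin(p[[5]], p[[8]])
    p[[5]] <- pmax(p[[7]], p[[5]])
    p[[5]] <- pmin(p[[3]], p[[5]])
    x <- p[[5]]
  }
  x
}

as_binary_mask <- function(mask) {
  if (!is.matrix(mask)) abort("mask must be a matrix")
  matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
}

is_odd <- function(x) x %% 2L == 1L
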