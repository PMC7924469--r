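#' Synthetic lesion fixtures
#'
#' Seeded generators for dermoscopy-style test images: a roughly centered dark
#' lesion on a lighter background with additive Gaussian noise, a noise-free
#' ground-truth mask, and a border whose roughness is controllable. Smooth
#' (elliptical) lesions carry label 1 = regular; fractally perturbed blobs
#' carry label 0 = irregular.
#'
#' @name fixtures
NULL

new_synthetic_lesion <- function(image, mask, label, roughness, seed, id) {
  structure(
    list(image = image, mask = mask, label = as.integer(label),
         roughness = roughness, seed = as.integer(seed), id = id),
    class = "synthetic_lesion"
  )
}

#' @export
print.synthetic_lesion <- function(x, ...) {
  cat(sprintf(
    "<synthetic_lesion %s> %dx%d, label = %d (%s), roughness = %.3g, seed = %d\n",
    x$id, nrow(x$image), ncol(x$image), x$label,
    if (x$label == 1L) "regular" else "irregular", x$roughness, x$seed))
  invisible(x)
}

#' Generate a regular (smooth-bordered) synthetic lesion
#'
#' Draws a dark filled ellipse on a lighter background with additive Gaussian
#' noise. The noise-free ellipse is the ground-truth mask and the sample is
#' labeled regular (1).
#'
#' @param size Canvas side length in pixels (square image), at least 64.
#' @param axes Semi-axes of the ellipse in pixels, `c(row, col)`.
#' @param contrast Gray-level gap between background and lesion mean (> 0).
#' @param noise_sd Standard deviation of the additive Gaussian noise, in gray
#'   levels.
#' @param seed Integer seed; identical seed and parameters reproduce
#'   bit-identical output.
#' @param background Background mean gray level.
#' @return A `synthetic_lesion`: list with integer `image` (0-255 matrix),
#'   binary `mask` (1 = lesion), `label`, `roughness`, `seed`, `id`.
#' @examples
#' les <- make_regular_lesion(size = 128, axes = c(30, 20), seed = 1)
#' table(les$mask)
#' @export
make_regular_lesion <- function(size = 256, axes = c(60, 40), contrast = 120,
                                noise_sd = 8, seed = 1, background = 200) {
  if (size < 64) abort("size must be at least 64 pixels")
  if (length(axes) != 2L || any(axes <= 0)) abort("axes must be two positive semi-axes")
  if (max(axes) > size / 2 - 8) {
    abort(sprintf(
      "ellipse semi-axes (%g, %g) do not fit a %dx%d canvas with an 8-pixel margin",
      axes[1], axes[2], size, size))
  }
  if (contrast <= 0) abort("contrast must be positive")
  ctr <- (size + 1) / 2
  rr <- matrix(seq_len(size), size, size)
  cc <- t(rr)
  mask <- matrix(as.integer(((rr - ctr) / axes[1])^2 + ((cc - ctr) / axes[2])^2 <= 1),
                 size, size)
  img <- matrix(background, size, size) - contrast * mask
  old <- .Random.seed_exists()
  set.seed(seed)
  img <- img + matrix(stats::rnorm(size * size, sd = noise_sd), size, size)
  .restore_seed(old)
  img <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), size, size)
  new_synthetic_lesion(img, mask, 1L, 0, seed, sprintf("reg-s%d", seed))
}

# save/restore the global RNG state so generators are pure in their seed
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Generate an irregular (rough-bordered) synthetic lesion
#'
#' Builds a star-convex blob whose polar radius is
#' `r(theta) = base_radius * (1 + roughness * s(theta))`, where `s` is a sum of
#' sinusoidal harmonics with seeded random phases and 1/f-weighted amplitudes,
#' rescaled to unit peak so `roughness` is the fractional perturbation
#' amplitude. Labeled irregular (0). Increasing `roughness` at a fixed seed
#' increases boundary length at comparable area.
#'
#' @inheritParams make_regular_lesion
#' @param base_radius Mean radius of the blob in pixels.
#' @param roughness Fractional radial perturbation amplitude in `[0, 1)`;
#'   0 reproduces the smooth disc limit.
#' @param harmonics Highest angular harmonic of the perturbation.
#' @return A `synthetic_lesion` with label 0.
#' @examples
#' les <- make_irregular_lesion(size = 128, base_radius = 30,
#'                              roughness = 0.35, seed = 2)
#' @export
make_irregular_lesion <- function(size = 256, base_radius = 60, roughness = 0.35,
                                  harmonics = 24, contrast = 120, noise_sd = 8,
                                  seed = 1, background = 200) {
  if (size < 64) abort("size must be at least 64 pixels")
  if (roughness < 0) abort("roughness must be non-negative")
  if (roughness >= 1) abort("roughness >= 1 would drive the radius r(theta) <= 0")
  if (base_radius * (1 + roughness) > size / 2 - 8) {
    abort("base_radius * (1 + roughness) does not fit the canvas with an 8-pixel margin")
  }
  ctr <- (size + 1) / 2
  rr <- matrix(seq_len(size), size, size)
  cc <- t(rr)
  theta <- atan2(cc - ctr, rr - ctr)
  rho <- sqrt((rr - ctr)^2 + (cc - ctr)^2)
  old <- .Random.seed_exists()
  set.seed(seed)
  if (roughness > 0 && harmonics >= 2) {
    ks <- 2:harmonics
    amp <- stats::rnorm(length(ks)) / ks
    phs <- stats::runif(length(ks), 0, 2 * pi)
    s <- matrix(0, size, size)
    for (i in seq_along(ks)) s <- s + amp[i] * cos(ks[i] * theta + phs[i])
    peak <- max(abs(range(s)))
    s <- s / peak
  } else {
    s <- matrix(0, size, size)
  }
  radius <- base_radius * (1 + roughness * s)
  if (any(radius <= 0)) {
    .restore_seed(old)
    abort("radial perturbation drove r(theta) <= 0; reduce roughness")
  }
  mask <- matrix(as.integer(rho <= radius), size, size)
  img <- matrix(background, size, size) - contrast * mask
  img <- img + matrix(stats::rnorm(size * size, sd = noise_sd), size, size)
  .restore_seed(old)
  img <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), size, size)
  new_synthetic_lesion(img, mask, 0L, roughness, seed, sprintf("irr-s%d", seed))
}

#' Rasterized Koch curve
#'
#' Constructs the classic fractal line: each segment is split in three and the
#' middle third replaced by two equal segments forming a triangular bump.
#' Iteration 0 is a straight line; the limiting curve has box-counting
#' dimension log(4)/log(3). Used as a fixture with a known fractal dimension.
#'
#' @param iterations Number of refinement steps (>= 0).
#' @param length Horizontal extent of the curve in pixels.
#' @return A `border_trace` (open curve) whose `coords` are the rasterized
#'   curve pixels; attribute `segments` holds the segment count `4^iterations`.
#' @examples
#' k <- koch_border(3, length = 243)
#' attr(k, "segments")
#' @export
koch_border <- function(iterations, length = 729) {
  if (iterations < 0) abort("iterations must be >= 0")
  pts <- c(0 + 0i, length + 0i)
  rot <- exp(-1i * pi / 3) # upward bump (negative imaginary = smaller row)
  for (it in seq_len(iterations)) {
    out <- vector("complex", (length(pts) - 1L) * 4L + 1L)
    j <- 1L
    for (i in seq_len(length(pts) - 1L)) {
      p <- pts[i]; q <- pts[i + 1L]
      v <- (q - p) / 3
      out[j:(j + 3L)] <- c(p, p + v, p + v + v * rot, p + 2 * v)
      j <- j + 4L
    }
    out[j] <- pts[length(pts)]
    pts <- out
  }
  y <- Im(pts)
  x <- Re(pts)
  poly <- cbind(max(0, -min(y)) + y, x) # rows grow downward; shift non-negative
  poly[, 1L] <- max(poly[, 1L]) - poly[, 1L] + 1 # bump points up the canvas
  poly[, 2L] <- poly[, 2L] + 1
  coords <- rasterize_polyline(poly)
  new_border_trace(coords, closed = FALSE,
                   segments = 4L^iterations)
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

apply_transform <- function(m, tf) {
  switch(tf,
    identity = m,
    rot90 = rot90cw(m),
    rot180 = rot90cw(rot90cw(m)),
    rot270 = rot90cw(rot90cw(rot90cw(m))),
    fliph = m[, ncol(m):1, drop = FALSE],
    flipv = m[nrow(m):1, , drop = FALSE],
    abort(sprintf("unknown transform '%s'", tf))
  )
}

lesion_transforms <- c("identity", "rot90", "rot180", "rot270", "fliph", "flipv")

#' Augment lesions by rotation and flipping
#'
#' Expands each sample into six: the original plus 90/180/270 degree rotations
#' and horizontal/vertical flips. Masks are transformed identically to images
#' and labels are preserved.
#'
#' @param samples A `synthetic_lesion` or a list of them.
#' @return A list of `synthetic_lesion`, six per input sample.
#' @export
augment_flip_rotate <- function(samples) {
  if (inherits(samples, "synthetic_lesion")) samples <- list(samples)
  if (length(samples) == 0L) abort("samples must be a nonempty list")
  purrr::map(samples, function(s) {
    purrr::map(lesion_transforms, function(tf) {
      out <- s
      out$image <- apply_transform(s$image, tf)
      out$mask <- apply_transform(s$mask, tf)
      out$id <- paste0(s$id, "-", tf)
      out
    })
  }) |> purrr::flatten()
}

#' Generate a labeled synthetic dataset
#'
#' Draws seeded, parameter-jittered regular and irregular lesions. Regular
#' samples are ellipses with randomized semi-axes; irregular samples are rough
#' blobs with roughness drawn from `roughness_range`. With `balance = TRUE`,
#' flip/rotate augmentation tops up the minority class to parity.
#'
#' @param n_regular,n_irregular Sample counts per class (not both 0).
#' @param seed Master seed; all per-sample seeds and jitter derive from it.
#' @param balance Top up the minority class by augmentation.
#' @param size Canvas side length in pixels.
#' @param roughness_range Range the irregular-class roughness is drawn from.
#' @return List of `synthetic_lesion` objects.
#' @examples
#' ds <- make_dataset(3, 3, seed = 1, size = 128)
#' table(vapply(ds, `[[`, integer(1), "label"))
#' @export
make_dataset <- function(n_regular, n_irregular, seed = 1, balance = FALSE,
                         size = 256, roughness_range = c(0.35, 0.55)) {
  if (n_regular < 0 || n_irregular < 0 || n_regular + n_irregular == 0) {
    abort("need non-negative class counts, not both zero")
  }
  old <- .Random.seed_exists()
  set.seed(seed)
  scale <- size / 256
  reg_par <- list(
    a = stats::runif(n_regular, 45, 75) * scale,
    b = stats::runif(n_regular, 35, 65) * scale,
    contrast = stats::runif(n_regular, 100, 140),
    noise = stats::runif(n_regular, 5, 10),
    seed = sample.int(1e6, n_regular)
  )
  irr_par <- list(
    radius = stats::runif(n_irregular, 40, 65) * scale,
    rough = stats::runif(n_irregular, roughness_range[1], roughness_range[2]),
    harm = sample(16:32, n_irregular, replace = TRUE),
    contrast = stats::runif(n_irregular, 100, 140),
    noise = stats::runif(n_irregular, 5, 10),
    seed = sample.int(1e6, n_irregular)
  )
  .restore_seed(old)
  reg <- purrr::map(seq_len(n_regular), function(i) {
    s <- make_regular_lesion(size = size,
                             axes = c(reg_par$a[i], reg_par$b[i]),
                             contrast = reg_par$contrast[i],
                             noise_sd = reg_par$noise[i],
                             seed = reg_par$seed[i])
    s$id <- sprintf("reg%03d", i)
    s
  })
  irr <- purrr::map(seq_len(n_irregular), function(i) {
    s <- make_irregular_lesion(size = size,
                               base_radius = irr_par$radius[i],
                               roughness = irr_par$rough[i],
                               harmonics = irr_par$harm[i],
                               contrast = irr_par$contrast[i],
                               noise_sd = irr_par$noise[i],
                               seed = irr_par$seed[i])
    s$id <- sprintf("irr%03d", i)
    s
  })
  samples <- c(reg, irr)
  if (balance && n_regular != n_irregular) {
    minority <- if (n_regular < n_irregular) reg else irr
    if (length(minority) == 0L) abort("cannot balance: minority class is empty")
    deficit <- abs(n_regular - n_irregular)
    pool <- purrr::map(minority, function(s) {
      purrr::map(lesion_transforms[-1L], function(tf) {
        out <- s
        out$image <- apply_transform(s$image, tf)
        out$mask <- apply_transform(s$mask, tf)
        out$id <- paste0(s$id, "-", tf)
        out
      })
    }) |> purrr::flatten()
    if (deficit > length(pool)) {
      abort("cannot balance: not enough augmented copies to reach parity")
    }
    samples <- c(samples, pool[seq_len(deficit)])
  }
  samples
}

#' Write a lesion dataset to disk
#'
#' Writes each sample's image and mask as 8-bit grayscale PNG, labels as a CSV
#' with columns `id, label`, and a JSON manifest of generation metadata.
#'
#' @param samples List of `synthetic_lesion`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest as a tibble.
#' @export
write_lesion_dataset <- function(samples, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- purrr::map(samples, function(s) {
    img_path <- file.path(dir, paste0(s$id, ".png"))
    mask_path <- file.path(dir, paste0(s$id, "_mask.png"))
    write_image_png(s$image, img_path)
    write_image_png(s$mask * 255L, mask_path)
    tibble::tibble(id = s$id, label = s$label, image = basename(img_path),
                   mask = basename(mask_path), roughness = s$roughness,
                   seed = s$seed)
  })
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest[, c("id", "label")], file.path(dir, "labels.csv"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read / write 8-bit grayscale images
#'
#' `read_image()` loads a PNG or TIFF as a numeric matrix in `[0, 255]`
#' (RGB inputs are kept as an array for [to_grayscale()]); `write_image_png()`
#' stores a matrix as an 8-bit grayscale PNG.
#'
#' @param path File path (`.png`, `.tif`, `.tiff`).
#' @return `read_image()`: a matrix (grayscale) or H x W x 3 array (RGB).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        abort("reading TIFF requires the 'tiff' package")
      }
      tiff::readTIFF(path)
    },
    abort(sprintf("unsupported image format '%s' (use PNG or TIFF)", ext))
  )
  if (length(dim(x)) == 3L && dim(x)[3L] == 4L) x <- x[, , 1:3] # drop alpha
  x * 255
}

#' @param image Numeric matrix; values are clipped to `[0, 255]`.
#' @rdname read_image
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 255) / 255, path)
  invisible(path)
}
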