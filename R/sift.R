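#' @name dense-descriptors
#' @title Dense multi-scale gradient-orientation descriptors
#'
#' @description
#' The baseline representation starts from SIFT-style local descriptors
#' computed densely on a regular grid (no keypoint detection): at each grid
#' position a 4x4 array of spatial cells, each summarizing gradient magnitude
#' into 8 orientation bins, gives a 128-dimensional descriptor. Descriptors
#' are computed at several scales (cell sizes) on an image first down-sampled
#' by area averaging. Descriptors with zero gradient energy ("zero
#' descriptors", e.g. from flat background) are not kept; they are counted and
#' that count becomes an extra histogram dimension downstream.
NULL

#' Down-sample an image by local (area) averaging
#'
#' @param image Numeric matrix.
#' @param factor Integer >= 1; trailing rows/columns that do not fill a
#'   complete block are dropped.
#' @return Numeric matrix of size `floor(dim / factor)`.
#' @export
downsample_image <- function(image, factor) {
  abort_if(factor < 1, "downsample factor must be >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(image)
  h2 <- nrow(image) %/% factor
  w2 <- ncol(image) %/% factor
  abort_if(h2 < 1 || w2 < 1, "image smaller than one downsampling block")
  m <- image[seq_len(h2 * factor), seq_len(w2 * factor), drop = FALSE]
  # average rows within blocks, then columns
  rb <- matrix(colMeans(matrix(m, nrow = factor)), nrow = h2)
  t(matrix(colMeans(matrix(t(rb), nrow = factor)), nrow = w2))
}

# exclusive-prefix integral image: sum over rows y0..y1, cols x0..x1 is
# I[y1+1,x1+1] - I[y0,x1+1] - I[y1+1,x0] + I[y0,x0]
integral_image <- function(m) {
  I <- matrix(apply(m, 2, cumsum), nrow(m), ncol(m))
  I <- matrix(t(apply(I, 1, cumsum)), nrow(m), ncol(m))
  rbind(0, cbind(0, I))
}

# number of grid positions along an axis of `n` pixels for footprint `f`
grid_len <- function(n, f, step) if (n >= f) (n - f) %/% step + 1L else 0L

#' Dense descriptors for one image
#'
#' @param image Numeric matrix (grayscale, any range) or 3-channel array
#'   (averaged to luminance).
#' @param scales Integer vector of cell sizes in pixels on the down-sampled
#'   image; the descriptor footprint at scale `b` is `4 b`. Default
#'   `c(4, 8, 16)`.
#' @param step Grid step in pixels on the down-sampled image (default 4).
#' @param downsample Area-averaging factor applied before extraction
#'   (default 4).
#' @return Object of class `ish_descriptor_set`: one element per scale, each
#'   `list(scale, descriptors, zero_count, grid_count)` where `descriptors`
#'   is a kept-by-128 matrix of unit-normalized (0.2-clamped, renormalized)
#'   descriptors and `zero_count + nrow(descriptors) == grid_count`. A scale
#'   whose footprint does not fit in the image yields an empty grid, not an
#'   error.
#' @export
dense_descriptors <- function(image, scales = c(4L, 8L, 16L), step = 4L,
                              downsample = 4L) {
  if (length(dim(image)) == 3) image <- rowMeans(image, dims = 2)
  abort_if(!is.matrix(image) || nrow(image) < 1 || ncol(image) < 1,
           "image must be a non-empty matrix")
  abort_if(length(scales) < 1, "need at least one scale")
  abort_if(step < 1, "step must be >= 1")
  img <- downsample_image(image, downsample)
  h <- nrow(img); w <- ncol(img)

  # gradients by central differences, replicated edges
  gx <- (img[, c(2:w, w), drop = FALSE] - img[, c(1, 1:(w - 1)), drop = FALSE]) / 2
  gy <- (img[c(2:h, h), , drop = FALSE] - img[c(1, 1:(h - 1)), , drop = FALSE]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx)                       # [-pi, pi]
  obin <- (floor((ang + pi) / (2 * pi) * 8)) %% 8 + 1

  ints <- lapply(1:8, function(o) integral_image(mag * (obin == o)))

  out <- lapply(scales, function(b) {
    f <- 4L * as.integer(b)
    nx <- grid_len(w, f, step)
    ny <- grid_len(h, f, step)
    n <- nx * ny
    if (n == 0L) {
      return(list(scale = b, descriptors = matrix(0, 0, 128),
                  zero_count = 0L, grid_count = 0L))
    }
    xs <- 1L + step * (seq_len(nx) - 1L)
    ys <- 1L + step * (seq_len(ny) - 1L)
    X0 <- rep(xs, each = ny)                 # grid enumerated y-fastest
    Y0 <- rep(ys, times = nx)
    D <- matrix(0, n, 128)
    for (ci in 0:3) for (cj in 0:3) for (o in 1:8) {
      I <- ints[[o]]
      y0 <- Y0 + ci * b; y1 <- y0 + b - 1L
      x0 <- X0 + cj * b; x1 <- x0 + b - 1L
      col <- (ci * 4L + cj) * 8L + o
      D[, col] <- I[cbind(y1 + 1L, x1 + 1L)] - I[cbind(y0, x1 + 1L)] -
        I[cbind(y1 + 1L, x0)] + I[cbind(y0, x0)]
    }
    nrm <- sqrt(rowSums(D^2))
    zero <- nrm < 1e-10
    D <- D[!zero, , drop = FALSE]
    if (nrow(D) > 0) {
      D <- D / nrm[!zero]
      D[D > 0.2] <- 0.2                      # standard SIFT clamp
      D <- D / sqrt(rowSums(D^2))
    }
    list(scale = b, descriptors = D, zero_count = sum(zero),
         grid_count = n)
  })
  structure(out, class = "ish_descriptor_set",
            scales = as.integer(scales), step = as.integer(step),
            downsample = as.integer(downsample))
}

#' @export
print.ish_descriptor_set <- function(x, ...) {
  for (s in x) {
    cat(sprintf("scale %d: %d kept + %d zero = %d grid positions\n",
                s$scale, nrow(s$descriptors), s$zero_count, s$grid_count))
  }
  invisible(x)
}
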