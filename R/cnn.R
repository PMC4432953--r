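#' @name cnn-features
#' @title Layer-tapped convolutional features for ISH sections
#'
#' @description
#' The second representation forwards each 231x231 section through a
#' reference convolutional architecture (the standard "fast" 7-stage
#' transfer-learning topology) and reads activations out at five tap layers
#' (6, 9, 12, 16, 18). At those taps the feature maps are
#' 256x12x12, 512x12x12, 1024x12x12, 1024x6x6 and 3072x1x1, giving flattened
#' vectors of length 36864, 73728, 147456, 36864 and 3072. Per-gene vectors
#' are the element-wise maximum (or average) across the gene's sections.
#' Weights are pluggable: seeded random (He) initialization by default, or a
#' flat binary weight file for users who have converted pretrained weights.
NULL

#' Layer indices at which network features can be tapped
#' @export
CNN_TAPS <- c(6L, 9L, 12L, 16L, 18L)

#' Reference convolutional architecture
#'
#' Layer-indexed topology whose shape propagation from a 231x231x3 input
#' reproduces the published tap shapes. Convolutions are "valid" (explicit
#' zero-padding layers carry the padding), every stage rectifies, and stages
#' 1, 2 and 5 end in 2x2/2 max-pooling; stage 6 is fully connected.
#'
#' @return Object of class `ish_cnn_arch`: `layers` (list of layer specs),
#'   `input_size`, `taps`, `expected_tap_shapes` (maps, h, w at each tap).
#' @export
overfeat_fast_architecture <- function() {
  L <- list(
    list(type = "conv", kernel = 11L, stride = 4L, out = 96L),   # 1
    list(type = "relu"),                                         # 2
    list(type = "maxpool", kernel = 2L, stride = 2L),            # 3
    list(type = "conv", kernel = 5L, stride = 1L, out = 256L),   # 4
    list(type = "relu"),                                         # 5
    list(type = "maxpool", kernel = 2L, stride = 2L),            # 6  tap
    list(type = "pad", pad = 1L),                                # 7
    list(type = "conv", kernel = 3L, stride = 1L, out = 512L),   # 8
    list(type = "relu"),                                         # 9  tap
    list(type = "pad", pad = 1L),                                # 10
    list(type = "conv", kernel = 3L, stride = 1L, out = 1024L),  # 11
    list(type = "relu"),                                         # 12 tap
    list(type = "pad", pad = 1L),                                # 13
    list(type = "conv", kernel = 3L, stride = 1L, out = 1024L),  # 14
    list(type = "relu"),                                         # 15
    list(type = "maxpool", kernel = 2L, stride = 2L),            # 16 tap
    list(type = "linear", out = 3072L),                          # 17
    list(type = "relu")                                          # 18 tap
  )
  structure(list(layers = L, input_size = c(231L, 231L, 3L), taps = CNN_TAPS,
                 expected_tap_shapes = list(`6` = c(256L, 12L, 12L),
                                            `9` = c(512L, 12L, 12L),
                                            `12` = c(1024L, 12L, 12L),
                                            `16` = c(1024L, 6L, 6L),
                                            `18` = c(3072L, 1L, 1L))),
            class = "ish_cnn_arch")
}

#' Symbolic shape propagation through an architecture
#'
#' @param arch An `ish_cnn_arch`.
#' @return List (one per layer) of `c(maps, height, width)`.
#' @export
propagate_shapes <- function(arch) {
  h <- arch$input_size[1]; w <- arch$input_size[2]; c <- arch$input_size[3]
  out <- vector("list", length(arch$layers))
  for (i in seq_along(arch$layers)) {
    l <- arch$layers[[i]]
    if (l$type == "conv") {
      h <- (h - l$kernel) %/% l$stride + 1L
      w <- (w - l$kernel) %/% l$stride + 1L
      c <- l$out
    } else if (l$type == "maxpool") {
      h <- (h - l$kernel) %/% l$stride + 1L
      w <- (w - l$kernel) %/% l$stride + 1L
    } else if (l$type == "pad") {
      h <- h + 2L * l$pad
      w <- w + 2L * l$pad
    } else if (l$type == "linear") {
      h <- 1L; w <- 1L; c <- l$out
    }
    abort_if(h < 1 || w < 1,
             sprintf("layer %d (%s) collapses the spatial extent", i, l$type))
    out[[i]] <- c(as.integer(c), as.integer(h), as.integer(w))
  }
  out
}

validate_architecture <- function(arch) {
  shapes <- propagate_shapes(arch)
  for (tp in arch$taps) {
    want <- arch$expected_tap_shapes[[as.character(tp)]]
    got <- shapes[[tp]]
    abort_if(!identical(as.integer(got), as.integer(want)),
             sprintf("tap layer %d has shape (%s), expected (%s)",
                     tp, paste(got, collapse = ","), paste(want, collapse = ",")))
  }
  shapes
}

#' Build a deterministic feature extractor from an architecture
#'
#' Shape propagation is checked against the tap-shape contract before any
#' weight is allocated. Weights come from a seeded He-style random
#' initialization (zero biases) or from a weight file written by
#' [write_cnn_weights()].
#'
#' @param arch An `ish_cnn_arch` (default [overfeat_fast_architecture()]).
#' @param weights_source `"random"` or a path to a weight file.
#' @param seed Integer seed for random weights.
#' @param max_layer Deepest layer whose weights are materialized (default:
#'   all). Features can then only be extracted at taps up to this layer;
#'   limiting it saves most of the memory when only an early tap is needed.
#'   Earlier layers' random weights do not depend on it.
#' @return Object of class `ish_cnn_extractor`.
#' @export
build_extractor <- function(arch = overfeat_fast_architecture(),
                            weights_source = "random", seed = 1,
                            max_layer = NULL) {
  shapes <- validate_architecture(arch)
  max_layer <- as.integer(max_layer %||% length(arch$layers))
  # input channel count / flat length feeding each parametric layer
  in_shape <- arch$input_size[c(3, 1, 2)]
  fanins <- vector("list", length(arch$layers))
  for (i in seq_along(arch$layers)) {
    l <- arch$layers[[i]]
    if (l$type == "conv") {
      fanins[[i]] <- l$kernel * l$kernel * in_shape[1]
    } else if (l$type == "linear") {
      fanins[[i]] <- prod(in_shape)
    }
    in_shape <- shapes[[i]]
  }
  weights <- if (identical(weights_source, "random")) {
    with_seed(derive_seed(seed, "cnn_weights"), {
      lapply(seq_along(arch$layers), function(i) {
        l <- arch$layers[[i]]
        if (!l$type %in% c("conv", "linear") || i > max_layer) return(NULL)
        fi <- fanins[[i]]
        list(W = matrix(stats::rnorm(fi * l$out, sd = sqrt(2 / fi)), fi, l$out),
             b = numeric(l$out))
      })
    })
  } else {
    read_cnn_weights(weights_source, arch, fanins)
  }
  structure(list(arch = arch, shapes = shapes, weights = weights, seed = seed,
                 max_layer = max_layer,
                 weights_source = if (identical(weights_source, "random"))
                   "random" else "file"),
            class = "ish_cnn_extractor")
}

#' @export
print.ish_cnn_extractor <- function(x, ...) {
  cat(sprintf("CNN feature extractor: %d layers, taps %s, weights: %s\n",
              length(x$arch$layers), paste(x$arch$taps, collapse = "/"),
              x$weights_source))
  invisible(x)
}

#' Preprocess a section image for the network
#'
#' Bilinear resize to the network input size, grayscale replicated to three
#' channels, intensities scaled to `[0, 1]` (8/16-bit integer ranges are
#' rescaled) and centered at 0.5.
#'
#' @param image Numeric matrix or h x w x 3 array.
#' @param size Spatial input size (default 231).
#' @return `size x size x 3` array, centered.
#' @export
preprocess_section <- function(image, size = 231L) {
  abort_if(is.null(dim(image)) || any(dim(image)[1:2] < 1) ||
             length(image) == 0, "empty image")
  x <- image
  mx <- max(x)
  if (mx > 1) x <- x / (if (mx > 255) 65535 else 255)
  if (length(dim(x)) == 2) x <- array(rep(x, 3), c(dim(x), 3))
  out <- array(0, c(size, size, 3))
  for (ch in 1:3) {
    out[, , ch] <- EBImage::resize(x[, , ch], w = size, h = size)
  }
  out - 0.5
}

# im2col: columns ordered channel-major, then kernel column, then kernel row
im2col <- function(A, k, stride) {
  h <- dim(A)[1]; w <- dim(A)[2]; c <- dim(A)[3]
  oh <- (h - k) %/% stride + 1L
  ow <- (w - k) %/% stride + 1L
  ys <- 1L + stride * (seq_len(oh) - 1L)
  xs <- 1L + stride * (seq_len(ow) - 1L)
  P <- matrix(0, oh * ow, k * k * c)
  col <- 0L
  for (ch in seq_len(c)) for (dx in seq_len(k)) for (dy in seq_len(k)) {
    col <- col + 1L
    P[, col] <- A[ys + dy - 1L, xs + dx - 1L, ch]
  }
  list(P = P, oh = oh, ow = ow)
}

forward_layer <- function(A, l, wt) {
  switch(l$type,
    conv = {
      ic <- im2col(A, l$kernel, l$stride)
      O <- ic$P %*% wt$W
      O <- sweep(O, 2, wt$b, "+")
      array(O, c(ic$oh, ic$ow, l$out))
    },
    relu = pmax(A, 0),
    maxpool = {
      oh <- (dim(A)[1] - l$kernel) %/% l$stride + 1L
      ow <- (dim(A)[2] - l$kernel) %/% l$stride + 1L
      i1 <- 1L + l$stride * (seq_len(oh) - 1L)
      j1 <- 1L + l$stride * (seq_len(ow) - 1L)
      O <- A[i1, j1, , drop = FALSE]
      for (dy in seq_len(l$kernel) - 1L) for (dx in seq_len(l$kernel) - 1L) {
        if (dy == 0L && dx == 0L) next
        O <- pmax(O, A[i1 + dy, j1 + dx, , drop = FALSE])
      }
      O
    },
    pad = {
      d <- dim(A)
      O <- array(0, c(d[1] + 2L * l$pad, d[2] + 2L * l$pad, d[3]))
      O[l$pad + seq_len(d[1]), l$pad + seq_len(d[2]), ] <- A
      O
    },
    linear = {
      v <- flatten_maps(A)
      array(as.vector(v %*% wt$W + wt$b), c(1L, 1L, l$out))
    },
    stop("unknown layer type: ", l$type)
  )
}

# flatten h x w x maps activations map-major, then row, then column
flatten_maps <- function(A) {
  matrix(as.vector(aperm(A, c(2, 1, 3))), nrow = 1)
}

#' Extract tap-layer feature vectors for one section
#'
#' One forward pass collects every requested tap. Flattening is map-major,
#' then row, then column.
#'
#' @param extractor An `ish_cnn_extractor`.
#' @param image Section image (any size; preprocessed internally).
#' @param taps Tap layer indices, a subset of 6/9/12/16/18.
#' @return Named list (by tap) of numeric vectors with attribute `tap`; or a
#'   single vector when one tap is requested via [extract_features()].
#' @export
extract_taps <- function(extractor, image, taps = CNN_TAPS) {
  bad <- setdiff(taps, extractor$arch$taps)
  abort_if(length(bad) > 0,
           sprintf("unsupported tap layer %s; valid taps: %s",
                   paste(bad, collapse = ","),
                   paste(extractor$arch$taps, collapse = ", ")))
  abort_if(max(taps) > (extractor$max_layer %||% max(taps)),
           sprintf("extractor was built with weights up to layer %d",
                   extractor$max_layer))
  A <- preprocess_section(image, extractor$arch$input_size[1])
  out <- list()
  upto <- max(taps)
  for (i in seq_len(upto)) {
    A <- forward_layer(A, extractor$arch$layers[[i]],
                       extractor$weights[[i]])
    if (i %in% taps) {
      v <- as.vector(flatten_maps(A))
      attr(v, "tap") <- i
      out[[as.character(i)]] <- v
    }
  }
  out
}

#' @rdname extract_taps
#' @param tap A single tap layer index.
#' @export
extract_features <- function(extractor, image, tap = 12L) {
  extract_taps(extractor, image, taps = tap)[[as.character(tap)]]
}

#' Pool per-section feature vectors into one per-gene vector
#'
#' @param vectors List of equal-length tap vectors (same tap).
#' @param mode `"max"` (element-wise maximum, default) or `"average"`.
#' @return Numeric vector of the common length.
#' @export
pool_sections <- function(vectors, mode = c("max", "average")) {
  mode <- match.arg(mode)
  abort_if(length(vectors) == 0, "no vectors to pool")
  p <- length(vectors[[1]])
  taps <- unique(vapply(vectors, function(v) attr(v, "tap") %||% NA_integer_,
                        numeric(1)))
  abort_if(length(taps) > 1, "cannot pool vectors from different tap layers")
  abort_if(any(vapply(vectors, length, integer(1)) != p),
           "cannot pool vectors of differing lengths")
  out <- if (mode == "max") {
    Reduce(pmax, vectors)
  } else {
    Reduce(`+`, vectors) / length(vectors)
  }
  out <- as.vector(out)
  if (!is.na(taps[1])) attr(out, "tap") <- as.integer(taps[1])
  out
}

#' Extract pooled convolutional features for a dataset
#'
#' @param stacks Named list of `ish_stack` objects (or an `ish_dataset`).
#' @param tap Tap layer (6, 9, 12, 16 or 18; default 12, the intermediate
#'   layer that performed best in the annotation experiments).
#' @param pooling `"max"` or `"average"` across sections.
#' @param weights_source `"random"` or a weight-file path.
#' @param arch Architecture (default [overfeat_fast_architecture()]).
#' @param seed Seed for random weights.
#' @param verbose Log progress.
#' @return `ish_features` matrix with representation tag `"cnn:L<tap>"`.
#' @export
extract_cnn_features <- function(stacks, tap = 12L,
                                 pooling = c("max", "average"),
                                 weights_source = "random",
                                 arch = overfeat_fast_architecture(),
                                 seed = 1, verbose = FALSE) {
  pooling <- match.arg(pooling)
  if (inherits(stacks, "ish_dataset")) stacks <- stacks$stacks
  abort_if(length(stacks) == 0, "no stacks supplied")
  ext <- build_extractor(arch, weights_source = weights_source, seed = seed,
                         max_layer = tap)
  vecs <- lapply(seq_along(stacks), function(i) {
    st <- stacks[[i]]
    per <- lapply(st$sections, function(s) {
      extract_features(ext, s$image, tap = tap)
    })
    if (i == 1 || i %% 25 == 0) {
      log_msg("cnn features: stack ", i, "/", length(stacks),
              verbose = verbose)
    }
    pool_sections(per, mode = pooling)
  })
  X <- do.call(rbind, vecs)
  rownames(X) <- names(stacks)
  feature_matrix(X, representation = paste0("cnn:L", tap),
                 config = list(tap = tap, pooling = pooling,
                               weights_source = if (identical(weights_source,
                                                              "random"))
                                 "random" else weights_source,
                               seed = seed))
}

#' Write / read extractor weights as a flat binary file
#'
#' Format: one JSON header line (per-layer matrix shapes) terminated by a
#' newline, followed by all weight matrices then bias vectors in layer order
#' as little-endian 32-bit floats (column-major).
#'
#' @param extractor An `ish_cnn_extractor`.
#' @param path Output file.
#' @export
write_cnn_weights <- function(extractor, path) {
  hdr <- lapply(seq_along(extractor$weights), function(i) {
    wt <- extractor$weights[[i]]
    if (is.null(wt)) return(NULL)
    list(layer = i, w_dim = dim(wt$W), b_len = length(wt$b))
  })
  hdr <- Filter(Negate(is.null), hdr)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(hdr, auto_unbox = FALSE), con)
  for (wt in extractor$weights) {
    if (is.null(wt)) next
    writeBin(as.vector(wt$W), con, size = 4, endian = "little")
    writeBin(wt$b, con, size = 4, endian = "little")
  }
  invisible(path)
}

read_cnn_weights <- function(path, arch, fanins) {
  abort_if(!file.exists(path), sprintf("weight file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- jsonlite::fromJSON(readLines(con, n = 1), simplifyVector = FALSE)
  weights <- vector("list", length(arch$layers))
  for (h in hdr) {
    i <- h$layer[[1]]
    l <- arch$layers[[i]]
    wd <- unlist(h$w_dim)
    abort_if(!l$type %in% c("conv", "linear") ||
               wd[1] != fanins[[i]] || wd[2] != l$out,
             sprintf("weight file layer %d does not match the architecture", i))
    W <- matrix(readBin(con, "numeric", n = prod(wd), size = 4,
                        endian = "little"), wd[1], wd[2])
    b <- readBin(con, "numeric", n = h$b_len[[1]], size = 4, endian = "little")
    weights[[i]] <- list(W = W, b = b)
  }
  for (i in seq_along(arch$layers)) {
    if (arch$layers[[i]]$type %in% c("conv", "linear")) {
      abort_if(is.null(weights[[i]]),
               sprintf("weight file is missing layer %d", i))
    }
  }
  weights
}
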