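#' Assign sections to sagittal intervals
#'
#' The brain is divided sagittally into equal-width intervals spanning the
#' range of the observed section positions; every section falls in exactly one
#' interval, with the maximum position clamped into the last.
#'
#' @param positions Numeric vector of sagittal positions (finite).
#' @param n_intervals Number of intervals (default 7).
#' @return Integer vector of interval indices in `1..n_intervals`.
#' @export
assign_intervals <- function(positions, n_intervals = 7L) {
  abort_if(length(positions) == 0, "empty position list")
  abort_if(any(!is.finite(positions)), "positions must be finite")
  abort_if(n_intervals < 1, "n_intervals must be >= 1")
  lo <- min(positions); hi <- max(positions)
  if (hi == lo) return(rep(1L, length(positions)))
  idx <- floor((positions - lo) / (hi - lo) * n_intervals) + 1L
  pmin(as.integer(idx), as.integer(n_intervals))
}

#' Aggregate per-section histograms into one brain-wide vector
#'
#' Histograms of sections assigned to the same sagittal interval are averaged
#' (reflecting regional sagittal expression) and the per-interval means are
#' concatenated in interval order. An interval with no sections contributes a
#' zero block. The result has length `per-section length x n_intervals`
#' (10521 = 501 x 3 x 7 at the default configuration).
#'
#' @param per_image_vectors List of equal-length numeric vectors, one per
#'   section.
#' @param interval_assignment Integer vector from [assign_intervals()].
#' @param n_intervals Number of intervals.
#' @return Numeric vector of length `length(v) * n_intervals`.
#' @export
build_global_bow <- function(per_image_vectors, interval_assignment,
                             n_intervals = 7L) {
  abort_if(length(per_image_vectors) == 0, "no per-image vectors")
  p <- length(per_image_vectors[[1]])
  lens <- vapply(per_image_vectors, length, integer(1))
  abort_if(any(lens != p), "per-image vectors differ in length")
  abort_if(length(interval_assignment) != length(per_image_vectors),
           "one interval index per section required")
  blocks <- lapply(seq_len(n_intervals), function(iv) {
    member <- which(interval_assignment == iv)
    if (length(member) == 0) return(numeric(p))
    Reduce(`+`, per_image_vectors[member]) / length(member)
  })
  unlist(blocks, use.names = FALSE)
}

#' Extract bag-of-visual-words features for a dataset
#'
#' Runs the full baseline representation: dense multi-scale descriptors per
#' section, a per-scale descriptor pool sampled across the whole corpus,
#' restarted K-means codebooks, per-section word histograms with the
#' zero-descriptor slot, and sagittal-interval aggregation into one global
#' vector per gene.
#'
#' @param stacks Named list of `ish_stack` objects (or an `ish_dataset`).
#' @param scales,step,downsample Passed to [dense_descriptors()].
#' @param K Codebook size per scale (default 500).
#' @param pool_size Descriptor pool size per scale (default 100000).
#' @param per_image_quota See [sample_pool()].
#' @param restarts K-means restarts (default 5).
#' @param iter_max Lloyd iteration cap per restart.
#' @param n_intervals Sagittal intervals (default 7).
#' @param normalize Histogram normalization, `"none"` or `"l1"`.
#' @param codebooks Optional pre-built codebooks (e.g. to featurize new genes
#'   against a frozen vocabulary); when NULL they are built from this corpus.
#' @param seed Integer seed for pooling and K-means.
#' @param verbose Log stage progress.
#'
#' @details Descriptors are streamed: each section's descriptor set is
#' computed, used (pool sampling or quantization) and discarded, so memory
#' stays bounded by one section plus the pool regardless of corpus size. When
#' codebooks are built from the corpus, descriptors are therefore computed
#' twice (once for pooling, once for quantization). Pool sampling keeps up to
#' `per_image_quota` descriptors per section and scale (default
#' `ceiling(pool_size / n_sections)`) and subsamples to `pool_size` if over
#' target; a corpus that undersupplies descriptors at some scale simply
#' yields a smaller pool at that scale.
#' @return Object of class `ish_features`: numeric matrix genes x features
#'   with gene IDs as rownames; attributes `representation = "bow"`,
#'   `config`, and `codebooks`.
#' @export
extract_bow_features <- function(stacks, scales = c(4L, 8L, 16L), step = 4L,
                                 downsample = 4L, K = 500L,
                                 pool_size = 100000L, per_image_quota = NULL,
                                 restarts = 5L, iter_max = 300L,
                                 n_intervals = 7L,
                                 normalize = c("none", "l1"),
                                 codebooks = NULL, seed = 1, verbose = FALSE) {
  normalize <- match.arg(normalize)
  if (inherits(stacks, "ish_dataset")) stacks <- stacks$stacks
  abort_if(length(stacks) == 0, "no stacks supplied")
  n_images <- sum(vapply(stacks, function(st) length(st$sections), integer(1)))

  if (is.null(codebooks)) {
    quota <- per_image_quota %||% ceiling(pool_size / n_images)
    abort_if(quota < 1, "per_image_quota must be >= 1")
    log_msg("sampling descriptor pool (target ", pool_size, " per scale)",
            verbose = verbose)
    sampled <- rep(list(list()), length(scales))
    pools <- with_seed(derive_seed(seed, "pool"), {
      for (st in stacks) {
        for (s in st$sections) {
          d <- dense_descriptors(s$image, scales = scales, step = step,
                                 downsample = downsample)
          for (si in seq_along(scales)) {
            D <- d[[si]]$descriptors
            take <- sample.int(nrow(D), min(quota, nrow(D)))
            if (length(take) > 0) {
              sampled[[si]][[length(sampled[[si]]) + 1L]] <-
                D[take, , drop = FALSE]
            }
          }
        }
      }
      ps <- lapply(seq_along(scales), function(si) {
        P <- do.call(rbind, sampled[[si]])
        abort_if(is.null(P) || nrow(P) == 0,
                 sprintf("no nonzero descriptors in the corpus at scale %d",
                         scales[si]))
        if (nrow(P) > pool_size) {
          P <- P[sample.int(nrow(P), pool_size), , drop = FALSE]
        }
        list(descriptors = P)
      })
      names(ps) <- paste0("scale", scales)
      attr(ps, "scales") <- as.integer(scales)
      ps
    })
    rm(sampled)
    log_msg("building codebooks: K = ", K, ", ", restarts, " restarts",
            verbose = verbose)
    codebooks <- build_codebooks(pools, K = K, restarts = restarts,
                                 seed = seed, iter_max = iter_max)
    rm(pools)
  }

  log_msg("quantizing and pooling over ", n_intervals, " sagittal intervals",
          verbose = verbose)
  vecs <- lapply(seq_along(stacks), function(i) {
    st <- stacks[[i]]
    per_img <- lapply(st$sections, function(s) {
      quantize(dense_descriptors(s$image, scales = scales, step = step,
                                 downsample = downsample),
               codebooks = codebooks, normalize = normalize)
    })
    pos <- vapply(st$sections, `[[`, numeric(1), "position")
    build_global_bow(per_img, assign_intervals(pos, n_intervals), n_intervals)
  })
  X <- do.call(rbind, vecs)
  rownames(X) <- names(stacks)
  feature_matrix(X, representation = "bow",
                 config = list(scales = scales, step = step,
                               downsample = downsample, K = K,
                               pool_size = pool_size, restarts = restarts,
                               n_intervals = n_intervals,
                               normalize = normalize, seed = seed),
                 codebooks = codebooks)
}

#' Construct an `ish_features` matrix
#'
#' Tags a genes-x-features numeric matrix (gene IDs as rownames) with its
#' representation label and extraction configuration.
#'
#' @param X Numeric matrix with gene IDs as rownames.
#' @param representation Representation tag, e.g. `"bow"` or `"cnn:L12"`.
#' @param config List of extraction parameters (stored as an attribute).
#' @param codebooks Optional codebooks used to produce `X`.
#' @return The matrix with class `ish_features`.
#' @export
feature_matrix <- function(X, representation, config = list(),
                           codebooks = NULL) {
  abort_if(is.null(rownames(X)), "feature matrix needs gene IDs as rownames")
  structure(X, class = c("ish_features", class(X)),
            representation = representation, config = config,
            codebooks = codebooks)
}

#' @export
print.ish_features <- function(x, ...) {
  cat(sprintf("Feature matrix [%s]: %d genes x %d features\n",
              attr(x, "representation"), nrow(x), ncol(x)))
  invisible(x)
}
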