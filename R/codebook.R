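#' Sample a per-scale descriptor pool from an image corpus
#'
#' Nonzero descriptors are sampled from every image (up to a per-image quota)
#' and pooled per scale for codebook construction. When the corpus holds at
#' least `pool_size` descriptors at a scale, the pool has exactly `pool_size`
#' rows: quota sampling is topped up from the unsampled remainder if needed.
#'
#' @param descriptor_sets List of [dense_descriptors()] outputs, one per image.
#' @param per_image_quota Max descriptors drawn per image per scale; default
#'   `ceiling(pool_size / n_images)`.
#' @param pool_size Target pool size per scale (default 100000).
#' @param seed Integer seed; sampling is deterministic given it.
#' @return Named list (by scale) of `list(descriptors, source_image)`, where
#'   `source_image` records each pooled row's image index.
#' @export
sample_pool <- function(descriptor_sets, per_image_quota = NULL,
                        pool_size = 100000L, seed = 1) {
  abort_if(length(descriptor_sets) < 1, "empty image corpus")
  scales <- attr(descriptor_sets[[1]], "scales")
  for (d in descriptor_sets) {
    abort_if(!identical(attr(d, "scales"), scales),
             "descriptor sets computed at differing scales")
  }
  quota <- per_image_quota %||% ceiling(pool_size / length(descriptor_sets))
  abort_if(quota < 1, "per_image_quota must be >= 1")

  pools <- with_seed(derive_seed(seed, "pool"), {
    lapply(seq_along(scales), function(si) {
      per_img <- lapply(seq_along(descriptor_sets), function(i) {
        D <- descriptor_sets[[i]][[si]]$descriptors
        n <- nrow(D)
        take <- sample.int(n, min(quota, n)) # no-op sample when n = 0
        list(sampled = D[take, , drop = FALSE],
             rest = D[setdiff(seq_len(n), take), , drop = FALSE],
             src = rep(i, length(take)),
             src_rest = rep(i, n - length(take)))
      })
      P <- do.call(rbind, lapply(per_img, `[[`, "sampled"))
      src <- unlist(lapply(per_img, `[[`, "src"))
      abort_if(is.null(P) || nrow(P) == 0,
               sprintf("no nonzero descriptors in the corpus at scale %d",
                       scales[si]))
      if (nrow(P) > pool_size) {
        keep <- sample.int(nrow(P), pool_size)
        P <- P[keep, , drop = FALSE]; src <- src[keep]
      } else if (nrow(P) < pool_size) {
        R <- do.call(rbind, lapply(per_img, `[[`, "rest"))
        src_r <- unlist(lapply(per_img, `[[`, "src_rest"))
        if (!is.null(R) && nrow(R) > 0) {
          add <- sample.int(nrow(R), min(pool_size - nrow(P), nrow(R)))
          P <- rbind(P, R[add, , drop = FALSE]); src <- c(src, src_r[add])
        }
      }
      list(descriptors = P, source_image = src)
    })
  })
  names(pools) <- paste0("scale", scales)
  attr(pools, "scales") <- scales
  pools
}

#' Build a visual-word codebook by restarted K-means
#'
#' K-means (Lloyd iterations) is run `restarts` times from random initial
#' centers drawn from the pool, and the solution with the smallest
#' within-cluster distance (total sum of squared distances of pool members to
#' their assigned centroid) is kept, since the outcome of K-means depends on
#' its initialization.
#'
#' @param pool Numeric matrix of descriptors (rows).
#' @param K Number of visual words (default 500).
#' @param restarts Number of random restarts (default 5).
#' @param seed Integer seed.
#' @param iter_max Lloyd iteration cap per restart (default 300).
#' @param scale Optional scale label stored with the codebook.
#' @return Object of class `ish_codebook`: `centroids` (K x p),
#'   `within_cluster_distance`, `K`, `scale`, `restarts`.
#' @export
build_codebook <- function(pool, K = 500L, restarts = 5L, seed = 1,
                           iter_max = 300L, scale = NA) {
  if (is.list(pool) && !is.null(pool$descriptors)) pool <- pool$descriptors
  abort_if(!is.matrix(pool), "pool must be a matrix of descriptors")
  abort_if(restarts < 1, "restarts must be >= 1")
  abort_if(nrow(pool) < K,
           sprintf("pool size %d is smaller than K = %d", nrow(pool), K))
  uniq <- unique(pool)
  abort_if(nrow(uniq) < K,
           sprintf("pool has only %d distinct descriptors for K = %d",
                   nrow(uniq), K))
  best <- NULL
  for (r in seq_len(restarts)) {
    km <- with_seed(derive_seed(seed, paste0("kmeans_restart_", r)), {
      fit <- NULL
      for (try in 1:10) {       # empty Lloyd cluster: re-draw the init
        init <- uniq[sample.int(nrow(uniq), K), , drop = FALSE]
        fit <- tryCatch(
          suppressWarnings(stats::kmeans(pool, centers = init,
                                         iter.max = iter_max,
                                         algorithm = "Lloyd")),
          error = function(e) NULL)
        if (!is.null(fit)) break
      }
      abort_if(is.null(fit), "K-means failed to produce K non-empty clusters")
      fit
    })
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  structure(list(centroids = unname(best$centers), K = as.integer(K),
                 scale = scale, within_cluster_distance = best$tot.withinss,
                 restarts = as.integer(restarts), seed = seed),
            class = "ish_codebook")
}

#' @export
print.ish_codebook <- function(x, ...) {
  cat(sprintf("Visual codebook (scale %s): K = %d, within-cluster distance = %.4g\n",
              as.character(x$scale), x$K, x$within_cluster_distance))
  invisible(x)
}

#' Build one codebook per scale from sampled pools
#'
#' @param pools Output of [sample_pool()].
#' @inheritParams build_codebook
#' @return Named list of `ish_codebook`, one per scale.
#' @export
build_codebooks <- function(pools, K = 500L, restarts = 5L, seed = 1,
                            iter_max = 300L) {
  scales <- attr(pools, "scales")
  cbs <- lapply(seq_along(pools), function(i) {
    build_codebook(pools[[i]]$descriptors, K = K, restarts = restarts,
                   seed = derive_seed(seed, paste0("codebook_scale_", scales[i])),
                   iter_max = iter_max, scale = scales[i])
  })
  names(cbs) <- names(pools)
  attr(cbs, "scales") <- scales
  cbs
}

# nearest centroid (squared Euclidean), deterministic tie-break to the
# lowest centroid index
nearest_centroid <- function(D, C) {
  s <- D %*% t(C) - matrix(rowSums(C^2) / 2, nrow(D), nrow(C), byrow = TRUE)
  max.col(s, ties.method = "first")
}

#' Quantize one image's descriptors against per-scale codebooks
#'
#' Each kept descriptor is assigned to its nearest visual word (Euclidean);
#' the per-scale histogram of word occurrences is extended by one extra
#' dimension holding the count of zero descriptors at that scale, and scales
#' are concatenated scale-major (all `K` word slots of scale 1, its
#' zero-count slot, then scale 2, ...).
#'
#' @param descriptor_set A [dense_descriptors()] result.
#' @param codebooks Named per-scale list from [build_codebooks()].
#' @param normalize `"none"` (raw counts, default) or `"l1"`.
#' @return Numeric vector of length `(K + 1) * n_scales` with attributes
#'   `K` and `scales`.
#' @export
quantize <- function(descriptor_set, codebooks, normalize = c("none", "l1")) {
  normalize <- match.arg(normalize)
  scales <- attr(descriptor_set, "scales")
  abort_if(!identical(as.integer(scales), as.integer(attr(codebooks, "scales"))),
           "codebook scales do not match descriptor scales")
  blocks <- lapply(seq_along(scales), function(si) {
    D <- descriptor_set[[si]]$descriptors
    K <- codebooks[[si]]$K
    counts <- if (nrow(D) == 0) {
      numeric(K)
    } else {
      tabulate(nearest_centroid(D, codebooks[[si]]$centroids), nbins = K)
    }
    v <- c(counts, descriptor_set[[si]]$zero_count)
    if (normalize == "l1" && sum(v) > 0) v <- v / sum(v)
    v
  })
  out <- unlist(blocks)
  attr(out, "K") <- codebooks[[1]]$K
  attr(out, "scales") <- scales
  out
}
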