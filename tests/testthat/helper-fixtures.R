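# Shared fixtures, all generated in code.

tiny_ontology <- function() generate_ontology(2, c(3, 2))

# small textured image: smooth blobs on noise, deterministic
textured_image <- function(h = 128, w = 128, seed = 42) {
  set.seed(seed)
  img <- matrix(stats::runif(h * w, 0, 0.1), h, w)
  xs <- seq_len(w); ys <- seq_len(h)
  for (i in 1:12) {
    cx <- stats::runif(1, 1, w); cy <- stats::runif(1, 1, h)
    img <- img + 0.5 * exp(-outer((ys - cy)^2, (xs - cx)^2, "+") / 50)
  }
  pmin(img, 1)
}

# exhaustive nearest-centroid assignment (oracle for quantize)
brute_force_assign <- function(D, C) {
  apply(D, 1, function(d) which.min(colSums((t(C) - d)^2)))
}

# O(n+ * n-) pairwise AUC (oracle for auc_score)
brute_force_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == -1]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# stub codebooks with arbitrary centroids (for dimension contracts without
# running K-means)
stub_codebooks <- function(scales, K, d = 128, seed = 1) {
  set.seed(seed)
  cbs <- lapply(scales, function(s) {
    structure(list(centroids = matrix(stats::rnorm(K * d), K, d),
                   K = as.integer(K), scale = s,
                   within_cluster_distance = NA_real_, restarts = 0L,
                   seed = seed),
              class = "ish_codebook")
  })
  names(cbs) <- paste0("scale", scales)
  attr(cbs, "scales") <- as.integer(scales)
  cbs
}

# mean intensity over a structure's painted region (its exclusive mask,
# sections inside its sagittal range)
masked_mean <- function(sim_or_stack, layout, ontology, sid) {
  stack <- if (inherits(sim_or_stack, "ish_stack_sim")) sim_or_stack$stack
    else sim_or_stack
  mask <- structure_mask(layout, ontology, sid)
  pos <- vapply(stack$sections, `[[`, numeric(1), "position")
  inr <- sections_in_range(layout, sid, pos)
  vals <- unlist(lapply(which(inr), function(k)
    stack$sections[[k]]$image[mask]))
  mean(vals)
}
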