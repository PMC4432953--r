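#' @name synthetic-ish
#' @title Synthetic ISH section stacks with ground-truth annotations
#'
#' @description
#' The generator emulates the statistical structure the annotation pipeline
#' assumes, without any atlas data: a stack of sagittal sections per gene, a
#' level-tagged structure ontology, and per-(gene, structure) categorical
#' annotations over the three metrics (pattern, intensity, density).
#'
#' Structures are rendered as nested axis-aligned rectangles (children inside
#' parents, siblings disjoint) so every mask is computable in closed form. In
#' addition to its in-plane rectangle, each structure owns a sagittal range:
#' siblings partition their parent's range, so expression localizes along the
#' medial-lateral axis exactly as the downstream sagittal-interval pooling
#' assumes. Expression is painted as Gaussian blob "cell" texture inside the
#' structure's exclusive region (its rectangle minus its children's), in the
#' sections whose position falls in its sagittal range:
#' * pattern `full`: blobs across the whole exclusive region;
#' * pattern `regional`: blobs confined to a contiguous half of it;
#' * pattern `gradient`: blobs everywhere, amplitude ramping across it;
#' * `undetected`: nothing painted, background noise only.
#' The intensity category sets blob amplitude and the density category sets
#' blob count per unit area, so all three metrics have visible correlates.
NULL

PATTERN_LEVELS <- c("undetected", "full", "regional", "gradient")
GRADE_LEVELS <- c("undetected", "low", "median", "high")

# Painting constants: amplitudes above background per intensity grade,
# blobs per 1000 px^2 per density grade, blob spread in pixels.
INTENSITY_AMPLITUDE <- c(low = 0.15, median = 0.30, high = 0.50)
DENSITY_PER_1000PX <- c(low = 4, median = 9, high = 18)
BLOB_SIGMA <- 2.5

#' Deterministic rectangle-and-slab layout for an ontology
#'
#' Assigns every structure an in-plane rectangle (nested inside its parent's,
#' disjoint from its siblings', axis of subdivision alternating by level) and
#' a sagittal range in `[0, 1]` (siblings partition their parent's range).
#' The layout is a pure function of the ontology and image size, so tests can
#' recompute any mask from scratch.
#'
#' @param ontology An `ish_ontology`.
#' @param image_size `c(height, width)` in pixels.
#' @return data.frame: structure_id, y0, y1, x0, x1 (inclusive pixel bounds),
#'   sag_lo, sag_hi.
#' @export
compute_layout <- function(ontology, image_size) {
  validate_ontology(ontology)
  h <- image_size[1]; w <- image_size[2]
  abort_if(h < 8 || w < 8, "image_size too small to lay out structures")
  rows <- list(root = list(y0 = 1, y1 = h, x0 = 1, x1 = w, sag = c(0, 1)))
  out <- vector("list", nrow(ontology))
  for (lev in sort(unique(ontology$level))) {
    at <- ontology[ontology$level == lev, , drop = FALSE]
    for (p in unique(at$parent_id)) {
      kids <- at$structure_id[at$parent_id == p]
      pr <- rows[[p]]
      # shrink the parent's rectangle so it keeps an exclusive border band
      my0 <- pr$y0 + max(2, round(0.10 * (pr$y1 - pr$y0)))
      my1 <- pr$y1 - max(2, round(0.10 * (pr$y1 - pr$y0)))
      mx0 <- pr$x0 + max(2, round(0.10 * (pr$x1 - pr$x0)))
      mx1 <- pr$x1 - max(2, round(0.10 * (pr$x1 - pr$x0)))
      n <- length(kids)
      for (k in seq_len(n)) {
        if (lev %% 2L == 1L) { # odd level: split into columns
          e <- mx0 + floor((mx1 - mx0 + 1) * c(k - 1, k) / n)
          rect <- list(y0 = my0, y1 = my1, x0 = e[1] + (k > 1), x1 = e[2] - 1 + (k == n))
        } else {             # even level: split into rows
          e <- my0 + floor((my1 - my0 + 1) * c(k - 1, k) / n)
          rect <- list(y0 = e[1] + (k > 1), y1 = e[2] - 1 + (k == n), x0 = mx0, x1 = mx1)
        }
        rect$sag <- pr$sag[1] + diff(pr$sag) * c(k - 1, k) / n
        rows[[kids[k]]] <- rect
        out[[match(kids[k], ontology$structure_id)]] <- data.frame(
          structure_id = kids[k], y0 = rect$y0, y1 = rect$y1,
          x0 = rect$x0, x1 = rect$x1,
          sag_lo = rect$sag[1], sag_hi = rect$sag[2],
          stringsAsFactors = FALSE)
      }
    }
  }
  layout <- do.call(rbind, out)
  layout$height <- h
  layout$width <- w
  layout
}

#' Ground-truth mask of a structure's painted region
#'
#' @param layout Output of [compute_layout()].
#' @param ontology The ontology the layout was computed from.
#' @param structure_id Structure to mask.
#' @param exclusive If TRUE (default) subtract the rectangles of the
#'   structure's children: that is the region where the structure's own
#'   expression is painted.
#' @return Logical matrix `height x width`.
#' @export
structure_mask <- function(layout, ontology, structure_id, exclusive = TRUE) {
  r <- layout[layout$structure_id == structure_id, , drop = FALSE]
  abort_if(nrow(r) != 1, sprintf("unknown structure ID '%s'", structure_id))
  m <- matrix(FALSE, layout$height[1], layout$width[1])
  m[r$y0:r$y1, r$x0:r$x1] <- TRUE
  if (exclusive) {
    kids <- ontology$structure_id[ontology$parent_id == structure_id]
    for (k in kids) {
      kr <- layout[layout$structure_id == k, , drop = FALSE]
      m[kr$y0:kr$y1, kr$x0:kr$x1] <- FALSE
    }
  }
  m
}

#' Sections in which a structure's expression can appear
#'
#' @param layout Output of [compute_layout()].
#' @param structure_id Structure ID.
#' @param positions Numeric sagittal positions in `[0, 1]`.
#' @return Logical vector over `positions`.
#' @export
sections_in_range <- function(layout, structure_id, positions) {
  r <- layout[layout$structure_id == structure_id, , drop = FALSE]
  abort_if(nrow(r) != 1, sprintf("unknown structure ID '%s'", structure_id))
  positions >= r$sag_lo & positions <= r$sag_hi + 1e-12
}

normalize_gene_spec <- function(gene_spec, ontology) {
  abort_if(is.null(names(gene_spec)) || any(!nzchar(names(gene_spec))),
           "gene_spec must be a named list keyed by structure ID")
  unknown <- setdiff(names(gene_spec), ontology$structure_id)
  abort_if(length(unknown) > 0,
           sprintf("unknown structure ID in gene_spec: %s",
                   paste(unknown, collapse = ", ")))
  lapply(gene_spec, function(s) {
    if (is.character(s) && length(s) == 1 && s == "undetected") {
      return(list(pattern = "undetected", intensity = "undetected",
                  density = "undetected"))
    }
    s <- as.list(s)
    abort_if(!all(c("pattern", "intensity", "density") %in% names(s)),
             "a detected gene_spec entry needs pattern, intensity and density")
    abort_if(!(s$pattern %in% PATTERN_LEVELS[-1]) ||
               !(s$intensity %in% GRADE_LEVELS[-1]) ||
               !(s$density %in% GRADE_LEVELS[-1]),
             "invalid category in gene_spec")
    s[c("pattern", "intensity", "density")]
  })
}

# Add gaussian blobs to image `img` at n random positions inside logical
# mask `sub`; amplitude may vary per blob (gradient pattern).
paint_blobs <- function(img, sub, n, amp_at) {
  idx <- which(sub)
  if (length(idx) == 0 || n == 0) return(img)
  h <- nrow(img); w <- ncol(img)
  pick <- idx[sample.int(length(idx), n, replace = TRUE)]
  ys <- ((pick - 1) %% h) + 1
  xs <- ((pick - 1) %/% h) + 1
  r <- ceiling(3 * BLOB_SIGMA)
  off <- seq(-r, r)
  kern <- exp(-(outer(off^2, off^2, "+")) / (2 * BLOB_SIGMA^2))
  for (i in seq_len(n)) {
    yy <- (ys[i] - r):(ys[i] + r)
    xx <- (xs[i] - r):(xs[i] + r)
    ky <- which(yy >= 1 & yy <= h)
    kx <- which(xx >= 1 & xx <= w)
    img[yy[ky], xx[kx]] <- img[yy[ky], xx[kx]] + amp_at(ys[i], xs[i]) * kern[ky, kx]
  }
  img
}

paint_structure <- function(img, layout, ontology, sid, spec) {
  mask <- structure_mask(layout, ontology, sid, exclusive = TRUE)
  r <- layout[layout$structure_id == sid, ]
  if (spec$pattern == "regional") {
    # contiguous half of the exclusive region, along the wider rectangle axis
    if ((r$x1 - r$x0) >= (r$y1 - r$y0)) {
      mask[, seq_len(ncol(mask)) > floor((r$x0 + r$x1) / 2)] <- FALSE
    } else {
      mask[seq_len(nrow(mask)) > floor((r$y0 + r$y1) / 2), ] <- FALSE
    }
  }
  amp <- INTENSITY_AMPLITUDE[[spec$intensity]]
  n_blobs <- max(1L, round(DENSITY_PER_1000PX[[spec$density]] * sum(mask) / 1000))
  amp_at <- if (spec$pattern == "gradient") {
    # amplitude ramps from 15% to 100% across the rectangle's width
    function(y, x) amp * (0.15 + 0.85 * (x - r$x0) / max(1, r$x1 - r$x0))
  } else {
    function(y, x) amp
  }
  paint_blobs(img, mask, n_blobs, amp_at)
}

#' Generate one gene's synthetic section stack and its ground-truth annotations
#'
#' @param gene_spec Named list keyed by structure ID; each element is either
#'   the string `"undetected"` or a list with `pattern`, `intensity`,
#'   `density` categories. Structures absent from the spec get no annotation
#'   rows and no paint.
#' @param ontology An `ish_ontology`.
#' @param n_sections Number of sagittal sections (default 17; real experiments
#'   image 15-20 sections per gene).
#' @param image_size `c(height, width)` pixels.
#' @param seed Integer seed; the stack is a deterministic function of it.
#' @param gene_id Identifier stored in the stack and annotation rows.
#' @param noise_sd Additive Gaussian pixel noise, on the `[0, 1]` intensity
#'   scale.
#' @param background Mean background intensity.
#' @return List of class `ish_stack_sim`: `stack` (class `ish_stack`: gene_id,
#'   stage, sections = list of `list(image, position)`), `annotations`
#'   (data.frame gene_id/structure_id/metric/category), and `layout` for
#'   ground-truth mask recomputation.
#' @export
generate_stack <- function(gene_spec, ontology, n_sections = 17,
                           image_size = c(270, 360), seed = 1,
                           gene_id = "gene1", noise_sd = 0.02,
                           background = 0.12, stage = "S1") {
  abort_if(n_sections < 1, "n_sections must be >= 1")
  abort_if(any(image_size < 1), "image_size must be positive")
  spec <- normalize_gene_spec(gene_spec, ontology)
  layout <- compute_layout(ontology, image_size)
  positions <- if (n_sections == 1) 0.5 else (seq_len(n_sections) - 1) / (n_sections - 1)

  sections <- with_seed(seed, {
    lapply(seq_len(n_sections), function(k) {
      img <- matrix(background + stats::rnorm(prod(image_size), sd = noise_sd),
                    image_size[1], image_size[2])
      for (sid in names(spec)) {
        s <- spec[[sid]]
        if (s$pattern == "undetected") next
        if (!sections_in_range(layout, sid, positions[k])) next
        img <- paint_structure(img, layout, ontology, sid, s)
      }
      list(image = pmin(pmax(img, 0), 1), position = positions[k])
    })
  })

  ann <- do.call(rbind, lapply(names(spec), function(sid) {
    s <- spec[[sid]]
    data.frame(gene_id = gene_id, structure_id = sid,
               metric = c("pattern", "intensity", "density"),
               category = c(s$pattern, s$intensity, s$density),
               stringsAsFactors = FALSE)
  }))

  stack <- structure(list(gene_id = gene_id, stage = stage, sections = sections),
                     class = "ish_stack")
  structure(list(stack = stack, annotations = ann, layout = layout),
            class = "ish_stack_sim")
}

#' @export
print.ish_stack <- function(x, ...) {
  d <- dim(x$sections[[1]]$image)
  cat(sprintf("ISH section stack '%s' (stage %s): %d sections of %dx%d\n",
              x$gene_id, x$stage, length(x$sections), d[1], d[2]))
  invisible(x)
}

#' Simulate a full multi-gene dataset in memory
#'
#' Draws, for every gene and every structure, whether expression is detected
#' (independently, with probability `1 - undetected_fraction`, reproducing the
#' strong dominance of the undetected category seen in curated atlases) and,
#' if detected, uniform pattern/intensity/density categories. Detected
#' structures are painted into every section within their sagittal range.
#'
#' @param n_genes Number of genes (>= 2).
#' @param undetected_fraction Probability a (gene, structure) pair is
#'   undetected.
#' @param ontology An `ish_ontology`; default a depth-2 tree with 3 + 6
#'   structures.
#' @param stage_label Developmental stage tag stored with each stack.
#' @param n_sections,image_size,noise_sd,background Passed to
#'   [generate_stack()].
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @return List of class `ish_dataset`: `stacks` (named list of `ish_stack`),
#'   `ontology`, `annotations`, `layout`, `stage`, `config`.
#' @export
simulate_dataset <- function(n_genes, undetected_fraction = 0.8,
                             ontology = generate_ontology(2, c(3, 2)),
                             stage_label = "S1", n_sections = 17,
                             image_size = c(270, 360), noise_sd = 0.02,
                             background = 0.12, seed = 1) {
  abort_if(n_genes < 2, "n_genes must be >= 2")
  abort_if(undetected_fraction <= 0 && undetected_fraction != 0,
           "undetected_fraction must be in [0, 1]")
  abort_if(undetected_fraction < 0 || undetected_fraction > 1,
           "undetected_fraction must be in [0, 1]")
  validate_ontology(ontology)
  gene_ids <- sprintf("gene%03d", seq_len(n_genes))

  specs <- with_seed(derive_seed(seed, "labels"), {
    lapply(gene_ids, function(g) {
      sp <- lapply(ontology$structure_id, function(sid) {
        if (stats::runif(1) < undetected_fraction) {
          "undetected"
        } else {
          list(pattern = sample(PATTERN_LEVELS[-1], 1),
               intensity = sample(GRADE_LEVELS[-1], 1),
               density = sample(GRADE_LEVELS[-1], 1))
        }
      })
      names(sp) <- ontology$structure_id
      sp
    })
  })

  sims <- lapply(seq_along(gene_ids), function(i) {
    generate_stack(specs[[i]], ontology, n_sections = n_sections,
                   image_size = image_size,
                   seed = derive_seed(seed, paste0("stack_", gene_ids[i])),
                   gene_id = gene_ids[i], noise_sd = noise_sd,
                   background = background, stage = stage_label)
  })
  stacks <- lapply(sims, function(s) s$stack)
  names(stacks) <- gene_ids
  annotations <- do.call(rbind, lapply(sims, function(s) s$annotations))
  rownames(annotations) <- NULL

  structure(list(stacks = stacks, ontology = ontology,
                 annotations = annotations, layout = sims[[1]]$layout,
                 stage = stage_label,
                 config = list(n_genes = n_genes,
                               undetected_fraction = undetected_fraction,
                               n_sections = n_sections,
                               image_size = image_size, noise_sd = noise_sd,
                               background = background, seed = seed)),
            class = "ish_dataset")
}

#' @export
print.ish_dataset <- function(x, ...) {
  cat(sprintf("Synthetic ISH dataset: %d genes x %d sections (stage %s), %d structures\n",
              length(x$stacks), length(x$stacks[[1]]$sections), x$stage,
              nrow(x$ontology)))
  invisible(x)
}

#' Generate a synthetic dataset and write it to disk
#'
#' On-disk layout: `<out>/<gene_id>/section_<k>.png` (8-bit grayscale),
#' `ontology.json`, `annotations.csv`
#' (header `gene_id,structure_id,metric,category`) and `manifest.csv`
#' (`gene_id,section,position,path`).
#'
#' @inheritParams simulate_dataset
#' @param out_dir Output directory (created if needed).
#' @param ... Passed on to [simulate_dataset()].
#' @return The in-memory `ish_dataset`, invisibly.
#' @export
generate_dataset <- function(out_dir, n_genes, undetected_fraction = 0.8,
                             stage_label = "S1", seed = 1, ...) {
  ds <- simulate_dataset(n_genes, undetected_fraction,
                         stage_label = stage_label, seed = seed, ...)
  write_dataset(ds, out_dir)
  invisible(ds)
}
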