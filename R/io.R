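#' Default pipeline configuration
#'
#' One source of truth for the pipeline constants. Defaults with an
#' established published value keep it: downsample factor 4, K = 500 visual
#' words, descriptor pool 100,000, seven sagittal intervals, 231x231 network
#' input, train fraction 2/3, 5,000 split attempts per threshold. The dense
#' descriptor scales (4, 8, 16 px cells) and grid step (4 px) are
#' conventional dense-SIFT settings, configurable here.
#'
#' @param ... Overrides, named as in the returned list (nested lists are
#'   merged shallowly).
#' @return Nested list of class `ish_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    stage = "S1",
    representation = "bow",
    bow = list(scales = c(4L, 8L, 16L), step = 4L, downsample = 4L,
               K = 500L, pool_size = 100000L, restarts = 5L,
               iter_max = 300L, n_intervals = 7L, normalize = "none"),
    cnn = list(tap = 12L, pooling = "max", weights_source = "random",
               input_size = 231L),
    split = list(train_fraction = 2 / 3, max_attempts = 5000L,
                 threshold_start = 1 / 3, threshold_decay = 0.8,
                 threshold_floor = 0.01),
    lambda = 1,
    seed = 1L,
    synth = list(n_genes = 60L, undetected_fraction = 0.8, n_sections = 17L,
                 image_size = c(270L, 360L), noise_sd = 0.02,
                 background = 0.12, depth = 2L, branching = c(3L, 2L))
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = c("ish_config", "list"))
}

#' Write a synthetic dataset to disk
#'
#' Layout: `<dir>/<gene_id>/section_<k>.png` (8-bit grayscale),
#' `ontology.json`, `annotations.csv`, `manifest.csv`.
#'
#' @param dataset An `ish_dataset`.
#' @param dir Output directory (created recursively).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  abort_if(!inherits(dataset, "ish_dataset"), "not an ish_dataset")
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  abort_if(!ok, sprintf("cannot create output directory '%s'", dir))
  jsonlite::write_json(
    list(stage = dataset$stage,
         nodes = dataset$ontology[, c("structure_id", "parent_id", "level")]),
    file.path(dir, "ontology.json"), auto_unbox = TRUE, digits = NA)
  data.table::fwrite(dataset$annotations, file.path(dir, "annotations.csv"))
  manifest <- list()
  for (g in names(dataset$stacks)) {
    gd <- file.path(dir, g)
    dir.create(gd, showWarnings = FALSE)
    st <- dataset$stacks[[g]]
    for (k in seq_along(st$sections)) {
      rel <- file.path(g, sprintf("section_%02d.png", k))
      png::writePNG(st$sections[[k]]$image, file.path(dir, rel))
      manifest[[length(manifest) + 1]] <- data.frame(
        gene_id = g, section = k,
        position = st$sections[[k]]$position, path = rel,
        stringsAsFactors = FALSE)
    }
  }
  data.table::fwrite(do.call(rbind, manifest), file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' Read a dataset from disk
#'
#' Reads the layout written by [write_dataset()] / [generate_dataset()].
#' Sections are ordered by ascending position; gene IDs are cross-checked
#' across manifest, annotations and images. A gene annotated but lacking
#' images is dropped with a warning; an annotation naming an unknown
#' structure is a hard error.
#'
#' @param dir Dataset root directory.
#' @return List of class `ish_dataset` (without the synthetic `layout`).
#' @export
read_dataset <- function(dir) {
  for (f in c("ontology.json", "annotations.csv", "manifest.csv")) {
    abort_if(!file.exists(file.path(dir, f)),
             sprintf("missing dataset file: %s", file.path(dir, f)))
  }
  oj <- jsonlite::fromJSON(file.path(dir, "ontology.json"))
  ontology <- as.data.frame(oj$nodes, stringsAsFactors = FALSE)
  class(ontology) <- c("ish_ontology", "data.frame")
  validate_ontology(ontology)
  annotations <- as.data.frame(data.table::fread(
    file.path(dir, "annotations.csv"), colClasses = "character"))
  unknown <- setdiff(annotations$structure_id, ontology$structure_id)
  abort_if(length(unknown) > 0,
           sprintf("annotations reference unknown structure '%s'", unknown[1]))
  manifest <- as.data.frame(data.table::fread(file.path(dir, "manifest.csv")))

  stacks <- lapply(split(manifest, manifest$gene_id), function(m) {
    m <- m[order(m$position), , drop = FALSE]
    sections <- lapply(seq_len(nrow(m)), function(i) {
      p <- file.path(dir, m$path[i])
      abort_if(!file.exists(p), sprintf("manifest references missing image: %s", p))
      img <- png::readPNG(p)
      if (length(dim(img)) == 3) img <- rowMeans(img, dims = 2)
      list(image = img, position = m$position[i])
    })
    structure(list(gene_id = m$gene_id[1], stage = oj$stage %||% "unknown",
                   sections = sections), class = "ish_stack")
  })
  no_images <- setdiff(unique(annotations$gene_id), names(stacks))
  if (length(no_images) > 0) {
    warning("dropping annotated genes with no images: ",
            paste(no_images, collapse = ", "))
    annotations <- annotations[!annotations$gene_id %in% no_images, ,
                               drop = FALSE]
  }
  structure(list(stacks = stacks, ontology = ontology,
                 annotations = annotations, stage = oj$stage %||% "unknown"),
            class = "ish_dataset")
}

#' Write / read a feature matrix
#'
#' Values go to `<path>.tsv` (gene per row, full double precision) with a
#' JSON sidecar `<path>.json` recording the representation tag, dimensions
#' and the extraction configuration, so a round trip is lossless and a file
#' of the wrong representation is refused on read.
#'
#' @param features An `ish_features` matrix.
#' @param path Path prefix (no extension).
#' @return `write_feature_matrix`: the prefix, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  abort_if(!inherits(features, "ish_features"), "not an ish_features matrix")
  dt <- data.table::data.table(gene_id = rownames(features))
  dt <- cbind(dt, data.table::as.data.table(unclass(features)))
  data.table::fwrite(dt, paste0(path, ".tsv"), sep = "\t")
  jsonlite::write_json(list(representation = attr(features, "representation"),
                            n_genes = nrow(features),
                            n_features = ncol(features),
                            config = attr(features, "config")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @param representation When non-NULL, the stored representation tag must
#'   match or the read fails.
#' @return `read_feature_matrix`: the `ish_features` matrix.
#' @export
read_feature_matrix <- function(path, representation = NULL) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  abort_if(!is.null(representation) &&
             !identical(meta$representation, representation),
           sprintf("feature file holds representation '%s' but '%s' was requested",
                   meta$representation, representation))
  dt <- data.table::fread(paste0(path, ".tsv"), sep = "\t")
  X <- as.matrix(dt[, -1])
  dimnames(X) <- list(dt[[1]], NULL)
  feature_matrix(X, representation = meta$representation,
                 config = meta$config)
}

#' Write an evaluation report as CSV plus a JSON summary
#'
#' @param report An `ish_eval_report` or `ish_eval_set`.
#' @param path Path prefix; writes `<path>.csv` and `<path>.json`.
#' @export
write_report <- function(report, path) {
  if (inherits(report, "ish_eval_set")) {
    results <- do.call(rbind, lapply(report$reports, function(r) r$results))
    summary <- report$summary
    splits <- lapply(report$reports, function(r)
      r$split[c("threshold", "attempts", "excluded", "relaxations")])
  } else {
    results <- report$results
    summary <- data.frame(level = report$level,
                          n_structures = nrow(report$results),
                          overall_auc = report$overall_auc)
    splits <- list(report$split[c("threshold", "attempts", "excluded",
                                  "relaxations")])
  }
  rownames(results) <- NULL
  rownames(summary) <- NULL
  data.table::fwrite(results, paste0(path, ".csv"))
  jsonlite::write_json(list(summary = summary, splits = splits),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Persist codebooks as delimited text with a JSON sidecar
#'
#' @param codebooks Output of [build_codebooks()].
#' @param path Path prefix; writes `<path>_scale<k>.tsv` plus `<path>.json`.
#' @export
write_codebooks <- function(codebooks, path) {
  meta <- lapply(codebooks, function(cb) {
    list(scale = cb$scale, K = cb$K,
         within_cluster_distance = cb$within_cluster_distance,
         restarts = cb$restarts, seed = cb$seed)
  })
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  for (cb in codebooks) {
    data.table::fwrite(data.table::as.data.table(cb$centroids),
                       sprintf("%s_scale%s.tsv", path, cb$scale), sep = "\t")
  }
  invisible(path)
}

#' @rdname write_codebooks
#' @export
read_codebooks <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"), simplifyVector = FALSE)
  cbs <- lapply(meta, function(m) {
    M <- as.matrix(data.table::fread(
      sprintf("%s_scale%s.tsv", path, m$scale), sep = "\t"))
    dimnames(M) <- NULL
    structure(list(centroids = M, K = m$K, scale = m$scale,
                   within_cluster_distance = m$within_cluster_distance,
                   restarts = m$restarts, seed = m$seed),
              class = "ish_codebook")
  })
  names(cbs) <- paste0("scale", vapply(meta, `[[`, numeric(1), "scale"))
  attr(cbs, "scales") <- as.integer(vapply(meta, `[[`, numeric(1), "scale"))
  cbs
}
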