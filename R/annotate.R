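#' Binarize an annotation table for one metric
#'
#' The multi-category annotation task is reformulated as binary
#' detected-vs-undetected: the undetected category maps to -1 and every other
#' category to +1. Genes with no record for a structure are absent from that
#' structure's label map.
#'
#' @param table Annotation data.frame with columns gene_id, structure_id,
#'   metric, category.
#' @param metric One of "pattern", "intensity", "density".
#' @return Named list (by structure) of named -1/+1 vectors (by gene).
#' @export
binarize <- function(table, metric = c("pattern", "intensity", "density")) {
  metric <- match.arg(metric)
  abort_if(!metric %in% table$metric,
           sprintf("metric '%s' not present in the annotation table", metric))
  t0 <- table[table$metric == metric, , drop = FALSE]
  abort_if(anyDuplicated(t0[, c("gene_id", "structure_id")]) > 0,
           "duplicate (gene, structure) records for one metric")
  maps <- split(t0, t0$structure_id)
  lapply(maps, function(d) {
    stats::setNames(ifelse(d$category == "undetected", -1, 1), d$gene_id)
  })
}

label_ratio <- function(y) {
  n1 <- sum(y == 1); n0 <- sum(y == -1)
  if (max(n1, n0) == 0) return(0)
  min(n1, n0) / max(n1, n0)
}

#' Balance-maximizing train/test split
#'
#' Genes are randomly split (2/3 train by default); the split is accepted if
#' in every eligible structure the minority/majority class ratio, in both the
#' training and the test part, reaches the current threshold. After
#' `max_attempts` failed draws the threshold is relaxed by `threshold_decay`
#' and the sampling repeats, so the threshold actually achieved can differ
#' between datasets. Structures carrying a single class overall cannot be
#' balanced and are excluded from the ratio check and flagged.
#'
#' @param label_maps Output of [binarize()], restricted to one ontology level.
#' @param train_fraction Fraction of genes in the training set (default 2/3).
#' @param max_attempts Draws per threshold before relaxing (default 5000).
#' @param threshold_start Initial minority/majority ratio demanded
#'   (default 1/3).
#' @param threshold_decay Multiplicative relaxation per exhausted round
#'   (default 0.8).
#' @param threshold_floor Lowest threshold tried; if even the floor is
#'   unsatisfiable the best draw seen at the floor is returned with a warning.
#' @param seed Integer seed; the split is deterministic given it.
#' @return List: `train`, `test` (gene IDs), `threshold` (achieved),
#'   `attempts` (total draws), `excluded` (flagged single-class structures),
#'   `relaxations` (number of threshold reductions).
#' @export
balanced_split <- function(label_maps, train_fraction = 2 / 3,
                           max_attempts = 5000L, threshold_start = 1 / 3,
                           threshold_decay = 0.8, threshold_floor = 0.01,
                           seed = 1) {
  abort_if(train_fraction <= 0 || train_fraction >= 1,
           "train_fraction must be in (0, 1)")
  abort_if(max_attempts < 1, "max_attempts must be >= 1")
  genes <- sort(unique(unlist(lapply(label_maps, names))))
  abort_if(length(genes) < 2, "need at least 2 genes to split")
  excluded <- names(label_maps)[vapply(label_maps, function(y)
    length(unique(y)) < 2, logical(1))]
  eligible <- setdiff(names(label_maps), excluded)
  n_train <- max(1L, min(length(genes) - 1L,
                         round(train_fraction * length(genes))))

  min_ratio <- function(train_genes) {
    if (length(eligible) == 0) return(Inf)
    test_genes <- setdiff(genes, train_genes)
    min(vapply(label_maps[eligible], function(y) {
      min(label_ratio(y[names(y) %in% train_genes]),
          label_ratio(y[names(y) %in% test_genes]))
    }, numeric(1)))
  }

  with_seed(derive_seed(seed, "split"), {
    threshold <- threshold_start
    attempts <- 0L
    relaxations <- 0L
    best <- list(ratio = -1, train = NULL)
    repeat {
      for (a in seq_len(max_attempts)) {
        attempts <- attempts + 1L
        train_genes <- sort(sample(genes, n_train))
        r <- min_ratio(train_genes)
        if (r > best$ratio) best <- list(ratio = r, train = train_genes)
        if (r >= threshold) {
          return(list(train = train_genes,
                      test = setdiff(genes, train_genes),
                      threshold = threshold, attempts = attempts,
                      excluded = excluded, relaxations = relaxations))
        }
      }
      if (threshold <= threshold_floor) {
        warning("no split met the floor threshold; returning the most ",
                "balanced draw (min ratio ", signif(best$ratio, 3), ")")
        return(list(train = best$train, test = setdiff(genes, best$train),
                    threshold = best$ratio, attempts = attempts,
                    excluded = excluded, relaxations = relaxations))
      }
      threshold <- max(threshold_floor, threshold * threshold_decay)
      relaxations <- relaxations + 1L
    }
  })
}

#' Train and evaluate per-structure classifiers at one ontology level
#'
#' For every structure at the level with both classes present (in the full
#' data and in both split parts), an L2-regularized logistic classifier is
#' trained on the training genes' features and scored on the test genes; the
#' per-structure AUC and the unweighted mean across structures (the per-level
#' overall AUC) are reported. Alignment is by gene ID, never by row order.
#'
#' @param features An `ish_features` matrix (genes x features).
#' @param table Annotation data.frame.
#' @param ontology An `ish_ontology`.
#' @param level Ontology level to evaluate.
#' @param metric Annotation metric (default "pattern"; the binary
#'   reformulation makes the three metrics the same set of tasks on
#'   consistent tables).
#' @param lambda Regularization parameter (default 1).
#' @param split Optional precomputed [balanced_split()] result; when NULL one
#'   is drawn with the remaining arguments.
#' @param train_fraction,max_attempts,threshold_start,threshold_decay,threshold_floor,seed
#'   Passed to [balanced_split()].
#' @return Object of class `ish_eval_report`: `results` (data.frame
#'   structure_id, level, n_train, n_test, n_pos_test, auc), `overall_auc`
#'   (unweighted mean), `skipped` (structures without both classes in both
#'   parts), `split`, `level`, `metric`, `representation`.
#' @export
annotate_level <- function(features, table, ontology, level,
                           metric = "pattern", lambda = 1, split = NULL,
                           train_fraction = 2 / 3, max_attempts = 5000L,
                           threshold_start = 1 / 3, threshold_decay = 0.8,
                           threshold_floor = 0.01, seed = 1) {
  validate_ontology(ontology)
  abort_if(!level %in% ontology$level, sprintf("no structures at level %s",
                                               as.character(level)))
  sids <- structures_at_level(ontology, level)
  maps <- binarize(table, metric)
  maps <- maps[names(maps) %in% sids]
  maps <- lapply(maps, function(y) y[names(y) %in% rownames(features)])
  maps <- maps[vapply(maps, length, integer(1)) > 0]
  if (length(maps) == 0) {
    warning("no eligible structures at level ", level)
    return(empty_report(level, metric, features))
  }
  if (is.null(split)) {
    split <- balanced_split(maps, train_fraction = train_fraction,
                            max_attempts = max_attempts,
                            threshold_start = threshold_start,
                            threshold_decay = threshold_decay,
                            threshold_floor = threshold_floor, seed = seed)
  }

  rows <- list()
  skipped <- character(0)
  for (sid in names(maps)) {
    y <- maps[[sid]]
    ytr <- y[names(y) %in% split$train]
    yte <- y[names(y) %in% split$test]
    if (length(unique(ytr)) < 2 || length(unique(yte)) < 2) {
      skipped <- c(skipped, sid)
      next
    }
    fit <- train_logistic(features[names(ytr), , drop = FALSE], ytr,
                          lambda = lambda)
    sc <- score_genes(fit, features[names(yte), , drop = FALSE])
    rows[[sid]] <- data.frame(structure_id = sid, level = level,
                              n_train = length(ytr), n_test = length(yte),
                              n_pos_test = sum(yte == 1),
                              auc = auc_score(sc, yte),
                              stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    warning("no structure at level ", level,
            " had both classes in both split parts")
    rep <- empty_report(level, metric, features)
    rep$skipped <- skipped
    rep$split <- split
    return(rep)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(results = results,
                 overall_auc = mean(results$auc),
                 skipped = skipped, split = split, level = level,
                 metric = metric,
                 representation = attr(features, "representation")),
            class = "ish_eval_report")
}

empty_report <- function(level, metric, features) {
  structure(list(results = data.frame(structure_id = character(0),
                                      level = integer(0), n_train = integer(0),
                                      n_test = integer(0),
                                      n_pos_test = integer(0),
                                      auc = numeric(0)),
                 overall_auc = NA_real_, skipped = character(0), split = NULL,
                 level = level, metric = metric,
                 representation = attr(features, "representation")),
            class = "ish_eval_report")
}

#' @export
print.ish_eval_report <- function(x, ...) {
  cat(sprintf("Annotation evaluation [%s], level %s (%s metric):\n",
              x$representation %||% "?", as.character(x$level), x$metric))
  cat(sprintf("  %d structures, overall AUC = %s\n", nrow(x$results),
              ifelse(is.na(x$overall_auc), "NA",
                     sprintf("%.3f", x$overall_auc))))
  if (length(x$skipped) > 0) {
    cat("  skipped (single class in a split part):",
        paste(x$skipped, collapse = ", "), "\n")
  }
  if (!is.null(x$split)) {
    cat(sprintf("  split: %d train / %d test, achieved balance threshold %.3g\n",
                length(x$split$train), length(x$split$test),
                x$split$threshold))
    if (length(x$split$excluded) > 0) {
      cat("  excluded single-class structures:",
          paste(x$split$excluded, collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' Evaluate every ontology level
#'
#' @inheritParams annotate_level
#' @param levels Levels to run (default all levels in the ontology).
#' @return List of class `ish_eval_set`: per-level `ish_eval_report`s plus a
#'   `summary` data.frame (level, n_structures, overall_auc).
#' @export
annotate_all_levels <- function(features, table, ontology, levels = NULL,
                                metric = "pattern", lambda = 1, seed = 1,
                                ...) {
  levels <- levels %||% sort(unique(ontology$level))
  reports <- lapply(levels, function(lv) {
    annotate_level(features, table, ontology, lv, metric = metric,
                   lambda = lambda, seed = derive_seed(seed, paste0("lv", lv)),
                   ...)
  })
  names(reports) <- paste0("level", levels)
  summary <- data.frame(level = levels,
                        n_structures = vapply(reports, function(r)
                          nrow(r$results), integer(1)),
                        overall_auc = vapply(reports, function(r)
                          r$overall_auc, numeric(1)))
  structure(list(reports = reports, summary = summary),
            class = "ish_eval_set")
}

#' @export
print.ish_eval_set <- function(x, ...) {
  cat("Per-level annotation performance:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
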