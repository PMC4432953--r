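#' Generate a hierarchical brain-structure ontology
#'
#' Builds a synthetic level-tagged structure hierarchy analogous to a
#' developmental neuroanatomy reference ontology: a tree whose nodes carry a
#' level from 1 (coarsest) down to at most 10 (finest), where every node's
#' parent sits exactly one level above it.
#'
#' @param depth Number of levels (integer in 1..10).
#' @param branching Integer vector of length `depth`; `branching[l]` children
#'   are attached under each node of level `l - 1` (level-1 nodes hang off the
#'   implicit root). Per-level node counts are therefore the cumulative
#'   products of `branching`.
#' @param seed Optional integer; the construction is deterministic, the seed is
#'   accepted for interface symmetry with the other generators.
#' @return An object of class `ish_ontology`: a data.frame with columns
#'   `structure_id`, `parent_id` (`"root"` for level-1 nodes) and `level`.
#' @examples
#' ont <- generate_ontology(depth = 2, branching = c(3, 2))
#' table(ont$level)
#' @export
generate_ontology <- function(depth, branching, seed = NULL) {
  abort_if(length(depth) != 1L || !is.finite(depth) || depth < 1 || depth > 10,
           "`depth` must be a single integer in [1, 10]")
  depth <- as.integer(depth)
  abort_if(length(branching) != depth,
           sprintf("`branching` must have length %d (= depth), got %d",
                   depth, length(branching)))
  abort_if(any(!is.finite(branching)) || any(branching < 1),
           "`branching` factors must all be positive integers")
  branching <- as.integer(branching)

  nodes <- list()
  parents <- "root"
  for (lev in seq_len(depth)) {
    ids <- character(0)
    par <- character(0)
    for (p in parents) {
      prefix <- if (identical(p, "root")) "S" else paste0(p, ".")
      kid_ids <- paste0(prefix, seq_len(branching[lev]))
      ids <- c(ids, kid_ids)
      par <- c(par, rep(p, branching[lev]))
    }
    nodes[[lev]] <- data.frame(structure_id = ids, parent_id = par,
                               level = lev, stringsAsFactors = FALSE)
    parents <- ids
  }
  out <- do.call(rbind, nodes)
  rownames(out) <- NULL
  class(out) <- c("ish_ontology", "data.frame")
  out
}

#' Build an ontology with prescribed per-level structure counts
#'
#' Unlike [generate_ontology()], which grows the tree by uniform per-level
#' branching, this constructor takes the exact number of structures wanted at
#' each level (counts need not be multiples of the level above) and assigns
#' parents round-robin among the previous level's nodes, preserving the
#' parent-level invariant.
#'
#' @param counts Integer vector; `counts[l]` structures at level `l`.
#' @return An `ish_ontology` data.frame.
#' @examples
#' # the classifier-per-structure layout used for a full 10-level atlas
#' ont <- ontology_from_counts(c(3, 6, 19, 14, 81, 46, 123, 40, 307, 432))
#' n_annotation_tasks(ont)
#' @export
ontology_from_counts <- function(counts) {
  abort_if(length(counts) < 1 || length(counts) > 10,
           "`counts` must have between 1 and 10 levels")
  abort_if(any(!is.finite(counts)) || any(counts < 1),
           "per-level counts must all be positive")
  counts <- as.integer(counts)
  nodes <- list()
  parents <- "root"
  for (lev in seq_along(counts)) {
    ids <- sprintf("L%d_%d", lev, seq_len(counts[lev]))
    par <- rep(parents, length.out = counts[lev])
    nodes[[lev]] <- data.frame(structure_id = ids, parent_id = par,
                               level = lev, stringsAsFactors = FALSE)
    parents <- ids
  }
  out <- do.call(rbind, nodes)
  rownames(out) <- NULL
  class(out) <- c("ish_ontology", "data.frame")
  out
}

#' Number of per-structure annotation tasks an ontology induces
#'
#' One binary (detected vs. undetected) classifier is trained per structure,
#' so the task count is simply the number of structures across all levels.
#'
#' @param ontology An `ish_ontology`.
#' @return Integer count.
#' @export
n_annotation_tasks <- function(ontology) {
  validate_ontology(ontology)
  nrow(ontology)
}

#' @export
print.ish_ontology <- function(x, ...) {
  cat(sprintf("Brain-structure ontology: %d structures over levels %d..%d\n",
              nrow(x), min(x$level), max(x$level)))
  print(table(level = x$level))
  invisible(x)
}

#' Validate an ontology table
#'
#' Checks the column contract (structure_id, parent_id, level), uniqueness of
#' IDs, contiguous levels starting at 1, and that every node's parent sits
#' exactly one level above (level-1 nodes have parent `"root"`). Errors name
#' the offending node.
#'
#' @param ontology An `ish_ontology` data.frame.
#' @return The ontology, invisibly.
#' @export
validate_ontology <- function(ontology) {
  abort_if(!is.data.frame(ontology) ||
             !all(c("structure_id", "parent_id", "level") %in% names(ontology)),
           "ontology must have columns structure_id, parent_id, level")
  abort_if(anyDuplicated(ontology$structure_id) > 0,
           "ontology structure IDs must be unique")
  lev <- sort(unique(ontology$level))
  abort_if(!identical(lev, seq_len(max(lev))),
           "ontology levels must be contiguous from 1")
  idx <- match(ontology$parent_id, ontology$structure_id)
  bad <- which(!(ontology$parent_id == "root" & ontology$level == 1L) &
                 (is.na(idx) | ontology$level[idx] != ontology$level - 1L))
  abort_if(length(bad) > 0,
           sprintf("malformed ontology: node '%s' has invalid parent '%s'",
                   ontology$structure_id[bad[1]], ontology$parent_id[bad[1]]))
  invisible(ontology)
}

#' Structure IDs at one ontology level
#'
#' @param ontology An `ish_ontology` data.frame.
#' @param level Level number.
#' @return Character vector of structure IDs.
#' @export
structures_at_level <- function(ontology, level) {
  ontology$structure_id[ontology$level == level]
}
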