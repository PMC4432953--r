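# helper: long annotation table for given label maps (one metric)
table_from_maps <- function(maps, metric = "pattern") {
  do.call(rbind, lapply(names(maps), function(sid) {
    y <- maps[[sid]]
    data.frame(gene_id = names(y), structure_id = sid, metric = metric,
               category = ifelse(y == 1, "regional", "undetected"),
               stringsAsFactors = FALSE)
  }))
}

test_that("binarize maps undetected to -1 and every other category to +1", {
  tab <- data.frame(
    gene_id = c("g1", "g2", "g3", "g1", "g2"),
    structure_id = c("s1", "s1", "s1", "s2", "s2"),
    metric = "pattern",
    category = c("undetected", "full", "gradient", "regional", "undetected"),
    stringsAsFactors = FALSE)
  maps <- binarize(tab, "pattern")
  expect_setequal(names(maps), c("s1", "s2"))
  expect_equal(maps$s1, c(g1 = -1, g2 = 1, g3 = 1))
  expect_equal(maps$s2, c(g1 = 1, g2 = -1))
  # g3 has no record for s2 and must be absent, not imputed
  expect_false("g3" %in% names(maps$s2))
})

test_that("binarize filters by metric and rejects malformed tables", {
  tab <- rbind(
    data.frame(gene_id = "g1", structure_id = "s1", metric = "pattern",
               category = "full"),
    data.frame(gene_id = "g1", structure_id = "s1", metric = "intensity",
               category = "undetected"))
  expect_equal(binarize(tab, "pattern")$s1, c(g1 = 1))
  expect_equal(binarize(tab, "intensity")$s1, c(g1 = -1))
  expect_error(binarize(tab, "density"), "not present")
  dup <- rbind(tab[1, ], tab[1, ])
  expect_error(binarize(dup, "pattern"), "duplicate")
})

test_that("the three metrics reduce to identical binary tasks on a consistent table", {
  # one gene set; detection status shared, category vocabulary differs
  genes <- paste0("g", 1:8)
  det <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  tab <- do.call(rbind, lapply(
    c(pattern = "regional", intensity = "high", density = "low"),
    function(cat) data.frame(gene_id = genes, structure_id = "s1",
                             metric = NA, category = ifelse(det, cat,
                                                            "undetected"))))
  tab$metric <- rep(c("pattern", "intensity", "density"), each = 8)
  expect_equal(binarize(tab, "pattern"), binarize(tab, "intensity"))
  expect_equal(binarize(tab, "pattern"), binarize(tab, "density"))
})

test_that("a balanced dataset splits at the initial threshold, deterministically", {
  genes <- sprintf("g%02d", 1:12)
  maps <- list(s1 = stats::setNames(rep(c(1, -1), 6), genes),
               s2 = stats::setNames(rep(c(1, 1, -1), 4), genes))
  sp <- balanced_split(maps, seed = 11)
  expect_equal(sp$threshold, 1 / 3)
  expect_equal(sp$relaxations, 0L)
  expect_length(sp$train, 8)          # round(2/3 * 12)
  expect_length(sp$test, 4)
  expect_setequal(c(sp$train, sp$test), genes)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_equal(sp$excluded, character(0))
  # both parts of both structures really meet the achieved threshold
  for (y in maps) {
    expect_gte(ishannotate:::label_ratio(y[sp$train]), sp$threshold)
    expect_gte(ishannotate:::label_ratio(y[sp$test]), sp$threshold)
  }
  expect_identical(sp, balanced_split(maps, seed = 11))
  sp2 <- balanced_split(maps, seed = 12)
  expect_false(identical(sp$train, sp2$train))
})

test_that("single-class structures are excluded from the check and flagged", {
  genes <- paste0("g", 1:9)
  maps <- list(allpos = stats::setNames(rep(1, 9), genes),
               mixed = stats::setNames(rep(c(1, -1, -1), 3), genes))
  sp <- balanced_split(maps, seed = 3)
  expect_equal(sp$excluded, "allpos")
  expect_equal(sp$relaxations, 0L)
})

test_that("an unreachable threshold is relaxed by the documented schedule", {
  # 2 positives among 9 genes: the best achievable min ratio over both parts
  # is 1/5 = 0.2 (one positive on each side), so 1/3, 1/3*0.8 and 1/3*0.8^2
  # all fail and the third relaxation (1/3 * 0.8^3 ~ 0.171) succeeds.
  genes <- paste0("g", 1:9)
  maps <- list(rare = stats::setNames(c(1, 1, rep(-1, 7)), genes))
  sp <- balanced_split(maps, max_attempts = 60, seed = 5)
  expect_equal(sp$relaxations, 3L)
  expect_equal(sp$threshold, (1 / 3) * 0.8^3)
  expect_gt(sp$attempts, 3 * 60)
  # the returned split has one positive on each side
  expect_equal(sum(maps$rare[sp$train] == 1), 1)
  expect_equal(sum(maps$rare[sp$test] == 1), 1)
})

test_that("when even the floor fails, the most balanced draw is returned with a warning", {
  # a single positive gene: one split part is always single-class (ratio 0)
  genes <- paste0("g", 1:6)
  maps <- list(solo = stats::setNames(c(1, rep(-1, 5)), genes))
  expect_warning(
    sp <- balanced_split(maps, max_attempts = 5, seed = 2),
    "most")
  expect_setequal(c(sp$train, sp$test), genes)
  expect_equal(sp$threshold, 0)       # the best achievable min ratio
  expect_gte(sp$relaxations, 1L)
})

test_that("degenerate split inputs are rejected", {
  expect_error(balanced_split(list(s = c(g1 = 1)), seed = 1), "at least 2")
  maps <- list(s = c(g1 = 1, g2 = -1, g3 = 1))
  expect_error(balanced_split(maps, train_fraction = 1), "train_fraction")
  expect_error(balanced_split(maps, max_attempts = 0), "max_attempts")
})

test_that("annotate_level recovers structure labels from informative features", {
  set.seed(19)
  onto <- tiny_ontology()
  genes <- sprintf("g%02d", 1:24)
  lv1 <- structures_at_level(onto, 1)
  # features: per level-1 structure one clean indicator column plus noise
  labs <- lapply(lv1, function(s)
    stats::setNames(sample(c(1, -1), 24, replace = TRUE, prob = c(.5, .5)),
                    genes))
  names(labs) <- lv1
  X <- do.call(cbind, lapply(labs, function(y) y + 0.05 * rnorm(24)))
  X <- cbind(X, matrix(rnorm(24 * 5), 24))
  rownames(X) <- genes
  fm <- feature_matrix(X, representation = "bow")
  tab <- table_from_maps(labs)
  rep <- annotate_level(fm, tab, onto, level = 1, lambda = 0.1, seed = 4)
  expect_s3_class(rep, "ish_eval_report")
  expect_setequal(rep$results$structure_id,
                  setdiff(lv1, c(rep$skipped, rep$split$excluded)))
  expect_gte(min(rep$results$auc), 0.9)
  expect_equal(rep$overall_auc, mean(rep$results$auc))
  expect_equal(rep$results$n_train + rep$results$n_test, rep(24L, nrow(rep$results)))
})

test_that("results are invariant to gene row order and unknown genes are ignored", {
  set.seed(23)
  onto <- tiny_ontology()
  genes <- sprintf("g%02d", 1:18)
  lv1 <- structures_at_level(onto, 1)
  labs <- stats::setNames(lapply(lv1, function(s)
    stats::setNames(sample(c(1, -1), 18, replace = TRUE), genes)), lv1)
  X <- matrix(rnorm(18 * 6), 18, dimnames = list(genes, NULL))
  fm <- feature_matrix(X, representation = "bow")
  tab <- table_from_maps(labs)
  r1 <- annotate_level(fm, tab, onto, 1, seed = 9)
  # permute feature rows: alignment is by gene ID
  perm <- sample(18)
  fm2 <- feature_matrix(X[perm, , drop = FALSE], representation = "bow")
  r2 <- annotate_level(fm2, tab, onto, 1, seed = 9)
  expect_equal(r1$results, r2$results)
  # annotated genes without feature rows are dropped from the label maps
  extra <- rbind(tab, data.frame(gene_id = "ghost", structure_id = lv1[1],
                                 metric = "pattern", category = "full"))
  r3 <- annotate_level(fm, extra, onto, 1, seed = 9)
  expect_equal(r1$results, r3$results)
})

test_that("uninformative features score near chance across the ontology", {
  set.seed(31)
  onto <- tiny_ontology()
  genes <- sprintf("g%02d", 1:30)
  sids <- onto$structure_id
  labs <- stats::setNames(lapply(sids, function(s)
    stats::setNames(sample(rep(c(1, -1), 15)), genes)), sids)
  X <- matrix(rnorm(30 * 8), 30, dimnames = list(genes, NULL))
  fm <- feature_matrix(X, representation = "bow")
  es <- annotate_all_levels(fm, table_from_maps(labs), onto, seed = 2)
  expect_s3_class(es, "ish_eval_set")
  expect_equal(es$summary$level, c(1, 2))
  aucs <- unlist(lapply(es$reports, function(r) r$results$auc))
  expect_gte(length(aucs), 6)
  # chance level: features carry no label information
  expect_lt(abs(mean(aucs) - 0.5), 0.2)
})

test_that("a level with no eligible structures yields an empty report with a warning", {
  onto <- tiny_ontology()
  X <- matrix(rnorm(12), 4, dimnames = list(paste0("g", 1:4), NULL))
  fm <- feature_matrix(X, representation = "bow")
  tab <- data.frame(gene_id = paste0("h", 1:4),   # none match the features
                    structure_id = structures_at_level(onto, 1)[1],
                    metric = "pattern", category = "full")
  expect_warning(rep <- annotate_level(fm, tab, onto, 1), "no eligible")
  expect_equal(nrow(rep$results), 0)
  expect_true(is.na(rep$overall_auc))
  expect_error(annotate_level(fm, tab, onto, 99), "no structures at level")
})
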