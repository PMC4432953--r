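ont <- tiny_ontology()

test_that("stack shape, ordering and determinism contracts hold", {
  sim <- generate_stack(list(S1 = "undetected"), ont, n_sections = 17,
                        image_size = c(320, 240), seed = 5)
  expect_length(sim$stack$sections, 17)
  expect_equal(dim(sim$stack$sections[[1]]$image), c(320, 240))
  pos <- vapply(sim$stack$sections, `[[`, numeric(1), "position")
  expect_equal(pos, seq(0, 1, length.out = 17))
  sim2 <- generate_stack(list(S1 = "undetected"), ont, n_sections = 17,
                         image_size = c(320, 240), seed = 5)
  expect_identical(sim, sim2)
})

test_that("an all-undetected spec paints pure background noise", {
  spec <- setNames(rep(list("undetected"), nrow(ont)), ont$structure_id)
  sim <- generate_stack(spec, ont, n_sections = 3, image_size = c(64, 80),
                        seed = 2, noise_sd = 0.02, background = 0.12)
  expect_true(all(sim$annotations$category == "undetected"))
  img <- sim$stack$sections[[1]]$image
  # noise around the background level, no structure anywhere
  expect_lt(abs(mean(img) - 0.12), 0.01)
  expect_lt(sd(img), 0.05)
})

test_that("unknown structures and empty images are rejected", {
  expect_error(generate_stack(list(nope = "undetected"), ont), "unknown")
  expect_error(generate_stack(list(S1 = "undetected"), ont,
                              image_size = c(0, 10)), "image_size")
})

test_that("painted intensity grades are recoverable from ground-truth masks", {
  spec_hi <- list(S1 = list(pattern = "full", intensity = "high",
                            density = "median"),
                  S2 = list(pattern = "full", intensity = "low",
                            density = "median"))
  sim <- generate_stack(spec_hi, ont, n_sections = 9,
                        image_size = c(180, 240), seed = 31)
  m_hi <- masked_mean(sim, sim$layout, ont, "S1")
  m_lo <- masked_mean(sim, sim$layout, ont, "S2")
  spec_none <- list(S1 = "undetected", S2 = "undetected")
  sim0 <- generate_stack(spec_none, ont, n_sections = 9,
                         image_size = c(180, 240), seed = 31)
  m_0 <- masked_mean(sim0, sim0$layout, ont, "S1")
  expect_gt(m_hi, m_lo)
  expect_gt(m_lo, m_0)
})

test_that("emitted annotations equal the spec that painted the images", {
  ds <- simulate_dataset(n_genes = 6, undetected_fraction = 0.5,
                         ontology = ont, n_sections = 3,
                         image_size = c(90, 120), seed = 9)
  # every (gene, structure, metric) exactly once
  expect_equal(nrow(ds$annotations), 6 * nrow(ont) * 3)
  expect_equal(anyDuplicated(ds$annotations[, 1:3]), 0L)
  # undetected pattern forces undetected intensity and density
  w <- reshape(ds$annotations, idvar = c("gene_id", "structure_id"),
               timevar = "metric", direction = "wide")
  und <- w$category.pattern == "undetected"
  expect_true(all(w$category.intensity[und] == "undetected"))
  expect_true(all(w$category.density[und] == "undetected"))
  expect_true(all(w$category.intensity[!und] != "undetected"))
})

test_that("undetected fraction is binomially consistent and boundary-exact", {
  ont1 <- generate_ontology(1, 1)
  ds <- simulate_dataset(n_genes = 60, undetected_fraction = 0.8,
                         ontology = ont1, n_sections = 1,
                         image_size = c(64, 64), seed = 4)
  pat <- ds$annotations[ds$annotations$metric == "pattern", ]
  detected <- sum(pat$category != "undetected")
  # E[detected] = 12, sd = sqrt(60 * .2 * .8)
  expect_lt(abs(detected - 12), 3 * sqrt(60 * 0.2 * 0.8))

  ds1 <- simulate_dataset(n_genes = 5, undetected_fraction = 1,
                          ontology = ont1, n_sections = 1,
                          image_size = c(64, 64), seed = 4)
  expect_true(all(ds1$annotations$category == "undetected"))
})

test_that("dataset simulation is deterministic under a fixed seed", {
  a <- simulate_dataset(n_genes = 3, ontology = ont, n_sections = 2,
                        image_size = c(64, 80), seed = 77)
  b <- simulate_dataset(n_genes = 3, ontology = ont, n_sections = 2,
                        image_size = c(64, 80), seed = 77)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$stacks, b$stacks)
})

test_that("a masked-mean threshold separates detected from undetected genes", {
  # easy settings: high intensity, low noise; this guarantees downstream
  # recovery experiments are meaningful
  ont1 <- generate_ontology(1, 2)
  ds <- simulate_dataset(n_genes = 40, undetected_fraction = 0.5,
                         ontology = ont1, n_sections = 7,
                         image_size = c(120, 160), noise_sd = 0.02, seed = 12)
  pat <- ds$annotations[ds$annotations$metric == "pattern", ]
  for (sid in ont1$structure_id) {
    lab <- pat[pat$structure_id == sid, ]
    y <- ifelse(lab$category[match(names(ds$stacks), lab$gene_id)] ==
                  "undetected", -1, 1)
    if (length(unique(y)) < 2) next
    sc <- vapply(ds$stacks, masked_mean, numeric(1), layout = ds$layout,
                 ontology = ont1, sid = sid)
    expect_gte(auc_score(sc, y), 0.95)
  }
})
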