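EXPECTED_TAP_LEN <- c(`6` = 36864L, `9` = 73728L, `12` = 147456L,
                      `16` = 36864L, `18` = 3072L)

test_that("symbolic shape propagation reproduces the published tap shapes", {
  arch <- overfeat_fast_architecture()
  shapes <- propagate_shapes(arch)
  expect_equal(shapes[[6]], c(256L, 12L, 12L))
  expect_equal(shapes[[9]], c(512L, 12L, 12L))
  expect_equal(shapes[[12]], c(1024L, 12L, 12L))
  expect_equal(shapes[[16]], c(1024L, 6L, 6L))
  expect_equal(shapes[[18]], c(3072L, 1L, 1L))
})

test_that("a mutated architecture is rejected naming the offending tap", {
  arch <- overfeat_fast_architecture()
  arch$layers[[1]]$stride <- 3L
  expect_error(build_extractor(arch), "tap layer 6")
})

test_that("preprocessing resizes, replicates channels and centers", {
  g <- matrix(runif(50 * 70), 50, 70)
  x <- preprocess_section(g)
  expect_equal(dim(x), c(231, 231, 3))
  expect_equal(x[, , 1], x[, , 2])
  expect_equal(x[, , 1], x[, , 3])
  # identity-size RGB input: only the dtype scaling/centering applies
  rgb <- array(runif(231 * 231 * 3), c(231, 231, 3))
  y <- preprocess_section(rgb)
  expect_equal(y, rgb - 0.5, tolerance = 1e-6)
  expect_error(preprocess_section(matrix(numeric(0), 0, 0)), "empty")
})

test_that("same seed gives identical weights and bit-identical features", {
  img <- textured_image(64, 64)
  e1 <- build_extractor(seed = 4, max_layer = 6)
  e2 <- build_extractor(seed = 4, max_layer = 6)
  expect_identical(e1$weights, e2$weights)
  expect_identical(extract_features(e1, img, tap = 6),
                   extract_features(e2, img, tap = 6))
  # limiting the materialized depth does not change earlier layers' weights
  e3 <- build_extractor(seed = 4, max_layer = 12)
  expect_identical(e1$weights[[4]], e3$weights[[4]])
})

test_that("tap vectors have the published lengths and zero biases pass zeros", {
  ext <- build_extractor(seed = 1)
  img <- textured_image(80, 100)
  taps <- extract_taps(ext, img)
  for (tp in names(EXPECTED_TAP_LEN)) {
    expect_length(taps[[tp]], EXPECTED_TAP_LEN[[tp]])
  }
  expect_error(extract_features(ext, img, tap = 13), "valid taps")
  # preprocessing centers at 0.5, so a 0.5-valued image becomes all zeros;
  # with zero biases every tap is exactly zero
  v0 <- extract_taps(ext, matrix(0.5, 64, 64), taps = c(6L, 18L))
  expect_true(all(v0[["6"]] == 0))
  expect_true(all(v0[["18"]] == 0))
})

test_that("section pooling matches a per-coordinate loop and its algebra", {
  set.seed(8)
  vecs <- lapply(1:3, function(i) {
    v <- runif(40)
    attr(v, "tap") <- 12L
    v
  })
  mx <- pool_sections(vecs, "max")
  av <- pool_sections(vecs, "average")
  for (j in 1:40) {
    expect_equal(mx[j], max(vecs[[1]][j], vecs[[2]][j], vecs[[3]][j]))
    expect_equal(av[j], mean(c(vecs[[1]][j], vecs[[2]][j], vecs[[3]][j])))
  }
  # permutation invariance and idempotence under duplication
  expect_equal(pool_sections(vecs[c(3, 1, 2)], "max"), mx)
  expect_equal(pool_sections(c(vecs, vecs[2]), "max"), mx)
  # identity on a single section
  expect_equal(pool_sections(vecs[1], "max"), as.vector(vecs[[1]]),
               ignore_attr = TRUE)
  # max dominates average for non-negative inputs
  expect_true(all(mx >= av))
  bad <- vecs
  attr(bad[[2]], "tap") <- 16L
  expect_error(pool_sections(bad), "different tap")
  expect_error(pool_sections(list(runif(3), runif(4))), "length")
})

test_that("symbolic shapes equal empirical activation sizes layer by layer", {
  ext <- build_extractor(seed = 3)
  shapes <- propagate_shapes(ext$arch)
  A <- preprocess_section(textured_image(60, 60), 231)
  for (i in seq_along(ext$arch$layers)) {
    A <- ishannotate:::forward_layer(A, ext$arch$layers[[i]],
                                     ext$weights[[i]])
    expect_equal(dim(A)[c(3, 1, 2)], shapes[[i]],
                 info = paste("layer", i))
  }
})

test_that("weight files round-trip through the flat binary format", {
  # a miniature architecture keeps the file tiny; the format is the same
  arch <- structure(list(
    layers = list(list(type = "conv", kernel = 3L, stride = 2L, out = 8L),
                  list(type = "relu"),
                  list(type = "maxpool", kernel = 2L, stride = 2L),
                  list(type = "linear", out = 16L),
                  list(type = "relu")),
    input_size = c(23L, 23L, 3L), taps = 5L,
    expected_tap_shapes = list(`5` = c(16L, 1L, 1L))),
    class = "ish_cnn_arch")
  ext <- build_extractor(arch, seed = 9)
  tf <- tempfile(fileext = ".bin")
  write_cnn_weights(ext, tf)
  ext2 <- build_extractor(arch, weights_source = tf)
  # 32-bit storage: equal to float precision
  expect_equal(ext2$weights[[1]]$W, ext$weights[[1]]$W, tolerance = 1e-6)
  expect_equal(ext2$weights[[4]]$W, ext$weights[[4]]$W, tolerance = 1e-6)
  img <- textured_image(50, 50)
  expect_equal(extract_features(ext2, img, 5),
               extract_features(ext, img, 5), tolerance = 1e-4)
  unlink(tf)
})

test_that("pooled CNN features are permutation-invariant across sections", {
  ds <- simulate_dataset(n_genes = 2, undetected_fraction = 0.3,
                         ontology = tiny_ontology(), n_sections = 3,
                         image_size = c(60, 80), seed = 6)
  fm <- extract_cnn_features(ds, tap = 6, seed = 1)
  expect_equal(dim(fm), c(2, 36864))
  expect_equal(attr(fm, "representation"), "cnn:L6")
  st <- ds$stacks[[1]]
  st$sections <- rev(st$sections)
  fm2 <- extract_cnn_features(list(gene001 = st), tap = 6, seed = 1)
  expect_equal(unclass(fm2)[1, ], unclass(fm)[1, ], ignore_attr = TRUE)
})
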