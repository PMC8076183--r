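test_that("generators are pure functions of seed and parameters", {
  expect_identical(as.matrix(random_bipartite(20, 20, 0.2, seed = 3)),
                   as.matrix(random_bipartite(20, 20, 0.2, seed = 3)))
  expect_identical(as.matrix(blocks(seed = 3)), as.matrix(blocks(seed = 3)))
  expect_false(identical(as.matrix(blocks(seed = 3)),
                         as.matrix(blocks(seed = 4))))
})

test_that("random tables have binomial edge counts and one component", {
  tb <- random_bipartite(50, 50, 0.2, seed = 1)
  n_edges <- sum(as.matrix(tb))
  mu <- 50 * 50 * 0.2
  sd3 <- 3 * sqrt(50 * 50 * 0.2 * 0.8)
  expect_gt(n_edges, mu - sd3)
  expect_lt(n_edges, mu + sd3)
  expect_equal(bfs_components(tb), 1)
  # sub-critical density warns about the expected degree, then fails to
  # produce a connected draw
  expect_warning(expect_error(random_bipartite(20, 20, 0.02, seed = 1),
                              "No valid draw"),
                 "degree below 1")
})

test_that("dense tables approach the rank-1 limit", {
  tb <- random_bipartite(20, 20, 0.99, seed = 2)
  expect_lt(ca_spectrum(tb)$eigenvalues[2], 0.05)
})

test_that("band generator plants a recoverable gradient", {
  tb <- gradient_band(seed = 2)
  pl <- planted_structure(tb)
  emb <- ca_embed(ca_spectrum(tb), n_axes = 1)
  rho <- cor(emb$coordinates[, 1], pl$row_order, method = "spearman")
  expect_gt(abs(rho), 0.95)
  # the normalized index difference spans [-1, 1]: bandwidth 2 covers every
  # cell, degenerating the band family to the random one
  expect_true(all(caspectral:::band_mask(10, 12, 2) == 1))
  expect_false(all(caspectral:::band_mask(10, 12, 1) == 1))
})

test_that("block generator plants exact or weak component structure", {
  t0 <- blocks(2, c(15, 20), 0.4, noise = 0, seed = 5)
  lam <- ca_spectrum(t0)$eigenvalues
  expect_equal(lam[1:2], c(1, 1), tolerance = 1e-10)
  expect_equal(bfs_components(t0), 2)

  t1 <- blocks(2, c(30, 40), 0.3, noise = 0.01, seed = 6)
  lam1 <- ca_spectrum(t1)$eigenvalues
  expect_gt(lam1[2], 0.8) # close to 1 ...
  expect_lt(lam1[2], 1 - 1e-8) # ... but strictly below it
  expect_equal(bfs_components(t1), 1)

  t3 <- blocks(3, c(30, 40), 0.3, noise = 0.01, seed = 7)
  expect_equal(eigengap_count(ca_spectrum(t3)$eigenvalues)$K, 3L)
})

test_that("blocks with gradients separate clusters in the leading axis", {
  tw <- blocks_with_gradients(seed = 8)
  sp <- ca_spectrum(tw)
  pl <- planted_structure(tw)
  # second eigenvector is sign-homogeneous within each planted block
  v2 <- sp$row_scores[, 2]
  s1 <- sign(v2[pl$row_block == 1])
  s2 <- sign(v2[pl$row_block == 2])
  expect_true(all(s1 == s1[1]))
  expect_true(all(s2 == s2[1]))
  expect_true(s1[1] != s2[1])
})

test_that("RCA binarization follows the Balassa rule", {
  # hand oracle: RCA11 = (10/10)/(11/20) = 20/11, RCA21 = 2/11, RCA22 = 2
  w <- matrix(c(10, 0, 1, 9), 2, byrow = TRUE)
  expect_equal(unname(as.matrix(binarize_rca(w))),
               matrix(c(1, 0, 0, 1), 2, byrow = TRUE))
  # uniform weights: every RCA is exactly 1, so everything is present
  expect_true(all(as.matrix(binarize_rca(matrix(5, 3, 4))) == 1))
  # one nonzero cell per row/column: identity pattern survives
  expect_equal(unname(as.matrix(binarize_rca(diag(3) * 7))), diag(3))
  # threshold is configurable
  expect_equal(sum(as.matrix(binarize_rca(w, threshold = 1.9))), 1)
})

test_that("planted metadata round-trips through export and import", {
  tb <- blocks_with_gradients(seed = 12)
  path <- withr::local_tempfile(fileext = ".mtx")
  write_generated(tb, path)
  back <- read_generated(path)
  expect_equal(unname(as.matrix(back)), unname(as.matrix(tb)))
  pl0 <- planted_structure(tb)
  pl1 <- planted_structure(back)
  expect_equal(pl1$family, pl0$family)
  expect_equal(pl1$seed, pl0$seed)
  expect_equal(as.integer(pl1$row_block), as.integer(pl0$row_block))
  expect_equal(as.integer(pl1$row_order), as.integer(pl0$row_order))
})
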