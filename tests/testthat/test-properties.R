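# Property-style invariants over seeded random tables.

test_that("SVD route and generalized Laplacian eigensolver agree", {
  for (s in 1:20) {
    set.seed(s)
    nr <- sample(8:40, 1)
    nc <- sample(10:60, 1)
    tb <- random_bipartite(nr, nc, 0.25, seed = 2000 + s)
    sp <- ca_spectrum(tb)
    le <- laplacian_generalized_eigs(project_similarity(tb, "row"))
    K <- length(sp$eigenvalues)
    expect_equal(le$values[seq_len(K)], 1 - sp$eigenvalues,
                 tolerance = 1e-8)
    # eigenvectors match up to sign on well-separated eigenvalues
    lam <- sp$eigenvalues
    for (k in 2:K) {
      if (min(abs(lam[k] - lam[-k])) > 1e-6) {
        v1 <- sp$row_scores[, k]
        v2 <- le$vectors[, k]
        expect_lt(min(max(abs(v1 - v2)), max(abs(v1 + v2))), 1e-8)
      }
    }
  }
})

test_that("eigenvalues are real, clipped to [0, 1], led by 1", {
  for (s in 1:10) {
    tb <- random_bipartite(15, 25, 0.2, seed = 2100 + s)
    lam <- ca_spectrum(tb)$eigenvalues
    expect_true(all(lam >= 0 & lam <= 1))
    expect_equal(lam[1], 1, tolerance = 1e-12)
    expect_true(all(diff(lam) <= 1e-12))
  }
})

test_that("permuting rows and columns permutes scores and fixes eigenvalues", {
  for (s in 1:5) {
    set.seed(s)
    tb <- random_bipartite(12, 16, 0.3, seed = 2200 + s)
    A <- as.matrix(tb)
    pr <- sample(nrow(A))
    pc <- sample(ncol(A))
    tp <- incidence_table(A[pr, pc])
    sp <- ca_spectrum(tb)
    spp <- ca_spectrum(tp)
    expect_equal(spp$eigenvalues, sp$eigenvalues, tolerance = 1e-10)
    lam <- sp$eigenvalues
    for (k in 2:length(lam)) {
      if (min(abs(lam[k] - lam[-k])) > 1e-6) {
        expect_equal(unname(spp$row_scores[, k]),
                     unname(sp$row_scores[pr, k]), tolerance = 1e-8)
      }
    }
  }
})

test_that("component counting matches the BFS oracle on block tables", {
  for (s in 1:20) {
    set.seed(s)
    nb <- sample(2:4, 1)
    shape <- c(sample(6:12, 1), sample(8:14, 1))
    tb <- blocks(nb, shape, 0.45, noise = 0, seed = 2300 + s)
    expect_equal(count_components(ca_spectrum(tb)), bfs_components(tb))
  }
})

test_that("tidiers expose spectra and trees as well-formed tibbles", {
  tb <- blocks(seed = 14)
  sp <- ca_spectrum(tb)
  td <- tidy(sp)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$eigenvalue, sp$eigenvalues)
  expect_equal(td$ca_axis[2], 1L) # eigenvector 2 is CA axis 1
  expect_equal(sum(td$variation_share, na.rm = TRUE), 1, tolerance = 1e-10)
  gl <- glance(sp)
  expect_equal(gl$n_components, 1L)
  tree <- recursive_scca(tb, seed = 1)
  tt <- tidy(tree)
  expect_equal(nrow(tt), tree$n_nodes)
  expect_equal(glance(tree)$n_leaves, sum(tt$leaf))
  te <- tidy(ca_embed(sp, 2))
  expect_named(te, c("label", "side", "axis1", "axis2"))
})

test_that("autoplot returns ggplot objects for spectra and embeddings", {
  tb <- blocks(seed = 15)
  sp <- ca_spectrum(tb)
  expect_s3_class(autoplot(sp), "ggplot")
  emb <- ca_embed(sp, 2)
  part <- kmeans_partition(emb, 2, seed = 1)
  expect_s3_class(autoplot(emb, cluster_labels = part$cluster), "ggplot")
})
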