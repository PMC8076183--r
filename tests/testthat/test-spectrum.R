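test_that("hand-worked 2x3 table yields the known eigenstructure", {
  # oracle: dense eigensolver on the 2x2 row operator [[0.75,0.25],[0.25,0.75]]
  tab <- small_table()
  op <- row_operator(tab)
  expect_equal(unname(op), matrix(c(0.75, 0.25, 0.25, 0.75), 2))
  oracle <- eigen(op)
  sp <- ca_spectrum(tab)
  expect_equal(sp$eigenvalues, oracle$values, tolerance = 1e-12) # (1, 0.5)
  v2 <- sp$row_scores[, 2]
  expect_equal(v2 / v2[1], c(r001 = 1, r002 = -1), tolerance = 1e-10)
  u2 <- sp$col_scores[, 2]
  expect_equal(u2 / u2[1], c(c001 = 1, c002 = 0, c003 = -1),
               tolerance = 1e-10)
})

test_that("rank-1 and block-diagonal limits are exact", {
  expect_equal(ca_spectrum(incidence_table(matrix(1, 2, 2)))$eigenvalues,
               c(1, 0), tolerance = 1e-12)
  A <- matrix(c(1, 1, 0, 0,
                1, 1, 0, 0,
                0, 0, 1, 1,
                0, 0, 1, 1), 4, byrow = TRUE)
  sp <- ca_spectrum(incidence_table(A))
  expect_equal(sp$eigenvalues[1:2], c(1, 1), tolerance = 1e-10)
})

test_that("trivial axis is constant and scores satisfy the CA identities", {
  for (s in 1:5) {
    tab <- random_bipartite(12, 18, 0.3, seed = 70 + s)
    sp <- ca_spectrum(tab)
    lam <- sp$eigenvalues
    r <- sp$row_margins; cc <- sp$col_margins; n <- sp$total
    A <- as.matrix(tab)
    expect_equal(lam[1], 1, tolerance = 1e-12)
    expect_equal(unname(sp$row_scores[, 1]), rep(1, nrow(A)),
                 tolerance = 1e-8)
    for (k in 2:length(lam)) {
      v <- sp$row_scores[, k]; u <- sp$col_scores[, k]
      # centering and unit-variance standardization
      expect_equal(sum(r * v), 0, tolerance = 1e-8)
      expect_equal(sum(cc * u), 0, tolerance = 1e-8)
      expect_equal(sum(r * v^2), n, tolerance = 1e-6)
      # eigenproblem residual for the row operator
      expect_equal(unname(row_operator(tab) %*% v), unname(cbind(lam[k] * v)),
                   tolerance = 1e-8)
      # transition duality: D_c^{-1} t(A) v = +/- sqrt(lambda) u
      trans <- drop(t(A) %*% v) / cc
      expect_lt(min(max(abs(trans - sqrt(lam[k]) * u)),
                    max(abs(trans + sqrt(lam[k]) * u))), 1e-8)
    }
  }
})

test_that("unit-norm normalization scales scores without changing structure", {
  tab <- small_table()
  sp <- ca_spectrum(tab, normalization = "unit-norm")
  expect_equal(sum(sp$row_scores[, 2]^2), 1, tolerance = 1e-10)
  spv <- ca_spectrum(tab)
  expect_equal(sp$eigenvalues, spv$eigenvalues, tolerance = 1e-12)
  # same direction after renormalization
  a <- sp$row_scores[, 2] / sqrt(sum(sp$row_scores[, 2]^2))
  b <- spv$row_scores[, 2] / sqrt(sum(spv$row_scores[, 2]^2))
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("sign convention is deterministic and orients the largest entry up", {
  tab <- random_bipartite(10, 12, 0.3, seed = 5)
  sp1 <- ca_spectrum(tab)
  sp2 <- ca_spectrum(tab)
  expect_identical(sp1$row_scores, sp2$row_scores)
  for (k in seq_len(ncol(sp1$row_scores))) {
    v <- sp1$row_scores[, k]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("degenerate and over-asked spectra warn as promised", {
  expect_warning(ca_spectrum(incidence_table(matrix(c(1, 2, 1), 1, 3))),
                 "single row")
  tab <- small_table()
  expect_warning(sp <- ca_spectrum(tab, k_max = 3), "paired")
  expect_equal(sp$eigenvalues, c(1, 0.5, 0), tolerance = 1e-10)
  # the null-space axis lives on the larger (column) side; the row side has
  # no paired scores for it
  expect_true(all(is.na(sp$row_scores[, 3])))
  expect_true(all(is.finite(sp$col_scores[, 3])))
})

test_that("eigenvalue-1 multiplicity counts components, matching BFS", {
  tab <- incidence_table(diag(2))
  expect_equal(count_components(ca_spectrum(tab)), 2L)
  band <- gradient_band(30, 30, seed = 4)
  expect_equal(count_components(ca_spectrum(band)), 1L)
  for (s in 1:10) {
    nb <- 2 + s %% 3
    tb <- blocks(nb, c(8, 10), 0.4, noise = 0, seed = 300 + s)
    expect_equal(count_components(ca_spectrum(tb)), bfs_components(tb))
    expect_equal(bfs_components(tb), nb)
  }
})

test_that("nontrivial eigenvalues agree with classical CA (vegan oracle)", {
  skip_if_not_installed("vegan")
  tab <- random_bipartite(15, 20, 0.3, seed = 11)
  lam <- ca_spectrum(tab)$eigenvalues
  ref <- vegan::cca(as.matrix(tab))$CA$eig
  expect_equal(unname(lam[-1][seq_along(ref)]), unname(ref),
               tolerance = 1e-8)
})
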