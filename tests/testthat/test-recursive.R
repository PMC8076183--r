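test_that("two disconnected random blocks split into two terminal leaves", {
  tb <- blocks(2, c(20, 25), 0.4, noise = 0, seed = 51)
  tree <- recursive_scca(tb, seed = 1)
  td <- tidy(tree)
  expect_equal(sum(td$leaf), 2L)
  expect_equal(td$K[!td$leaf], 2L)
  expect_true(all(td$K[td$leaf] == 1L))
  # leaves partition the root members into the planted blocks
  asg <- scca_assignments(tree)
  pl <- planted_structure(tb)
  expect_equal(ari(asg$leaf[match(tb$row_labels, asg$label)], pl$row_block), 1)
})

test_that("leaves of gradient-in-block data carry the planted gradients", {
  tw <- blocks_with_gradients(seed = 61)
  tree <- recursive_scca(tw, seed = 2)
  expect_equal(tree$n_leaves, 2L)
  asg <- scca_assignments(tree)
  pl <- planted_structure(tw)
  for (lf in unique(asg$leaf)) {
    idx <- match(asg$label[asg$leaf == lf], tw$row_labels)
    expect_equal(length(unique(pl$row_block[idx])), 1L) # pure leaf
    rho <- cor(asg$axis1_score[asg$leaf == lf], pl$row_order[idx],
               method = "spearman")
    expect_gt(abs(rho), 0.9)
  }
})

test_that("a connected structureless table is a single leaf", {
  tb <- random_bipartite(30, 30, 0.3, seed = 71)
  tree <- recursive_scca(tb, seed = 1)
  expect_equal(tree$n_nodes, 1L)
  expect_equal(tree$root$K, 1L)
  expect_length(tree$root$children, 0)
})

test_that("children's member sets partition the parent's members", {
  tw <- blocks_with_gradients(3, c(15, 20), seed = 81)
  tree <- recursive_scca(tw, seed = 3)
  check <- function(node) {
    if (length(node$children)) {
      kids <- unlist(lapply(node$children, `[[`, "members"))
      expect_setequal(kids, node$members)
      expect_equal(length(kids), length(node$members)) # disjoint
      lapply(node$children, check)
    }
    invisible(NULL)
  }
  check(tree$root)
})

test_that("identical seed and input reproduce the tree bit-for-bit", {
  tw <- blocks_with_gradients(seed = 91)
  j1 <- tree_to_json(recursive_scca(tw, seed = 5))
  j2 <- tree_to_json(recursive_scca(tw, seed = 5))
  expect_identical(as.character(j1), as.character(j2))
})

test_that("undersized children become leaves with a warning", {
  # 2 tiny blocks: the split produces children below min_size
  A <- matrix(0, 4, 6)
  A[1:2, 1:3] <- 1
  A[3:4, 4:6] <- 1
  tb <- incidence_table(A)
  warns <- testthat::capture_warnings(
    tree <- recursive_scca(tb, min_size = 3, seed = 1))
  expect_true(all(grepl("below min_size", warns)))
  expect_length(warns, 2)
  expect_equal(tree$n_leaves, 2L)
})
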