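# Shared fixtures and independent oracles.

# 2x3 hand-worked example: r = (2, 2), c = (1, 2, 1), n = 4,
# lambda = (1, 0.5), v2 ~ (1, -1), u2 ~ (1, 0, -1).
small_table <- function() {
  incidence_table(matrix(c(1, 1, 0, 0, 1, 1), nrow = 2, byrow = TRUE))
}

# Independent combinatorial oracle: connected-component count of the
# bipartite graph, via igraph's BFS-based components().
bfs_components <- function(table) {
  A <- as.matrix(table)
  g <- igraph::graph_from_biadjacency_matrix(A > 0)
  igraph::components(g)$no
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Direct-arithmetic oracle for the row operator D_r^{-1} A D_c^{-1} A^T.
row_operator <- function(table) {
  A <- as.matrix(table)
  diag(1 / rowSums(A)) %*% A %*% diag(1 / colSums(A)) %*% t(A)
}
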