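#' K-means partition of a spectral embedding
#'
#' Discretizes the relaxed normalized-cut solution: runs k-means on the first
#' `K - 1` principal-coordinate axes of the embedding (the trivial axis is
#' constant and cannot influence the result, so `K` clusters need only
#' `K - 1` informative axes). The best of `n_restarts` k-means starts by
#' within-cluster sum of squares is kept, and the run is seeded so results
#' are reproducible. Labels are relabelled in order of first appearance, so
#' identical inputs yield identical label vectors.
#'
#' @param embedding A [ca_embedding()] with at least `K - 1` axes.
#' @param K Number of clusters, `2 <= K <=` number of nodes.
#' @param seed Integer seed for the restarts (applied locally; the session
#'   RNG state is untouched). `NULL` uses the current RNG state.
#' @param n_restarts Number of random k-means starts (default 50).
#' @return A tibble with columns `label` (node identifier) and `cluster`
#'   (integer in `1..K`). The k-means objective is attached as attribute
#'   `tot_withinss`.
#' @export
kmeans_partition <- function(embedding, K, seed = NULL, n_restarts = 50) {
  stopifnot(inherits(embedding, "ca_embedding"))
  X <- embedding$coordinates
  n <- nrow(X)
  if (K < 2) stop("`K` must be at least 2.", call. = FALSE)
  if (K > n) {
    stop(sprintf("`K` = %d exceeds the %d nodes in the embedding.", K, n),
         call. = FALSE)
  }
  d <- min(K - 1L, ncol(X))
  if (d < K - 1L) {
    warning(sprintf("Embedding has only %d axes; k-means uses all of them.",
                    ncol(X)), call. = FALSE)
  }
  Xd <- X[, seq_len(d), drop = FALSE]
  if (K == n) {
    cl <- seq_len(n) # degenerate: every node its own cluster
    wss <- 0
  } else {
    km <- local_seed(seed, stats::kmeans(Xd, centers = K,
                                         nstart = n_restarts, iter.max = 100))
    cl <- km$cluster
    wss <- km$tot.withinss
  }
  cl <- match(cl, unique(cl)) # canonical labels: order of first appearance
  out <- tibble::tibble(label = embedding$labels, cluster = as.integer(cl))
  attr(out, "tot_withinss") <- wss
  out
}

# Evaluate `expr` under a locally-set seed without disturbing the caller's
# RNG stream; a NULL seed evaluates in the ambient stream.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}
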