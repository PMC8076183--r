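#' Recursive cluster-then-ordinate decomposition of an incidence table
#'
#' When a similarity network mixes weakly connected clusters with
#' within-cluster gradients, the leading CA axes describe the clusters and
#' the gradients are pushed into noisy higher-order axes. This procedure
#' therefore clusters first and ordinates within clusters: at each node it
#' computes the CA spectrum of the (sub)table, estimates the cluster count
#' `K` with the eigengap heuristic, and — if `K > 1` — partitions the rows
#' by k-means on the `K - 1` leading nontrivial principal-coordinate axes,
#' recursing on each cluster's row-subset table (columns that become empty
#' in a subset are dropped, so every child is a valid incidence table).
#' Recursion stops at nodes where the eigengap indicates a single cluster
#' (`K = 1`) or that are smaller than `min_size`; each leaf keeps its own
#' spectrum and embedding so that within-leaf gradients can be read from the
#' leaf's first CA axis.
#'
#' The procedure is fully reproducible: node identifiers are assigned in
#' depth-first preorder and each node's k-means seed is derived
#' deterministically from `seed` and the node id.
#'
#' @param table An [incidence_table()].
#' @param max_k Eigengap search bound passed to [eigengap_count()]
#'   (default 20).
#' @param min_size Minimum number of rows a node must have to be considered
#'   for splitting (default 3); smaller nodes become leaves with a warning
#'   when produced by a split.
#' @param seed Integer seed controlling all k-means runs.
#' @param normalization Passed to [ca_spectrum()].
#' @return An object of class `scca_tree`: list with `root` (recursive node
#'   structure), `n_nodes`, `n_leaves`, and the call parameters. Each node
#'   carries `id`, `parent`, `members` (row labels), `size`, `K`,
#'   `eigenvalues` (examined prefix), `quality`, `eigengap` (the full
#'   [eigengap_count()] decision), `children`; leaves additionally carry
#'   `spectrum` and `embedding`.
#' @seealso [scca_assignments()], [tidy.scca_tree()], [tree_to_json()]
#' @export
recursive_scca <- function(table, max_k = 20, min_size = 3, seed = 1,
                           normalization = "unit-variance") {
  stopifnot(inherits(table, "incidence_table"))
  counter <- new.env(parent = emptyenv())
  counter$next_id <- 1L
  counter$n_leaves <- 0L

  grow <- function(tbl, parent_id, depth, undersized) {
    id <- counter$next_id
    counter$next_id <- id + 1L
    node <- list(id = id, parent = parent_id, depth = depth,
                 members = tbl$row_labels, size = nrow(tbl$values))

    degenerate <- nrow(tbl$values) < 2L || ncol(tbl$values) < 2L
    spec <- if (degenerate) {
      suppressWarnings(ca_spectrum(tbl, normalization = normalization))
    } else {
      ca_spectrum(tbl, normalization = normalization)
    }
    eg <- suppressWarnings(eigengap_count(spec$eigenvalues, max_k = max_k))
    node$eigenvalues <- eg$spectrum_prefix
    node$eigengap <- eg
    node$K <- eg$K
    node$quality <- partition_quality(spec$eigenvalues, eg$K)

    n_avail <- if (degenerate) 0L else sum(!is.na(spec$row_scores[1, -1]))
    splittable <- !undersized && !degenerate && eg$K > 1L &&
      node$size >= min_size && eg$K < node$size && n_avail >= 1L
    if (!splittable) {
      if (undersized) {
        warning(sprintf("Node %d (%d rows) is below min_size = %d: kept as a leaf.",
                        id, node$size, min_size), call. = FALSE)
      }
      node$K <- if (undersized || degenerate) node$K else eg$K
      node$children <- list()
      node$spectrum <- spec
      node$embedding <- if (n_avail >= 1L) {
        ca_embed(spec, n_axes = min(n_avail, max(max_k - 1L, 1L)))
      } else NULL
      counter$n_leaves <- counter$n_leaves + 1L
      return(node)
    }

    emb <- ca_embed(spec, n_axes = min(eg$K - 1L, n_avail))
    part <- kmeans_partition(emb, K = eg$K, seed = seed + id,
                             n_restarts = 50)
    A <- tbl$values
    node$children <- lapply(seq_len(eg$K), function(g) {
      rows <- part$label[part$cluster == g]
      child_tbl <- incidence_table(A[rows, , drop = FALSE],
                                   row_labels = rows,
                                   col_labels = tbl$col_labels,
                                   drop_empty = TRUE)
      grow(child_tbl, parent_id = id, depth = depth + 1L,
           undersized = length(rows) < min_size)
    })
    node
  }

  root <- grow(table, parent_id = NA_integer_, depth = 0L, undersized = FALSE)
  structure(
    list(root = root,
         n_nodes = counter$next_id - 1L,
         n_leaves = counter$n_leaves,
         max_k = max_k, min_size = min_size, seed = seed,
         normalization = normalization),
    class = "scca_tree"
  )
}

# Depth-first preorder walk collecting every node of the tree.
tree_nodes <- function(tree) {
  out <- list()
  walk <- function(node) {
    out[[length(out) + 1L]] <<- node
    for (ch in node$children) walk(ch)
  }
  walk(tree$root)
  out
}

#' @export
print.scca_tree <- function(x, ...) {
  cat(sprintf("<scca_tree> %d node(s), %d leaf/leaves (seed %d, max_k %d, min_size %d)\n",
              x$n_nodes, x$n_leaves, x$seed, x$max_k, x$min_size))
  walk <- function(node, indent) {
    tag <- if (length(node$children)) "split" else "leaf"
    cat(sprintf("%s- node %d [%s]: %d rows, K = %d, quality = %.3f\n",
                strrep("  ", indent), node$id, tag, node$size, node$K,
                node$quality))
    for (ch in node$children) walk(ch, indent + 1L)
  }
  walk(x$root, 1L)
  invisible(x)
}

#' Flat leaf assignments of a recursive decomposition
#'
#' One row per row node of the original table: the leaf it ended in and its
#' score on the leaf's first CA axis (the within-cluster gradient), `NA`
#' when the leaf is too small to carry a nontrivial axis.
#'
#' @param tree An [recursive_scca()] result.
#' @return A tibble with columns `label`, `leaf`, `axis1_score`.
#' @export
scca_assignments <- function(tree) {
  stopifnot(inherits(tree, "scca_tree"))
  leaves <- purrr::keep(tree_nodes(tree), ~ length(.x$children) == 0L)
  purrr::map_dfr(leaves, function(node) {
    score <- if (!is.null(node$embedding)) {
      unname(node$embedding$coordinates[node$members, 1])
    } else {
      rep(NA_real_, length(node$members))
    }
    tibble::tibble(label = node$members, leaf = node$id,
                   axis1_score = score)
  })
}

#' Serialize a cluster tree to JSON
#'
#' Exports the node table of the tree — id, parent, members, `K`, quality
#' and the examined eigenvalue prefix — as a JSON array, deterministic for a
#' given tree (used for reproducibility checks and by the pipeline).
#'
#' @param tree An [recursive_scca()] result.
#' @param path Optional file path; when given the JSON is written there.
#' @return The JSON string (class `json`), invisibly when `path` is given.
#' @export
tree_to_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "scca_tree"))
  nodes <- purrr::map(tree_nodes(tree), function(node) {
    list(id = node$id, parent = node$parent,
         leaf = length(node$children) == 0L,
         size = node$size, K = node$K,
         quality = node$quality,
         eigenvalues = as.numeric(node$eigenvalues),
         members = node$members)
  })
  js <- jsonlite::toJSON(nodes, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
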