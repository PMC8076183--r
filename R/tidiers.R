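#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a CA spectrum into one row per axis
#'
#' @param x A [ca_spectrum()].
#' @param ... Unused.
#' @return A tibble with columns `eigenvector` (index `k`, 1 = trivial),
#'   `ca_axis` (`k - 1`, `NA` for the trivial axis), `eigenvalue`,
#'   `sqrt_eigenvalue` (the row-column score correlation magnitude), and
#'   `variation_share` (share of nontrivial inertia; `NA` for the trivial
#'   axis, which classical CA excludes from the total).
#' @method tidy ca_spectrum
#' @export
tidy.ca_spectrum <- function(x, ...) {
  lam <- x$eigenvalues
  K <- length(lam)
  inertia <- sum(lam[-1])
  tibble::tibble(
    eigenvector = seq_len(K),
    ca_axis = c(NA_integer_, seq_len(K - 1L)),
    eigenvalue = lam,
    sqrt_eigenvalue = sqrt(lam),
    variation_share = c(NA_real_,
                        if (K > 1) lam[-1] / max(inertia, .Machine$double.eps))
  )
}

#' @rdname tidy.ca_spectrum
#' @return For `glance()`: a one-row tibble with `n_rows`, `n_cols`,
#'   `total`, `n_components`, `total_inertia`, `leading_nontrivial`
#'   (the largest nontrivial eigenvalue) and `normalization`.
#' @method glance ca_spectrum
#' @export
glance.ca_spectrum <- function(x, ...) {
  lam <- x$eigenvalues
  tibble::tibble(
    n_rows = x$n_r, n_cols = x$n_c, total = x$total,
    n_components = x$n_components,
    total_inertia = sum(lam[-1]),
    leading_nontrivial = if (length(lam) > 1) lam[2] else NA_real_,
    normalization = x$normalization
  )
}

#' Tidy an embedding into one row per node
#'
#' @param x A [ca_embedding()].
#' @param ... Unused.
#' @return A tibble with `label`, `side`, and one `axis<k>` column per
#'   retained axis.
#' @method tidy ca_embedding
#' @export
tidy.ca_embedding <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$coordinates))
  dplyr::bind_cols(tibble::tibble(label = x$labels, side = x$side), out)
}

#' Tidy a recursive decomposition into one row per tree node
#'
#' @param x An [recursive_scca()] tree.
#' @param ... Unused.
#' @return A tibble with `node`, `parent`, `depth`, `leaf`, `size`, `K`,
#'   `quality`.
#' @method tidy scca_tree
#' @export
tidy.scca_tree <- function(x, ...) {
  purrr::map_dfr(tree_nodes(x), function(nd) {
    tibble::tibble(node = nd$id, parent = nd$parent, depth = nd$depth,
                   leaf = length(nd$children) == 0L, size = nd$size,
                   K = nd$K, quality = nd$quality)
  })
}

#' @rdname tidy.scca_tree
#' @return For `glance()`: a one-row tibble with `n_nodes`, `n_leaves`,
#'   `max_depth`, `seed`, `max_k`, `min_size`.
#' @method glance scca_tree
#' @export
glance.scca_tree <- function(x, ...) {
  depths <- vapply(tree_nodes(x), `[[`, integer(1), "depth")
  tibble::tibble(n_nodes = x$n_nodes, n_leaves = x$n_leaves,
                 max_depth = max(depths), seed = x$seed, max_k = x$max_k,
                 min_size = x$min_size)
}

#' Scree plot of a CA spectrum
#'
#' Eigenvalues in decreasing order with the eigengap position marked — the
#' visual used to judge how many weakly connected clusters the similarity
#' network contains.
#'
#' @param object A [ca_spectrum()].
#' @param max_k How many leading eigenvalues to display (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ca_spectrum
#' @export
autoplot.ca_spectrum <- function(object, max_k = 20, ...) {
  df <- tidy(object)
  df <- df[seq_len(min(max_k, nrow(df))), ]
  eg <- suppressWarnings(eigengap_count(object$eigenvalues, max_k = max_k))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$eigenvector,
                                   y = .data$eigenvalue)) +
    ggplot2::geom_vline(xintercept = eg$gap_position + 0.5,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "eigenvector index",
                  y = expression(lambda),
                  title = sprintf("Eigengap after position %d (K = %d)",
                                  eg$gap_position, eg$K)) +
    ggplot2::theme_minimal()
}

#' Correspondence plot of an embedding
#'
#' Scatter of two principal-coordinate axes, optionally coloured by cluster;
#' axis labels report each axis's variation share.
#'
#' @param object A [ca_embedding()].
#' @param axes Integer pair of CA axis indices (default `c(1, 2)`).
#' @param cluster_labels Optional cluster labels, one per node.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ca_embedding
#' @export
autoplot.ca_embedding <- function(object, axes = c(1, 2),
                                  cluster_labels = NULL, ...) {
  p <- ncol(object$coordinates)
  if (any(axes > p)) {
    stop(sprintf("Axis %s not available; embedding has axes 1..%d.",
                 paste(axes[axes > p], collapse = ", "), p), call. = FALSE)
  }
  df <- tibble::tibble(
    x = object$coordinates[, axes[1]],
    y = object$coordinates[, axes[2]],
    cluster = if (is.null(cluster_labels)) factor(1) else
      factor(cluster_labels)
  )
  lab <- function(k) sprintf("CA axis %d (%.1f%%)", k,
                             100 * object$variation_shares[k])
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  gg <- if (is.null(cluster_labels)) {
    gg + ggplot2::geom_point(alpha = 0.7)
  } else {
    gg + ggplot2::geom_point(ggplot2::aes(colour = .data$cluster),
                             alpha = 0.7)
  }
  gg + ggplot2::labs(x = lab(axes[1]), y = lab(axes[2]),
                     colour = "cluster") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
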