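#' Configuration for a reproducible analysis run
#'
#' Collects every knob of the file-based pipeline in one serializable
#' object; [run_pipeline()] echoes it into the output directory so a run can
#' be reproduced from its artifacts alone.
#'
#' @param input Path to the input table, or an [incidence_table()] directly.
#' @param format Input format, see [read_incidence()].
#' @param side `"row"` or `"column"`: which node set the recursive analysis
#'   partitions. Column-side analysis transposes the table.
#' @param max_k Eigengap search bound (default 20).
#' @param min_size Minimum split size (default 3).
#' @param seed Integer seed for all k-means runs (default 1).
#' @param normalization Score normalization, see [ca_spectrum()].
#' @param unit_tol Unit-eigenvalue tolerance for component counting.
#' @param out_dir Output directory (created if missing).
#' @return A list of class `scca_config`.
#' @export
scca_config <- function(input, out_dir, format = "auto",
                        side = c("row", "column"), max_k = 20, min_size = 3,
                        seed = 1, normalization = "unit-variance",
                        unit_tol = 1e-8) {
  side <- match.arg(side)
  structure(
    list(input = input, format = format, side = side,
         max_k = max_k, min_size = min_size, seed = seed,
         normalization = normalization, unit_tol = unit_tol,
         out_dir = out_dir),
    class = "scca_config"
  )
}

#' Run the full cluster-then-ordinate pipeline
#'
#' Loads the table, runs [recursive_scca()] and writes a reproducible output
#' bundle into `config$out_dir`:
#' \describe{
#'   \item{`spectrum.csv`}{root spectrum: eigenvector index, CA axis index,
#'     eigenvalue, its square root, variation share.}
#'   \item{`row_scores.csv` / `col_scores.csv`}{score matrices of the root
#'     spectrum.}
#'   \item{`cluster_tree.json`}{the recursive partition, see
#'     [tree_to_json()].}
#'   \item{`assignments.csv`}{flat (label, leaf, leaf-axis-1 score) table.}
#'   \item{`leaf_scores.csv`}{long table of within-leaf ordination scores.}
#'   \item{`run_log.json`}{config echo, dropped rows/columns, tolerances,
#'     seeds, and the eigengap decision trace at every node.}
#' }
#' Outputs carry no timestamps: re-running an identical configuration
#' produces byte-identical files.
#'
#' @param config An [scca_config()].
#' @return Invisibly, a list with the `tree`, root `spectrum`, the loaded
#'   `table`, and `paths` of the written files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "scca_config"))
  tab <- if (inherits(config$input, "incidence_table")) {
    config$input
  } else {
    read_incidence(config$input, format = config$format)
  }
  if (config$side == "column") {
    tab <- incidence_table(t(as_matrix_like(tab$values)),
                           row_labels = tab$col_labels,
                           col_labels = tab$row_labels)
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$out_dir, f)

  spec <- ca_spectrum(tab, normalization = config$normalization,
                      unit_tol = config$unit_tol)
  tree <- recursive_scca(tab, max_k = config$max_k,
                         min_size = config$min_size, seed = config$seed,
                         normalization = config$normalization)

  utils::write.csv(tidy(spec), path("spectrum.csv"), row.names = FALSE,
                   quote = FALSE)
  write_scores <- function(scores, labels, file) {
    df <- data.frame(label = labels, scores, check.names = FALSE)
    utils::write.csv(df, path(file), row.names = FALSE, quote = FALSE)
  }
  write_scores(spec$row_scores, rownames(spec$row_scores), "row_scores.csv")
  write_scores(spec$col_scores, rownames(spec$col_scores), "col_scores.csv")
  tree_to_json(tree, path("cluster_tree.json"))
  utils::write.csv(scca_assignments(tree), path("assignments.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(leaf_scores(tree), path("leaf_scores.csv"),
                   row.names = FALSE, quote = FALSE)

  trace <- purrr::map(tree_nodes(tree), function(node) {
    list(node = node$id,
         examined = as.numeric(node$eigengap$spectrum_prefix),
         gaps = as.numeric(node$eigengap$gaps),
         gap_position = node$eigengap$gap_position,
         K = node$K)
  })
  log <- list(
    config = unclass(config)[setdiff(names(config), "input")],
    input = if (is.character(config$input)) config$input else "<in-memory>",
    n_rows = nrow(tab$values), n_cols = ncol(tab$values),
    total = tab$total,
    dropped_rows = tab$dropped_rows, dropped_cols = tab$dropped_cols,
    n_components = spec$n_components,
    eigengap_trace = trace
  )
  jsonlite::write_json(log, path("run_log.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  paths <- vapply(c("spectrum.csv", "row_scores.csv", "col_scores.csv",
                    "cluster_tree.json", "assignments.csv",
                    "leaf_scores.csv", "run_log.json"), path, character(1))
  invisible(list(tree = tree, spectrum = spec, table = tab, paths = paths))
}

as_matrix_like <- function(x) if (inherits(x, "Matrix")) x else as.matrix(x)

# Long table of within-leaf ordination scores (one row per node, leaf, axis).
leaf_scores <- function(tree) {
  leaves <- purrr::keep(tree_nodes(tree), ~ length(.x$children) == 0L)
  purrr::map_dfr(leaves, function(nd) {
    if (is.null(nd$embedding)) {
      return(tibble::tibble(leaf = integer(0), label = character(0),
                            axis = integer(0), score = numeric(0),
                            variation_share = numeric(0)))
    }
    X <- nd$embedding$coordinates
    purrr::map_dfr(seq_len(ncol(X)), function(k) {
      tibble::tibble(leaf = nd$id, label = rownames(X), axis = k,
                     score = X[, k],
                     variation_share = nd$embedding$variation_shares[k])
    })
  })
}

#' Export correspondence-plot data
#'
#' Tabulates a pair of embedding axes — the classical correspondence plot,
#' usually axes 1 and 2 (eigenvectors 2 and 3) — together with optional
#' cluster labels and each axis's variation share, ready for plotting or
#' archiving. When `path` is given, the table is written as CSV preceded by
#' a comment line reporting the combined variation share of the two axes.
#'
#' @param embedding A [ca_embedding()].
#' @param axes Integer pair of CA axis indices (default `c(1, 2)`).
#' @param cluster_labels Optional vector of cluster labels, one per node (or
#'   a tibble from [kmeans_partition()]).
#' @param path Optional CSV output path.
#' @param plot If `TRUE`, also return a ggplot scatter (in element `plot`).
#' @return A tibble with columns `label`, `x_a`, `x_b`, `cluster`,
#'   `share_a`, `share_b` (invisibly when `path` is given). With
#'   `plot = TRUE`, a list with elements `data` and `plot`.
#' @export
export_correspondence_plot <- function(embedding, axes = c(1, 2),
                                       cluster_labels = NULL, path = NULL,
                                       plot = FALSE) {
  stopifnot(inherits(embedding, "ca_embedding"), length(axes) == 2)
  p <- ncol(embedding$coordinates)
  missing_ax <- axes[axes > p | axes < 1]
  if (length(missing_ax)) {
    stop(sprintf("Axis %s not available; embedding has axes 1..%d.",
                 paste(missing_ax, collapse = ", "), p), call. = FALSE)
  }
  if (tibble::is_tibble(cluster_labels) && "cluster" %in% names(cluster_labels)) {
    cluster_labels <- cluster_labels$cluster[
      match(embedding$labels, cluster_labels$label)]
  }
  out <- tibble::tibble(
    label = embedding$labels,
    x_a = embedding$coordinates[, axes[1]],
    x_b = embedding$coordinates[, axes[2]],
    cluster = if (is.null(cluster_labels)) NA_integer_ else cluster_labels,
    share_a = embedding$variation_shares[axes[1]],
    share_b = embedding$variation_shares[axes[2]]
  )
  gg <- NULL
  if (plot) {
    gg <- autoplot.ca_embedding(embedding, axes = axes,
                                cluster_labels = cluster_labels)
  }
  if (!is.null(path)) {
    header <- sprintf("# CA axes %d and %d: %.2f%% of variation explained",
                      axes[1], axes[2],
                      100 * sum(embedding$variation_shares[axes]))
    writeLines(header, path)
    suppressWarnings(
      utils::write.table(out, path, sep = ",", row.names = FALSE,
                         quote = FALSE, append = TRUE)
    )
    if (plot) return(invisible(list(data = out, plot = gg)))
    return(invisible(out))
  }
  if (plot) list(data = out, plot = gg) else out
}
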