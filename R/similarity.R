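#' Project a bipartite incidence table onto one node set
#'
#' Stochastic complementation collapses the bipartite network defined by `A`
#' onto its row layer (or column layer), giving the one-mode similarity
#' matrix `S_r = A %*% solve(D_c) %*% t(A)` (respectively
#' `S_c = t(A) %*% solve(D_r) %*% A`). Entry `S_r[i, l]` measures how many
#' columns rows `i` and `l` share, each shared column discounted by its
#' degree, so that ubiquitous columns contribute little. `S_r` is symmetric,
#' nonnegative, and its row sums reproduce the row degrees `r`, which makes
#' `D_r` both the degree matrix of the similarity network and the margin of
#' the original table.
#'
#' @param table An [incidence_table()].
#' @param side `"row"` to project onto row nodes, `"column"` for column nodes.
#' @return An object of class `ca_similarity`: list with `side`, `similarity`
#'   (dense symmetric matrix with labels), and `degrees` (the corresponding
#'   margins).
#' @examples
#' tab <- incidence_table(matrix(c(1, 1, 0, 0, 1, 1), 2, byrow = TRUE))
#' project_similarity(tab, "row")$similarity
#' #      [,1] [,2]
#' # r001  1.5  0.5
#' # r002  0.5  1.5
#' @export
project_similarity <- function(table, side = c("row", "column")) {
  stopifnot(inherits(table, "incidence_table"))
  side <- match.arg(side)
  A <- table$values
  if (side == "row") {
    S <- A %*% (t(A) / table$col_margins)
    degrees <- table$row_margins
    labels <- table$row_labels
  } else {
    S <- t(A) %*% (A / table$row_margins)
    degrees <- table$col_margins
    labels <- table$col_labels
  }
  S <- as.matrix(S)
  S <- (S + t(S)) / 2 # enforce exact symmetry against round-off
  dimnames(S) <- list(labels, labels)
  structure(
    list(side = side, similarity = S,
         degrees = stats::setNames(as.numeric(degrees), labels)),
    class = "ca_similarity"
  )
}

#' @export
print.ca_similarity <- function(x, ...) {
  cat(sprintf("<ca_similarity> %s-side projection, %d nodes, volume %g\n",
              x$side, nrow(x$similarity), sum(x$degrees)))
  invisible(x)
}

#' Generalized eigenpairs of the similarity-network Laplacian
#'
#' Solves `(D - S) v = lambda_tilde * D v`, the relaxed normalized-cut
#' problem on the similarity network, by symmetric eigendecomposition of
#' `I - D^{-1/2} S D^{-1/2}`. The generalized eigenvalues relate to the
#' correspondence-analysis eigenvalues by `lambda_tilde = 1 - lambda`, and the
#' eigenvectors coincide (up to sign and scale) with the CA row or column
#' scores; this function therefore serves as an independent numerical route
#' against [ca_spectrum()], which goes through the singular value
#' decomposition of the standardized table instead.
#'
#' The number of zero generalized eigenvalues equals the number of connected
#' components of the similarity network; the smallest is always 0 with a
#' constant eigenvector.
#'
#' @param graph A `ca_similarity` from [project_similarity()].
#' @param k_max Number of smallest eigenpairs to return (default: all).
#' @param tol Symmetry tolerance for rejecting a non-symmetric input.
#' @return A list with `values` (generalized eigenvalues, ascending) and
#'   `vectors` (columns matching `values`, scaled so that
#'   `sum(d * v^2) = sum(d)` with deterministic sign).
#' @export
laplacian_generalized_eigs <- function(graph, k_max = NULL, tol = 1e-8) {
  stopifnot(inherits(graph, "ca_similarity"))
  S <- graph$similarity
  if (max(abs(S - t(S))) > tol * max(abs(S))) {
    stop("Similarity matrix is not symmetric; refusing to solve.",
         call. = FALSE)
  }
  d <- graph$degrees
  if (any(d <= 0)) stop("All degrees must be positive.", call. = FALSE)
  ds <- 1 / sqrt(d)
  Nmat <- diag(nrow(S)) - (ds * S) * rep(ds, each = nrow(S))
  Nmat <- (Nmat + t(Nmat)) / 2
  eig <- eigen(Nmat, symmetric = TRUE)
  ord <- order(eig$values) # ascending lambda_tilde
  vals <- pmin(pmax(eig$values[ord], 0), 2)
  vecs <- eig$vectors[, ord, drop = FALSE]
  # back-transform: generalized eigenvector v = D^{-1/2} w, rescaled to the
  # degree-weighted unit-variance convention, deterministic orientation
  vecs <- vecs * ds
  scale <- sqrt(sum(d)) / sqrt(colSums(d * vecs^2))
  vecs <- sweep(vecs, 2, scale, `*`)
  vecs <- apply(vecs, 2, orient_vector)
  rownames(vecs) <- names(d)
  if (!is.null(k_max)) {
    k_max <- min(k_max, length(vals))
    vals <- vals[seq_len(k_max)]
    vecs <- vecs[, seq_len(k_max), drop = FALSE]
  }
  list(values = vals, vectors = vecs)
}

# Deterministic sign convention: the largest-magnitude entry is positive,
# ties broken toward the lowest index (which.max returns the first maximum).
orient_vector <- function(v) {
  idx <- which.max(abs(v))
  if (v[idx] < 0) -v else v
}
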