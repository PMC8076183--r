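#' Edge-wise row and column scores for one CA axis
#'
#' Reads the row and column scores of axis `k` along the edges of the
#' bipartite network: for every occurrence counted in the table (cells are
#' traversed in row-major order, and a cell with count `a` contributes `a`
#' identical edges), `y_r` records the score of the row node and `y_c` the
#' score of the column node. Under the unit-variance normalization these two
#' vectors have zero mean and unit variance, and their Pearson correlation
#' squared equals the eigenvalue of the axis — the identity that defines CA
#' as a canonical correlation analysis of the bipartite network (see
#' [score_correlation()]).
#'
#' @param table The [incidence_table()] the spectrum was computed from. Cell
#'   values must be (near-)integers, since they are expanded into discrete
#'   edges.
#' @param spectrum The matching [ca_spectrum()].
#' @param k Eigenvector index, `k >= 2` (the trivial axis `k = 1` has zero
#'   variance and no defined correlation).
#' @return An object of class `edge_scores`: list with `y_r`, `y_c` (numeric,
#'   length `n = sum(A)`), `axis` (the eigenvector index) and `eigenvalue`.
#' @examples
#' tab <- incidence_table(matrix(c(1, 1, 0, 0, 1, 1), 2, byrow = TRUE))
#' sp <- ca_spectrum(tab)
#' es <- edge_scores(tab, sp, k = 2)
#' score_correlation(es)^2 # 0.5, equal to sp$eigenvalues[2]
#' @export
edge_scores <- function(table, spectrum, k) {
  stopifnot(inherits(table, "incidence_table"),
            inherits(spectrum, "ca_spectrum"))
  if (k < 2) {
    stop("`k` must be >= 2: the trivial axis has zero variance, so the ",
         "edge-score correlation is undefined.", call. = FALSE)
  }
  if (k > length(spectrum$eigenvalues)) {
    stop(sprintf("Axis %d not available: spectrum holds %d eigenpairs.",
                 k, length(spectrum$eigenvalues)), call. = FALSE)
  }
  v <- spectrum$row_scores[, k]
  u <- spectrum$col_scores[, k]
  if (anyNA(v) || anyNA(u)) {
    stop(sprintf("Axis %d is beyond the paired rank (eigenvalue 0): no edge scores exist.",
                 k), call. = FALSE)
  }
  edges <- edge_list(table)
  structure(
    list(y_r = v[edges$row], y_c = u[edges$col],
         axis = k, eigenvalue = spectrum$eigenvalues[k]),
    class = "edge_scores"
  )
}

# Expand the table into its edge list (row-major), repeating each cell by its
# integer count. Shared by edge_scores() and the tests' enumeration oracle.
edge_list <- function(table) {
  A <- table$values
  if (inherits(A, "Matrix")) {
    trip <- Matrix::summary(methods::as(A, "TsparseMatrix"))
    ord <- order(trip$i, trip$j)
    i <- trip$i[ord]; j <- trip$j[ord]; a <- trip$x[ord]
  } else {
    nz <- which(t(A) != 0) # t() so enumeration is row-major
    j <- (nz - 1L) %% ncol(A) + 1L
    i <- (nz - 1L) %/% ncol(A) + 1L
    a <- A[cbind(i, j)]
  }
  if (any(abs(a - round(a)) > 1e-8)) {
    stop("Edge expansion requires integer cell counts; found non-integer ",
         "values. Weighted tables enter all spectral computations through ",
         "their margins instead.", call. = FALSE)
  }
  a <- as.integer(round(a))
  list(row = rep.int(i, a), col = rep.int(j, a))
}

#' @export
print.edge_scores <- function(x, ...) {
  cat(sprintf("<edge_scores> axis ev%d (CA axis %d), n = %d edges\n",
              x$axis, x$axis - 1L, length(x$y_r)))
  invisible(x)
}

#' Pearson correlation of edge-wise row and column scores
#'
#' For any nontrivial CA axis, the squared Pearson correlation between the
#' row scores and column scores read along the edges equals the axis
#' eigenvalue: `cor(y_r, y_c)^2 == lambda_k`. The sign of the correlation is
#' not fixed by the eigenproblem (both score vectors carry an arbitrary
#' orientation), so only its magnitude is informative.
#'
#' @param scores An [edge_scores()] object.
#' @return The signed Pearson correlation (a scalar).
#' @export
score_correlation <- function(scores) {
  stopifnot(inherits(scores, "edge_scores"))
  if (stats::sd(scores$y_r) == 0 || stats::sd(scores$y_c) == 0) {
    stop("Zero-variance edge scores: correlation is undefined.",
         call. = FALSE)
  }
  stats::cor(scores$y_r, scores$y_c)
}
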