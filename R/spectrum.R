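#' Correspondence analysis spectrum of an incidence table
#'
#' Solves the paired eigenproblem of simple correspondence analysis,
#' `solve(D_r) %*% A %*% solve(D_c) %*% t(A) %*% v = lambda * v` (and its
#' transpose for the column scores `u`), through the symmetrized operator
#' `M = D_r^{-1/2} A D_c^{-1/2}`: the eigenvalues are the squared singular
#' values of `M` and the score vectors are the degree-unscaled singular
#' vectors. The row-stochastic operator itself is non-symmetric, so this
#' route guarantees a real spectrum in `[0, 1]` and numerically stable,
#' orthogonal eigenvectors. Internally the decomposition is obtained from a
#' symmetric eigendecomposition of the Gram matrix of `M` on its smaller
#' side, which keeps the cost at `O(min(n_r, n_c)^3)` however wide or sparse
#' the table is; scores for the other side follow from the transition
#' formula `u = D_c^{-1} t(A) v / sqrt(lambda)`.
#'
#' The leading eigenvalue is always 1 with constant score vectors (the
#' trivial solution rejected by the centering constraint); the multiplicity
#' of eigenvalue 1 equals the number of connected components of the bipartite
#' network (see [count_components()]). Every nontrivial score vector `v_k`
#' satisfies the centering constraint `sum(r * v_k) = 0` (likewise `u_k` with
#' `c`). Each eigenvalue equals the squared Pearson correlation of the row
#' and column scores read along the edges of the network (see
#' [edge_scores()] and [score_correlation()]), and also measures the
#' normalized-cut quality of the corresponding bipartition of the similarity
#' network (see [laplacian_generalized_eigs()]).
#'
#' Axis indexing follows the convention that the k-th *nontrivial*
#' eigenvector carries subscript k+1: "CA axis 1" is eigenvector 2. All
#' outputs carry both indices.
#'
#' @param table An [incidence_table()].
#' @param k_max Number of leading eigenpairs to keep. Defaults to
#'   `min(n_r, n_c)`, the full paired spectrum. Values up to the size of the
#'   analysed side are allowed (with a warning) — axes beyond the rank have
#'   eigenvalue 0 and no paired scores on the opposite side.
#' @param normalization `"unit-variance"` (default): scores satisfy
#'   `sum(r * v) = 0` and `sum(r * v^2) = n`, so the edge-wise score vectors
#'   have zero mean and unit variance and the trivial vector is exactly 1.
#'   `"unit-norm"`: Euclidean norm 1 (`sum(v^2) = 1`). Rankings, clusters and
#'   correlations are invariant to this choice.
#' @param tol Numerical clipping tolerance: eigenvalues within `tol` outside
#'   `[0, 1]` are clipped.
#' @param unit_tol Tolerance for counting eigenvalues equal to 1 (connected
#'   components).
#' @return An object of class `ca_spectrum`: list with `eigenvalues`
#'   (descending, `lambda[1] = 1`), `row_scores` and `col_scores` (matrices
#'   with one column per eigenvector, named `ev1`, `ev2`, ...), `row_margins`,
#'   `col_margins`, `total`, `normalization`, `n_components`, and the table
#'   labels. Columns of `col_scores` beyond the paired rank are `NA`.
#' @examples
#' tab <- incidence_table(matrix(c(1, 1, 0, 0, 1, 1), 2, byrow = TRUE))
#' sp <- ca_spectrum(tab)
#' sp$eigenvalues       # 1.0 0.5
#' sp$row_scores[, 2]   # proportional to (1, -1)
#' @export
ca_spectrum <- function(table, k_max = NULL,
                        normalization = c("unit-variance", "unit-norm"),
                        tol = 1e-10, unit_tol = 1e-8) {
  stopifnot(inherits(table, "incidence_table"))
  normalization <- match.arg(normalization)
  A <- table$values
  n_r <- nrow(A)
  n_c <- ncol(A)
  r <- table$row_margins
  cc <- table$col_margins
  n <- table$total

  if (n_r == 1L || n_c == 1L) {
    warning("Table has a single row or column: only the trivial axis exists.",
            call. = FALSE)
    k_max <- 1L
  }
  if (is.null(k_max)) k_max <- min(n_r, n_c)
  if (k_max < 1L) stop("`k_max` must be at least 1.", call. = FALSE)
  if (k_max > max(n_r, n_c)) {
    warning(sprintf("`k_max` truncated to %d, the size of the larger side.",
                    max(n_r, n_c)), call. = FALSE)
    k_max <- max(n_r, n_c)
  }
  if (k_max > min(n_r, n_c)) {
    warning(paste("`k_max` exceeds min(n_r, n_c): trailing axes have",
                  "eigenvalue 0 and no paired scores on the smaller side."),
            call. = FALSE)
  }

  # standardized table M = D_r^{-1/2} A D_c^{-1/2}; kept sparse if A is
  M <- Matrix::Diagonal(n_r, 1 / sqrt(r)) %*% A %*%
    Matrix::Diagonal(n_c, 1 / sqrt(cc))

  # Gram side: the smaller dimension, unless k_max forces the larger side
  # (needed to materialize null-space axes past the rank).
  use_rows <- if (k_max > min(n_r, n_c)) n_r >= n_c else n_r <= n_c
  G <- if (use_rows) Matrix::tcrossprod(M) else Matrix::crossprod(M)
  G <- as.matrix(G)
  G <- (G + t(G)) / 2
  eig <- eigen(G, symmetric = TRUE)
  K <- min(k_max, ncol(eig$vectors))
  lambda <- eig$values[seq_len(K)]
  if (any(lambda < -tol) || any(lambda > 1 + 1e-6)) {
    warning("Eigenvalues outside [0, 1] beyond tolerance were clipped.",
            call. = FALSE)
  }
  lambda <- pmin(pmax(lambda, 0), 1)
  sigma <- sqrt(lambda)
  W <- eig$vectors[, seq_len(K), drop = FALSE] # orthonormal on the Gram side

  # paired singular vectors on the other side: Z = M' W / sigma (rank part);
  # axes with eigenvalue 0 at the clip tolerance have no paired scores
  rank_ok <- lambda > tol
  pair_of <- function(Wside, Mmat) {
    Z <- matrix(NA_real_, nrow = ncol(Mmat), ncol = K)
    if (any(rank_ok)) {
      Zr <- as.matrix(Matrix::crossprod(Mmat, Wside[, rank_ok, drop = FALSE]))
      Z[, rank_ok] <- sweep(Zr, 2, sigma[rank_ok], `/`)
    }
    Z
  }
  if (use_rows) {
    w_row <- W
    w_col <- pair_of(W, M)
  } else {
    w_col <- W
    w_row <- pair_of(W, t(M))
  }

  scale_scores <- function(Wmat, margins) {
    V <- Wmat / sqrt(margins)
    if (normalization == "unit-variance") {
      sc <- sqrt(n) / sqrt(colSums(margins * V^2))
    } else {
      sc <- 1 / sqrt(colSums(V^2))
    }
    V <- sweep(V, 2, sc, `*`)
    apply(V, 2, orient_vector)
  }
  ok_r <- !is.na(w_row[1, ])
  ok_c <- !is.na(w_col[1, ])
  row_scores <- matrix(NA_real_, n_r, K)
  col_scores <- matrix(NA_real_, n_c, K)
  if (any(ok_r)) {
    row_scores[, ok_r] <- scale_scores(w_row[, ok_r, drop = FALSE], r)
  }
  if (any(ok_c)) {
    col_scores[, ok_c] <- scale_scores(w_col[, ok_c, drop = FALSE], cc)
  }
  dimnames(row_scores) <- list(table$row_labels, paste0("ev", seq_len(K)))
  dimnames(col_scores) <- list(table$col_labels, paste0("ev", seq_len(K)))

  structure(
    list(
      eigenvalues = lambda,
      row_scores = row_scores,
      col_scores = col_scores,
      row_margins = r,
      col_margins = cc,
      total = n,
      normalization = normalization,
      n_components = sum(lambda >= 1 - unit_tol),
      unit_tol = unit_tol,
      n_r = n_r,
      n_c = n_c
    ),
    class = "ca_spectrum"
  )
}

#' @export
print.ca_spectrum <- function(x, ...) {
  K <- length(x$eigenvalues)
  cat(sprintf("<ca_spectrum> %d x %d table, %d eigenpair(s), %s scores\n",
              x$n_r, x$n_c, K, x$normalization))
  cat(sprintf("  connected components (eigenvalue 1 multiplicity): %d\n",
              x$n_components))
  show <- utils::head(x$eigenvalues, 8)
  cat("  eigenvalues:", paste(sprintf("%.4f", show), collapse = " "),
      if (K > 8) "...\n" else "\n")
  invisible(x)
}

#' Count connected components from the CA spectrum
#'
#' The multiplicity of eigenvalue 1 in the CA spectrum equals the number of
#' connected components of the bipartite network (equivalently, the number of
#' zero eigenvalues of the similarity-network Laplacian). Counting is done at
#' tolerance `tol`; the spectrum must extend far enough that some eigenvalue
#' below `1 - tol` was seen (or be complete), otherwise components may be
#' missed.
#'
#' @param spectrum A `ca_spectrum`.
#' @param tol Unit-eigenvalue tolerance (default `1e-8`).
#' @return Integer component count (at least 1).
#' @export
count_components <- function(spectrum, tol = 1e-8) {
  stopifnot(inherits(spectrum, "ca_spectrum"))
  lam <- spectrum$eigenvalues
  k <- sum(lam >= 1 - tol)
  if (k == length(lam) && spectrum$n_r > length(lam)) {
    warning("All computed eigenvalues are 1; increase `k_max` to be sure the ",
            "component count is not truncated.", call. = FALSE)
  }
  as.integer(max(1L, k))
}
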