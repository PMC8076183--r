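#' Principal-coordinate embedding of the similarity network
#'
#' Builds the graph embedding of the row-side (or column-side) similarity
#' network from a CA spectrum: axis `k` of the embedding is
#' `x_k = sqrt(lambda_{k+1}) * v_{k+1}`, the (k+1)-th eigenvector scaled by
#' the square root of its eigenvalue, with the trivial constant axis
#' excluded. Euclidean distances between node vectors in this embedding
#' approximate the chi-square distances between the node profiles, and the
#' share of total variation (inertia) carried by each axis is
#' `lambda_{k+1} / sum(lambda[-1])` — the trivial eigenvalue is excluded
#' from the total, following the classical CA convention.
#'
#' @param spectrum A [ca_spectrum()].
#' @param n_axes Number of nontrivial axes to retain (at least 1, at most the
#'   number of nontrivial eigenpairs in the spectrum).
#' @param side `"row"` or `"column"`: which node set to embed.
#' @return An object of class `ca_embedding`: list with `coordinates`
#'   (nodes x axes matrix, columns `axis1`, `axis2`, ... where `axis k` is
#'   eigenvector `k + 1`), `variation_shares`, `eigenvalues` (the nontrivial
#'   eigenvalues used), `side`, `labels`, and `inertia_total` (sum of all
#'   nontrivial eigenvalues in the spectrum).
#' @examples
#' tab <- incidence_table(matrix(c(1, 1, 0, 0, 1, 1), 2, byrow = TRUE))
#' emb <- ca_embed(ca_spectrum(tab), n_axes = 1)
#' emb$coordinates # sqrt(0.5) * v_2
#' @export
ca_embed <- function(spectrum, n_axes = NULL, side = c("row", "column")) {
  stopifnot(inherits(spectrum, "ca_spectrum"))
  side <- match.arg(side)
  lam <- spectrum$eigenvalues
  K <- length(lam)
  if (K < 2) {
    stop("Spectrum has no nontrivial axes to embed.", call. = FALSE)
  }
  scores <- if (side == "row") spectrum$row_scores else spectrum$col_scores
  if (is.null(n_axes)) n_axes <- K - 1L
  if (n_axes < 1) stop("`n_axes` must be at least 1.", call. = FALSE)
  if (n_axes > K - 1L) {
    stop(sprintf("`n_axes` = %d exceeds the %d nontrivial axes available.",
                 n_axes, K - 1L), call. = FALSE)
  }
  idx <- seq_len(n_axes) + 1L # eigenvector indices
  unpaired <- idx[is.na(scores[1, idx])]
  if (length(unpaired)) {
    stop(sprintf("Axes %s have no %s-side scores (beyond the paired rank).",
                 paste(unpaired, collapse = ", "), side), call. = FALSE)
  }
  coords <- sweep(scores[, idx, drop = FALSE], 2, sqrt(lam[idx]), `*`)
  colnames(coords) <- paste0("axis", seq_len(n_axes))
  inertia_total <- sum(lam[-1])
  shares <- if (inertia_total > 0) lam[idx] / inertia_total else
    rep(0, n_axes)
  structure(
    list(
      coordinates = coords,
      variation_shares = shares,
      eigenvalues = lam[idx],
      inertia_total = inertia_total,
      side = side,
      labels = rownames(scores)
    ),
    class = "ca_embedding"
  )
}

#' @export
print.ca_embedding <- function(x, ...) {
  cat(sprintf("<ca_embedding> %s side, %d nodes x %d axes (%.1f%% of variation)\n",
              x$side, nrow(x$coordinates), ncol(x$coordinates),
              100 * sum(x$variation_shares)))
  invisible(x)
}

#' Arch-effect diagnostic for a pair of embedding axes
#'
#' In tables driven by a single strong gradient, higher-order CA axes are
#' often near-polynomial functions of the leading axis rather than
#' independent structure — the "arch effect". A high coefficient of
#' determination of the least-squares quadratic regression of axis `axis_b`
#' on axis `axis_a` flags `axis_b` as such an artefact, carrying little
#' information beyond `axis_a`.
#'
#' @param embedding A [ca_embedding()].
#' @param axis_a,axis_b CA axis indices within the embedding (axis 1 is
#'   eigenvector 2). Defaults: 1 and 2.
#' @return The R-squared of the quadratic fit (scalar in `[0, 1]`).
#' @export
arch_diagnostic <- function(embedding, axis_a = 1, axis_b = 2) {
  stopifnot(inherits(embedding, "ca_embedding"))
  p <- ncol(embedding$coordinates)
  if (axis_a > p || axis_b > p || axis_a < 1 || axis_b < 1) {
    stop(sprintf("Requested axes %d, %d; embedding has axes 1..%d.",
                 axis_a, axis_b, p), call. = FALSE)
  }
  a <- embedding$coordinates[, axis_a]
  b <- embedding$coordinates[, axis_b]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("Degenerate (constant) axis: quadratic fit is undefined.",
         call. = FALSE)
  }
  fit <- stats::lm(b ~ a + I(a^2))
  summary(fit)$r.squared
}
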