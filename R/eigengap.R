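#' Estimate the cluster count with the eigengap heuristic
#'
#' The number of weakly connected clusters in the similarity network is
#' estimated as the number of eigenvalues that precede the largest
#' consecutive drop ("eigengap") in the descending spectrum. The trivial
#' eigenvalue 1 is included in the count: a spectrum like
#' `(1, 0.98, 0.40, ...)` has its largest drop after position 2, giving
#' `K = 2` clusters, while a connected structureless table drops immediately
#' after the trivial eigenvalue, giving `K = 1` (no subdivision). Ties
#' between equal largest drops are broken toward the smaller `K` —
#' conservative splitting avoids artificial cuts.
#'
#' @param eigenvalues Numeric vector, sorted descending (as returned in
#'   `ca_spectrum()$eigenvalues`).
#' @param max_k Search bound: only the first `max_k` eigenvalues are
#'   examined (default 20).
#' @return An object of class `eigengap_decision`: list with
#'   `spectrum_prefix` (the examined eigenvalues), `gaps` (consecutive
#'   differences), `gap_position` (index of the largest gap) and `K`
#'   (the cluster-count estimate, equal to `gap_position`).
#' @examples
#' eigengap_count(c(1, 0.99, 0.97, 0.30, 0.28))$K # 3
#' @export
eigengap_count <- function(eigenvalues, max_k = 20) {
  if (is.unsorted(rev(eigenvalues), strictly = FALSE)) {
    stop("`eigenvalues` must be sorted in descending order.", call. = FALSE)
  }
  m <- min(max_k, length(eigenvalues))
  prefix <- eigenvalues[seq_len(m)]
  if (m < 2) {
    warning("Fewer than 2 eigenvalues examined: returning K = 1.",
            call. = FALSE)
    return(structure(list(spectrum_prefix = prefix, gaps = numeric(0),
                          gap_position = 1L, K = 1L),
                     class = "eigengap_decision"))
  }
  gaps <- prefix[-m] - prefix[-1]
  pos <- which.max(gaps) # first maximum: ties break toward smaller K
  structure(
    list(spectrum_prefix = prefix, gaps = gaps,
         gap_position = as.integer(pos), K = as.integer(pos)),
    class = "eigengap_decision"
  )
}

#' @export
print.eigengap_decision <- function(x, ...) {
  cat(sprintf("<eigengap_decision> K = %d (largest gap %.4f after position %d of %d examined)\n",
              x$K, if (length(x$gaps)) max(x$gaps) else NA_real_,
              x$gap_position, length(x$spectrum_prefix)))
  invisible(x)
}

#' Normalized-cut quality of a K-way partition
#'
#' The quality of partitioning the similarity network into `K` clusters, as
#' measured by the relaxed normalized-cut objective, is the average of the
#' first `K` eigenvalues, `mean(eigenvalues[1:K])`. It equals 1 exactly when
#' the network splits into `K` fully disconnected components, and decreases
#' as the clusters become more interconnected. For a fixed descending
#' spectrum it is non-increasing in `K`.
#'
#' @param eigenvalues Descending numeric vector of CA eigenvalues.
#' @param K Number of clusters, `1 <= K <= length(eigenvalues)`.
#' @return Scalar quality in `[0, 1]`.
#' @examples
#' partition_quality(c(1, 0.5), K = 2) # 0.75
#' @export
partition_quality <- function(eigenvalues, K) {
  if (length(K) != 1 || K < 1) {
    stop("`K` must be a positive integer.", call. = FALSE)
  }
  if (K > length(eigenvalues)) {
    stop(sprintf("`K` = %d exceeds the %d available eigenvalues.",
                 K, length(eigenvalues)), call. = FALSE)
  }
  mean(eigenvalues[seq_len(K)])
}
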