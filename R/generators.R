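#' Stylized bipartite network generators
#'
#' Four generator families produce incidence matrices with planted
#' structure, spanning the qualitative regimes a spectral analysis must
#' distinguish: unstructured tables, a single smooth gradient, weakly
#' connected clusters, and clusters that each contain a gradient. Every
#' generator is a pure function of its parameters and `seed`; the planted
#' ground truth (block labels and/or gradient order) is attached to the
#' returned table as the `"planted"` attribute, retrievable with
#' [planted_structure()].
#'
#' All generators re-draw (bounded retries, advancing the seed
#' deterministically) until the realized network is connected, has no empty
#' rows or columns and — for block families with `noise = 0` — each block is
#' internally connected, so the planted component structure is exactly the
#' realized one.
#'
#' @name generators
#' @return An [incidence_table()] with attribute `"planted"`, a list with at
#'   least `family`, `params`, and `seed`; block families add `row_block`
#'   and `col_block` integer vectors, gradient families add `row_order` and
#'   `col_order`.
NULL

max_retries <- 100L

#' @describeIn generators i.i.d. Bernoulli(`p`) incidence matrix: a random
#'   bipartite network with no planted structure (its nontrivial eigenvalues
#'   are uniformly small).
#' @param n_r,n_c Numbers of row and column nodes.
#' @param p Edge probability in `(0, 1)`.
#' @param seed Integer seed.
#' @export
random_bipartite <- function(n_r = 50, n_c = 50, p = 0.2, seed = 1) {
  stopifnot(p > 0, p < 1, n_r >= 2, n_c >= 2)
  if (p * n_c < 1 || p * n_r < 1) {
    warning("Expected degree below 1: the network is unlikely to connect.",
            call. = FALSE)
  }
  A <- draw_until_valid(seed, function() {
    matrix(stats::rbinom(n_r * n_c, 1L, p), n_r, n_c)
  })
  tab <- incidence_table(A, drop_empty = FALSE)
  attr(tab, "planted") <- list(
    family = "random",
    params = list(n_r = n_r, n_c = n_c, p = p),
    seed = seed
  )
  tab
}

#' @describeIn generators band-diagonal gradient table:
#'   `P(A[i, j] = 1) = p_in` when `|i/n_r - j/n_c| <= bandwidth / 2`, zero
#'   outside the band. The planted gradient order is the row (column) index;
#'   the first CA axis recovers it and higher axes show the arch effect.
#' @param bandwidth Full width of the band, in units of the normalized index
#'   `i / n_r` (so the band keeps cells with
#'   `abs(i / n_r - j / n_c) <= bandwidth / 2`). The index difference spans
#'   `[-1, 1]`, so `bandwidth = 2` covers every cell, recovering the random
#'   family with density `p_in`.
#' @param p_in Within-band (or within-block) edge probability.
#' @export
gradient_band <- function(n_r = 60, n_c = 60, bandwidth = 0.75, p_in = 0.9,
                          seed = 1) {
  stopifnot(bandwidth > 0, bandwidth <= 2, p_in > 0, p_in <= 1,
            n_r >= 2, n_c >= 2)
  mask <- band_mask(n_r, n_c, bandwidth)
  A <- draw_until_valid(seed, function() {
    matrix(stats::rbinom(n_r * n_c, 1L, p_in), n_r, n_c) * mask
  }, error_hint = "increase `bandwidth` or `p_in`")
  tab <- incidence_table(A, drop_empty = FALSE)
  attr(tab, "planted") <- list(
    family = "gradient",
    params = list(n_r = n_r, n_c = n_c, bandwidth = bandwidth, p_in = p_in),
    seed = seed,
    row_order = seq_len(n_r),
    col_order = seq_len(n_c)
  )
  tab
}

# Cells within `bandwidth/2` of the diagonal in normalized index coordinates.
band_mask <- function(n_r, n_c, bandwidth) {
  di <- outer(seq_len(n_r) / n_r, seq_len(n_c) / n_c, `-`)
  (abs(di) <= bandwidth / 2 + 1e-12) * 1L
}

#' @describeIn generators block-diagonal table of `n_blocks` random
#'   bipartite blocks with off-block entries drawn Bernoulli(`noise`). With
#'   `noise = 0` the components are exactly the blocks (eigenvalue 1 with
#'   multiplicity `n_blocks`); small positive noise yields weakly connected
#'   clusters with leading eigenvalues close to 1.
#' @param n_blocks Number of diagonal blocks (at least 2).
#' @param block_shape Integer pair `c(rows, cols)` per block (recycled
#'   across blocks), or a list of per-block pairs.
#' @param noise Between-block edge probability, `0 <= noise < p_in`.
#' @export
blocks <- function(n_blocks = 2, block_shape = c(30, 40), p_in = 0.3,
                   noise = 0.01, seed = 1) {
  build_blocks(n_blocks, block_shape, p_in, noise, seed,
               family = "blocks", bandwidth = NULL)
}

#' @describeIn generators like [blocks()], but each diagonal block carries a
#'   band-diagonal gradient drawn as in [gradient_band()]. The spectrum
#'   shows `2 * n_blocks` leading eigenvalues separated from the bulk:
#'   `n_blocks` near-unit cluster eigenvalues followed by one gradient
#'   eigenvalue per block.
#' @export
blocks_with_gradients <- function(n_blocks = 2, block_shape = c(30, 40),
                                  bandwidth = 0.75, p_in = 0.9, noise = 0.01,
                                  seed = 1) {
  stopifnot(bandwidth > 0, bandwidth <= 2)
  build_blocks(n_blocks, block_shape, p_in, noise, seed,
               family = "blocks_with_gradients", bandwidth = bandwidth)
}

build_blocks <- function(n_blocks, block_shape, p_in, noise, seed, family,
                         bandwidth) {
  stopifnot(n_blocks >= 2, p_in > 0, p_in <= 1, noise >= 0, noise < p_in)
  shapes <- if (is.list(block_shape)) block_shape else
    rep(list(as.integer(block_shape)), n_blocks)
  stopifnot(length(shapes) == n_blocks,
            all(vapply(shapes, length, 1L) == 2L))
  nr_b <- vapply(shapes, `[`, 1L, 1L)
  nc_b <- vapply(shapes, `[`, 2L, 2L)
  n_r <- sum(nr_b)
  n_c <- sum(nc_b)
  row_block <- rep(seq_len(n_blocks), nr_b)
  col_block <- rep(seq_len(n_blocks), nc_b)

  draw_one <- function() {
    A <- if (noise > 0) {
      matrix(stats::rbinom(n_r * n_c, 1L, noise), n_r, n_c)
    } else {
      matrix(0L, n_r, n_c)
    }
    for (b in seq_len(n_blocks)) {
      rows <- which(row_block == b)
      cols <- which(col_block == b)
      blk <- matrix(stats::rbinom(length(rows) * length(cols), 1L, p_in),
                    length(rows), length(cols))
      if (!is.null(bandwidth)) {
        blk <- blk * band_mask(length(rows), length(cols), bandwidth)
      }
      A[rows, cols] <- blk
    }
    A
  }
  valid <- function(A) {
    if (any(Matrix::rowSums(A) == 0) || any(Matrix::colSums(A) == 0)) {
      return(FALSE)
    }
    if (noise == 0) {
      # each block must be internally connected so components == blocks
      all(vapply(seq_len(n_blocks), function(b) {
        bipartite_connected(A[row_block == b, col_block == b, drop = FALSE])
      }, logical(1)))
    } else {
      bipartite_connected(A)
    }
  }
  A <- draw_until_valid(seed, draw_one, valid = valid,
                        error_hint = "increase `p_in` or the block sizes")
  tab <- incidence_table(A, drop_empty = FALSE)
  planted <- list(
    family = family,
    params = list(n_blocks = n_blocks, block_shape = shapes, p_in = p_in,
                  noise = noise, bandwidth = bandwidth),
    seed = seed,
    row_block = row_block,
    col_block = col_block
  )
  if (!is.null(bandwidth)) {
    planted$row_order <- stats::ave(seq_len(n_r), row_block, FUN = seq_along)
    planted$col_order <- stats::ave(seq_len(n_c), col_block, FUN = seq_along)
  }
  attr(tab, "planted") <- planted
  tab
}

# Seeded rejection sampling: draw with seed, seed + 1, ... until `valid`
# holds (default: no empty margins and connected), up to max_retries.
draw_until_valid <- function(seed, draw, valid = NULL, error_hint = NULL) {
  if (is.null(valid)) {
    valid <- function(A) {
      !any(Matrix::rowSums(A) == 0) && !any(Matrix::colSums(A) == 0) &&
        bipartite_connected(A)
    }
  }
  for (attempt in seq_len(max_retries)) {
    A <- local_seed(seed + attempt - 1L, draw())
    if (valid(A)) return(A)
  }
  stop(sprintf("No valid draw in %d attempts%s.", max_retries,
               if (is.null(error_hint)) "" else paste0(" (", error_hint, ")")),
       call. = FALSE)
}

# Breadth-first search over the bipartite graph: TRUE when a single
# connected component spans all rows and columns.
bipartite_connected <- function(A) {
  n_r <- nrow(A)
  n_c <- ncol(A)
  seen_r <- logical(n_r)
  seen_c <- logical(n_c)
  queue_r <- 1L
  seen_r[1L] <- TRUE
  repeat {
    new_c <- integer(0)
    for (i in queue_r) {
      js <- which(A[i, ] != 0 & !seen_c)
      seen_c[js] <- TRUE
      new_c <- c(new_c, js)
    }
    if (!length(new_c)) break
    queue_r <- integer(0)
    for (j in new_c) {
      is <- which(A[, j] != 0 & !seen_r)
      seen_r[is] <- TRUE
      queue_r <- c(queue_r, is)
    }
    if (!length(queue_r)) break
  }
  all(seen_r) && all(seen_c)
}

#' Planted ground truth of a generated table
#'
#' @param table A table produced by one of the [generators].
#' @return The planted-structure list, or `NULL` for tables without one.
#' @export
planted_structure <- function(table) attr(table, "planted")

#' Binarize a weighted table by revealed comparative advantage
#'
#' Converts a nonnegative weighted table (e.g. country-by-product export
#' values) into a presence-absence incidence table using the Balassa index
#' `RCA[i, j] = (A[i, j] / r_i) / (c_j / n)`: cell `(i, j)` is a presence
#' when row `i`'s share of item `j` exceeds the item's global share, i.e.
#' `RCA >= threshold`. Rows or columns with zero margin are dropped first
#' (logged in the result), as are rows/columns left empty by thresholding.
#'
#' @param weights Nonnegative numeric matrix or data frame (a first
#'   character column is taken as row labels).
#' @param threshold Balassa cutoff, default 1 (the standard rule).
#' @return An [incidence_table()] of 0/1 presences.
#' @examples
#' w <- matrix(c(10, 0, 1, 9), 2, byrow = TRUE)
#' as.matrix(binarize_rca(w)) # diag(2) pattern
#' @export
binarize_rca <- function(weights, threshold = 1) {
  tab <- incidence_table(weights, drop_empty = TRUE)
  A <- as.matrix(tab$values)
  rca <- (A / tab$row_margins) /
    rep(tab$col_margins / tab$total, each = nrow(A))
  out <- incidence_table((rca >= threshold) * 1L,
                         row_labels = tab$row_labels,
                         col_labels = tab$col_labels,
                         drop_empty = TRUE)
  out$dropped_rows <- union(tab$dropped_rows, out$dropped_rows)
  out$dropped_cols <- union(tab$dropped_cols, out$dropped_cols)
  out
}

#' Write a generated table with its planted ground truth
#'
#' Emits the MatrixMarket table (with `.rows`/`.cols` label files) alongside
#' a `<path>.planted.json` file so that planted metadata round-trips through
#' export and import (see [read_generated()]).
#'
#' @param table A generated [incidence_table()] carrying planted structure.
#' @param path Output path for the `.mtx` file.
#' @return `path`, invisibly.
#' @export
write_generated <- function(table, path) {
  write_incidence(table, path, format = "mtx")
  planted <- planted_structure(table)
  if (!is.null(planted)) {
    jsonlite::write_json(planted, paste0(path, ".planted.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_generated
#' @export
read_generated <- function(path) {
  tab <- read_incidence(path, format = "mtx")
  pj <- paste0(path, ".planted.json")
  if (file.exists(pj)) {
    planted <- jsonlite::read_json(pj, simplifyVector = TRUE)
    bs <- planted$params$block_shape
    if (!is.null(bs) && (is.matrix(bs) || is.data.frame(bs))) {
      planted$params$block_shape <-
        lapply(seq_len(nrow(bs)), function(i) as.integer(unlist(bs[i, ])))
    }
    attr(tab, "planted") <- planted
  }
  tab
}
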