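#' Build an incidence table from a matrix or data frame
#'
#' An incidence table is a nonnegative contingency table `A` (counts or 0/1
#' presence-absence) viewed as the bi-adjacency matrix of a bipartite network:
#' rows are one node set (e.g. species), columns the other (e.g. sites), and
#' `A[i, j]` counts joint occurrences. The constructor validates the entries,
#' computes the row margins `r_i = sum_j A[i, j]`, column margins
#' `c_j = sum_i A[i, j]` and grand total `n = sum(A)`, and (by default) removes
#' empty rows and columns so that every margin is strictly positive — a
#' requirement of the degree-normalized operators used downstream. Removals
#' are recorded in the returned object.
#'
#' Tables with density below 5% are stored sparse (a `Matrix::dgCMatrix`);
#' denser tables are stored as a base matrix. All downstream operations accept
#' either representation.
#'
#' @param x A nonnegative numeric matrix, a sparse `Matrix`, or a data frame.
#'   For a data frame whose first column is character (or factor), that column
#'   is taken as the row labels and the remaining columns as the table.
#' @param row_labels,col_labels Optional character vectors of unique
#'   identifiers; default to the dimnames of `x`, or `r001.../c001...` when
#'   absent.
#' @param drop_empty Drop all-zero rows and columns (default `TRUE`). With
#'   `drop_empty = FALSE` an empty row or column is an error.
#' @return An object of class `incidence_table`: a list with elements
#'   `values` (the matrix), `row_labels`, `col_labels`, `row_margins`,
#'   `col_margins`, `total`, `density`, and `dropped_rows`/`dropped_cols`
#'   (labels removed at construction).
#' @examples
#' A <- matrix(c(1, 1, 0, 0, 1, 1), nrow = 2, byrow = TRUE)
#' tab <- incidence_table(A)
#' tab$row_margins # 2 2
#' tab$total       # 4
#' @seealso [read_incidence()], [project_similarity()], [ca_spectrum()]
#' @export
incidence_table <- function(x, row_labels = NULL, col_labels = NULL,
                            drop_empty = TRUE) {
  if (is.data.frame(x)) {
    if (ncol(x) > 1 && (is.character(x[[1]]) || is.factor(x[[1]]))) {
      if (is.null(row_labels)) row_labels <- as.character(x[[1]])
      x <- as.matrix(x[, -1, drop = FALSE])
    } else {
      x <- as.matrix(x)
    }
  }
  if (!(is.matrix(x) || inherits(x, "Matrix"))) {
    stop("`x` must be a matrix, Matrix, or data frame.", call. = FALSE)
  }
  if (is.matrix(x) && !is.numeric(x)) {
    stop("`x` must be numeric.", call. = FALSE)
  }
  if (nrow(x) == 0L || ncol(x) == 0L) {
    stop("`x` must have at least one row and one column.", call. = FALSE)
  }

  if (is.null(row_labels)) row_labels <- rownames(x)
  if (is.null(col_labels)) col_labels <- colnames(x)
  if (is.null(row_labels)) row_labels <- sprintf("r%03d", seq_len(nrow(x)))
  if (is.null(col_labels)) col_labels <- sprintf("c%03d", seq_len(ncol(x)))
  if (length(row_labels) != nrow(x) || anyDuplicated(row_labels)) {
    stop("`row_labels` must be unique and match nrow(x).", call. = FALSE)
  }
  if (length(col_labels) != ncol(x) || anyDuplicated(col_labels)) {
    stop("`col_labels` must be unique and match ncol(x).", call. = FALSE)
  }
  rownames(x) <- row_labels
  colnames(x) <- col_labels

  check_nonnegative(x)
  if (sum(x) <= 0) {
    stop("The table is all zero: total count must be positive.", call. = FALSE)
  }

  r <- as.numeric(Matrix::rowSums(x))
  cc <- as.numeric(Matrix::colSums(x))
  dropped_rows <- character(0)
  dropped_cols <- character(0)
  if (any(r == 0) || any(cc == 0)) {
    if (!drop_empty) {
      stop("Table has empty rows or columns; rerun with `drop_empty = TRUE`.",
           call. = FALSE)
    }
    dropped_rows <- row_labels[r == 0]
    dropped_cols <- col_labels[cc == 0]
    x <- x[r > 0, cc > 0, drop = FALSE]
    row_labels <- row_labels[r > 0]
    col_labels <- col_labels[cc > 0]
    r <- as.numeric(Matrix::rowSums(x))
    cc <- as.numeric(Matrix::colSums(x))
  }

  nnz <- sum(x != 0)
  density <- nnz / (nrow(x) * ncol(x))
  if (density < 0.05 && !inherits(x, "CsparseMatrix")) {
    x <- methods::as(methods::as(Matrix::Matrix(x, sparse = TRUE), "generalMatrix"),
                     "CsparseMatrix")
  } else if (density >= 0.05 && inherits(x, "Matrix")) {
    x <- as.matrix(x)
    rownames(x) <- row_labels
    colnames(x) <- col_labels
  }

  structure(
    list(
      values = x,
      row_labels = row_labels,
      col_labels = col_labels,
      row_margins = stats::setNames(r, row_labels),
      col_margins = stats::setNames(cc, col_labels),
      total = sum(r),
      density = density,
      dropped_rows = dropped_rows,
      dropped_cols = dropped_cols
    ),
    class = "incidence_table"
  )
}

# Locate and report negative entries by label; works for dense and sparse.
check_nonnegative <- function(x) {
  if (inherits(x, "Matrix")) {
    trip <- Matrix::summary(methods::as(x, "TsparseMatrix"))
    bad <- which(trip$x < 0)
    if (length(bad)) {
      i <- trip$i[bad[1]]
      j <- trip$j[bad[1]]
      stop(sprintf("Negative entry at row '%s', column '%s' (value %g).",
                   rownames(x)[i], colnames(x)[j], trip$x[bad[1]]),
           call. = FALSE)
    }
  } else {
    bad <- which(x < 0, arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("Negative entry at row '%s', column '%s' (value %g).",
                   rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]],
                   x[bad[1, 1], bad[1, 2]]),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
dim.incidence_table <- function(x) dim(x$values)

#' @export
as.matrix.incidence_table <- function(x, ...) as.matrix(x$values)

#' @export
print.incidence_table <- function(x, ...) {
  cat(sprintf("<incidence_table> %d rows x %d columns, total n = %g (density %.1f%%)\n",
              nrow(x$values), ncol(x$values), x$total, 100 * x$density))
  if (length(x$dropped_rows) || length(x$dropped_cols)) {
    cat(sprintf("  dropped at load: %d empty row(s), %d empty column(s)\n",
                length(x$dropped_rows), length(x$dropped_cols)))
  }
  invisible(x)
}

#' Read an incidence table from a file
#'
#' Supports dense delimited text (CSV/TSV with a header row of column labels
#' and a first column of row labels) and MatrixMarket coordinate format
#' (`.mtx`) with row/column labels supplied as separate plain-text files, one
#' label per line.
#'
#' @param path Path to the table file.
#' @param format `"auto"` (from the file extension), `"csv"`, `"tsv"`, or
#'   `"mtx"`.
#' @param row_labels_file,col_labels_file For `mtx` input, paths to the label
#'   files. Defaults to `<path>.rows` / `<path>.cols` when they exist.
#' @param drop_empty Passed to [incidence_table()].
#' @return An [incidence_table()].
#' @export
read_incidence <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                           row_labels_file = NULL, col_labels_file = NULL,
                           drop_empty = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("Input file not found: '%s'.", path), call. = FALSE)
  }
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", tab = "tsv", txt = "tsv",
                     mtx = "mtx",
                     stop(sprintf("Cannot infer format from extension of '%s'.",
                                  path), call. = FALSE))
  }
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE, comment.char = "#")
    return(incidence_table(as.matrix(df), drop_empty = drop_empty))
  }
  m <- Matrix::readMM(path)
  if (is.null(row_labels_file) && file.exists(paste0(path, ".rows"))) {
    row_labels_file <- paste0(path, ".rows")
  }
  if (is.null(col_labels_file) && file.exists(paste0(path, ".cols"))) {
    col_labels_file <- paste0(path, ".cols")
  }
  rl <- if (!is.null(row_labels_file)) readLines(row_labels_file) else NULL
  cl <- if (!is.null(col_labels_file)) readLines(col_labels_file) else NULL
  m <- m * 1 # pattern/logical MatrixMarket content becomes numeric
  incidence_table(methods::as(m, "CsparseMatrix"),
                  row_labels = rl, col_labels = cl, drop_empty = drop_empty)
}

#' Write an incidence table to a file
#'
#' Inverse of [read_incidence()]: dense CSV/TSV with labels in the header and
#' first column, or MatrixMarket coordinate format with `<path>.rows` and
#' `<path>.cols` label files.
#'
#' @param table An [incidence_table()].
#' @param path Output path.
#' @param format `"auto"`, `"csv"`, `"tsv"`, or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_incidence <- function(table, path, format = c("auto", "csv", "tsv", "mtx")) {
  stopifnot(inherits(table, "incidence_table"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", mtx = "mtx", "csv")
  }
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    m <- as.matrix(table$values)
    df <- data.frame(label = table$row_labels, m, check.names = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  } else {
    sm <- methods::as(methods::as(Matrix::Matrix(table$values, sparse = TRUE),
                                  "generalMatrix"), "CsparseMatrix")
    Matrix::writeMM(sm, path)
    writeLines(table$row_labels, paste0(path, ".rows"))
    writeLines(table$col_labels, paste0(path, ".cols"))
  }
  invisible(path)
}
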