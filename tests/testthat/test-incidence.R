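test_that("margins and total are direct sums of the entries", {
  tab <- small_table()
  expect_equal(unname(tab$row_margins), c(2, 2))
  expect_equal(unname(tab$col_margins), c(1, 2, 1))
  expect_equal(tab$total, 4)
  # stored margins always match recomputation from values
  expect_equal(unname(tab$row_margins), unname(rowSums(as.matrix(tab))))
  expect_equal(unname(tab$col_margins), unname(colSums(as.matrix(tab))))
})

test_that("empty rows and columns are dropped and logged", {
  A <- matrix(c(1, 0, 1,
                0, 0, 0,
                1, 0, 1), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("sp", 1:3), paste0("site", 1:3)))
  tab <- incidence_table(A)
  expect_equal(dim(tab), c(2L, 2L))
  expect_equal(tab$dropped_rows, "sp2")
  expect_equal(tab$dropped_cols, "site2")
  expect_true(all(tab$row_margins > 0))
  expect_error(incidence_table(A, drop_empty = FALSE), "empty")
})

test_that("invalid tables are rejected with the offending cell named", {
  A <- matrix(c(1, 2, -1, 3), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(incidence_table(A), "row 'a'.*column 'y'")
  expect_error(incidence_table(matrix(0, 2, 2)), "all zero")
})

test_that("data frames with a label column are accepted", {
  df <- data.frame(species = c("a", "b"),
                   s1 = c(1, 0), s2 = c(1, 1), s3 = c(0, 1))
  tab <- incidence_table(df)
  expect_equal(tab$row_labels, c("a", "b"))
  expect_equal(unname(as.matrix(tab)), unname(as.matrix(small_table())))
})

test_that("CSV and MatrixMarket IO round-trip values and labels", {
  tab <- small_table()
  csv <- withr::local_tempfile(fileext = ".csv")
  write_incidence(tab, csv)
  back <- read_incidence(csv)
  expect_equal(as.matrix(back), as.matrix(tab))
  expect_equal(back$row_labels, tab$row_labels)

  mtx <- withr::local_tempfile(fileext = ".mtx")
  write_incidence(tab, mtx, format = "mtx")
  back2 <- read_incidence(mtx)
  expect_equal(unname(as.matrix(back2)), unname(as.matrix(tab)))
  expect_equal(back2$col_labels, tab$col_labels)

  expect_error(read_incidence("no/such/file.csv"), "not found")
})

test_that("sparse tables are stored sparse and analysed identically", {
  set.seed(42)
  A <- matrix(rbinom(60 * 80, 1, 0.02), 60, 80)
  A[1, ] <- 1; A[, 1] <- 1 # keep margins positive and connected
  tab <- incidence_table(A)
  expect_s4_class(tab$values, "CsparseMatrix")
  dense <- incidence_table(A)
  dense$values <- as.matrix(A)
  expect_equal(ca_spectrum(tab)$eigenvalues, ca_spectrum(dense)$eigenvalues,
               tolerance = 1e-10)
})
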