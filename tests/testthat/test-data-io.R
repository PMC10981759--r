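test_that("CSV and MTX round trips preserve the matrix entrywise", {
  set.seed(11)
  m <- expression_matrix(matrix(rpois(3 * 4, 5), 3, 4),
                         cell_ids = c("c1", "c2", "c3"),
                         gene_ids = c("gA", "gB", "gC", "gD"))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_expression(m, csv, "csv")
  m2 <- read_expression(csv, "csv")
  expect_equal(dim(m2), c(3L, 4L))
  expect_identical(m2$cell_ids, m$cell_ids)
  expect_identical(m2$gene_ids, m$gene_ids)
  expect_equal(m2$values, m$values)

  mtx <- withr::local_tempdir()
  write_expression(m, mtx, "mtx_dir")
  m3 <- read_expression(mtx, "mtx_dir")
  expect_equal(m3$values, m$values)

  # genes x cells on disk is auto-transposed
  gxc <- withr::local_tempdir()
  Matrix::writeMM(Matrix::Matrix(t(m$values), sparse = TRUE),
                  file.path(gxc, "matrix.mtx"))
  writeLines(m$cell_ids, file.path(gxc, "barcodes.tsv"))
  writeLines(m$gene_ids, file.path(gxc, "features.tsv"))
  m4 <- read_expression(gxc, "mtx_dir")
  expect_equal(m4$values, m$values)
})

test_that("loading rejects broken inputs with informative errors", {
  mtx <- withr::local_tempdir()
  m <- expression_matrix(matrix(1:6, 2, 3))
  write_expression(m, mtx, "mtx_dir")
  file.remove(file.path(mtx, "barcodes.tsv"))
  expect_error(read_expression(mtx, "mtx_dir"), "barcodes.tsv")

  # features list longer than either matrix dimension
  mtx2 <- withr::local_tempdir()
  write_expression(m, mtx2, "mtx_dir")
  writeLines(paste0("g", 1:5), file.path(mtx2, "features.tsv"))
  expect_error(read_expression(mtx2, "mtx_dir"), "neither")

  expect_error(expression_matrix(matrix(1:4, 2, 2),
                                 cell_ids = c("x", "x")), "duplicate")
  expect_error(expression_matrix(matrix(c(-1, 1, 2, 3), 2, 2)),
               "non-negative")
  expect_error(read_expression("does/not/exist.csv", "csv"), "exist")
  expect_error(read_expression("whatever.h5ad", "h5ad"), "not supported")
})

test_that("normalization scales cells to the target sum and flags empties", {
  m <- expression_matrix(rbind(c(1, 1, 2), c(0, 0, 0)),
                         cell_ids = c("ok", "empty"),
                         gene_ids = c("g1", "g2", "g3"))
  expect_warning(n <- normalize_expression(m, target_sum = 4, log1p = FALSE),
                 "zero total")
  expect_equal(unname(n$values[1, ]), c(1, 1, 2))
  expect_equal(unname(n$values[2, ]), c(0, 0, 0))
  expect_identical(attr(n, "zero_cells"), "empty")
  expect_identical(n$layer, "normalized")

  set.seed(42)
  r <- expression_matrix(matrix(rpois(200, 3), 10, 20))
  s <- normalize_expression(r, target_sum = 1e4, log1p = FALSE)
  expect_true(all(abs(rowSums(s$values) - 1e4) < 1e-9))

  # idempotence in the scaled (pre-log) domain
  again <- normalize_expression(
    expression_matrix(s$values, s$cell_ids, s$gene_ids), 1e4, log1p = FALSE)
  expect_equal(again$values, s$values)

  lg <- normalize_expression(r, 1e4, log1p = TRUE)
  expect_equal(lg$values, log1p(s$values))
  expect_error(normalize_expression(lg), "raw")
})

test_that("gene alignment intersects in reference order and reports drops", {
  ref <- expression_matrix(matrix(1:6, 2, 3), gene_ids = c("A", "B", "C"))
  qry <- expression_matrix(matrix(1:6, 2, 3), gene_ids = c("B", "C", "D"))
  al <- align_genes(ref, qry)
  expect_identical(al$ref$gene_ids, c("B", "C"))
  expect_identical(al$query$gene_ids, c("B", "C"))
  expect_setequal(al$report$gene_id[al$report$side == "ref"], "A")
  expect_setequal(al$report$gene_id[al$report$side == "query"], "D")

  id <- align_genes(ref, ref)
  expect_equal(id$ref$values, ref$values)
  expect_equal(nrow(id$report), 0L)

  disjoint <- expression_matrix(matrix(1:4, 2, 2), gene_ids = c("X", "Y"))
  expect_error(align_genes(ref, disjoint), "no shared genes")
})

test_that("label round trip and highly-variable-gene selection work", {
  labs <- c(c1 = "T", c2 = "B", c3 = "T")
  f <- withr::local_tempfile(fileext = ".csv")
  write_labels(labs, f)
  expect_identical(read_labels(f, cell_ids = c("c3", "c1")),
                   c(c3 = "T", c1 = "T"))
  expect_error(read_labels(f, cell_ids = "missing"), "missing")

  set.seed(7)
  m <- expression_matrix(matrix(rpois(50 * 40, 2), 50, 40))
  hv <- select_hvg(m, 10)
  expect_equal(ncol(hv$values), 10L)
  expect_true(all(hv$gene_ids %in% m$gene_ids))
})
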