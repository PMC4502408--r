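test_that("matrix files round-trip through write and read", {
  vals <- cbind(R1 = c(1.5, 20, 300), R2 = c(2.25, 19, 310),
                S1 = c(3.5, 21, 290), S2 = c(4.75, 18, 305))
  rownames(vals) <- c("gA", "gB", "gC")
  ph <- c(R1 = "R", R2 = "R", S1 = "S", S2 = "S")
  x <- expr_matrix(vals, ph)
  mat_path <- withr::local_tempfile(fileext = ".tsv")
  ann_path <- withr::local_tempfile(fileext = ".tsv")
  write_expr_matrix(x, mat_path, ann_path)
  y <- read_expr_matrix(mat_path, ann_path)
  expect_identical(unclass(y), unclass(x))
  expect_identical(phenotypes(y), phenotypes(x))
})

test_that("loading rejects negative intensities and bad annotations", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tR1\tS1", "g1\t5\t-2"), p)
  expect_error(read_expr_matrix(p, c(R1 = "R", S1 = "S")), "negative intensity.*g1")
  writeLines(c("gene_id\tR1\tS1", "g1\t5\t2"), p)
  expect_error(read_expr_matrix(p, c(R1 = "R")), "missing from annotation.*S1")
  expect_error(read_expr_matrix(p, c(R1 = "R", S1 = "X")), "'R' or 'S'")
})

test_that("duplicate gene ids collapse by arithmetic mean of log2 values", {
  p <- withr::local_tempfile(fileext = ".tsv")
  # log2 values 4 and 6 -> collapsed linear value 2^5 = 32
  writeLines(c("gene_id\tR1\tS1", "g1\t16\t16", "g1\t64\t64", "g2\t8\t8"), p)
  x <- read_expr_matrix(p, c(R1 = "R", S1 = "S"))
  expect_equal(nrow(x), 2L)
  expect_equal(unclass(x)["g1", ], c(R1 = 32, S1 = 32))
  expect_equal(unclass(x)["g2", ], c(R1 = 8, S1 = 8))
})

test_that("rows with missing values are dropped with a message", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene_id,R1,S1", "g1,5,2", "g2,NA,3"), p)
  expect_message(x <- read_expr_matrix(p, c(R1 = "R", S1 = "S")), "1 row")
  expect_identical(rownames(x), "g1")
})

test_that("quantile normalisation equalises per-rank log2 means and is idempotent", {
  vals <- cbind(R1 = 2^c(1, 3), S1 = 2^c(2, 4))
  rownames(vals) <- c("g1", "g2")
  x <- expr_matrix(vals, c(R1 = "R", S1 = "S"))
  qn <- quantile_normalize_log2(x)
  # per-rank means of log2 columns (1,3) and (2,4) are (1.5, 3.5)
  expect_equal(log2(unclass(qn)), cbind(R1 = c(1.5, 3.5), S1 = c(1.5, 3.5)),
               ignore_attr = TRUE)
  # already-identical columns are a fixed point
  same <- mk_expr(R1 = c(4, 8, 32), S1 = c(4, 8, 32))
  expect_equal(unclass(quantile_normalize_log2(same)), unclass(same),
               tolerance = 1e-12)
  # idempotence and definitional postcondition on a random matrix
  set.seed(42)
  vr <- matrix(2^rnorm(60, 7, 2), 15, 4,
               dimnames = list(sprintf("g%02d", 1:15), c("R1", "R2", "S1", "S2")))
  xr <- expr_matrix(vr, c(R1 = "R", R2 = "R", S1 = "S", S2 = "S"))
  q1 <- quantile_normalize_log2(xr)
  q2 <- quantile_normalize_log2(q1)
  expect_equal(log2(unclass(q2)), log2(unclass(q1)), tolerance = 1e-9)
  sorted <- apply(log2(unclass(q1)), 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-9))
  withzero <- mk_expr(R1 = c(0, 2), S1 = c(1, 2))
  expect_error(quantile_normalize_log2(withzero), "floor_values")
})

test_that("probe collapse takes the log2-scale mean and keeps singletons exact", {
  vals <- cbind(R1 = c(4, 16, 7), S1 = c(4, 16, 7))
  rownames(vals) <- c("p1", "p2", "p3")
  x <- expr_matrix(vals, c(R1 = "R", S1 = "S"))
  map <- c(p1 = "gA", p2 = "gA", p3 = "gB")
  y <- collapse_probes(x, map)
  expect_equal(unclass(y)["gA", "R1"], 8)  # 2^((2+4)/2)
  expect_identical(unclass(y)["gB", ], unclass(x)["p3", ])
  expect_message(z <- collapse_probes(x, c(p1 = "gA", p2 = "gA")), "1 unmapped")
  expect_identical(rownames(z), "gA")
  expect_error(collapse_probes(x, character(0)), "empty probe map")
  expect_error(collapse_probes(x, c(p1 = "gA", p1 = "gB")), "more than one gene")
})

test_that("floor_values clamps from below and validates its bound", {
  vals <- cbind(R1 = c(0, 5, 100), S1 = c(0.5, 5, 100))
  rownames(vals) <- paste0("g", 1:3)
  x <- expr_matrix(vals, c(R1 = "R", S1 = "S"))
  f <- floor_values(x, 1)
  expect_equal(unname(unclass(f)[, "R1"]), c(1, 5, 100))
  expect_identical(unclass(floor_values(f, 1)), unclass(f))
  expect_error(floor_values(x, 0), "positive")
})
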