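test_that("expression matrices round-trip through tab-delimited text", {
  vals <- matrix(c(1.25, 2, 3, 4.5, 5, 6, 7, 8, 9, 10, 11, 12.75,
                   13, 14, 15, 16, 17, 18), nrow = 3, byrow = TRUE,
                 dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:6)))
  ds <- clic_dataset("toy", vals)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(ds, path)
  back <- read_expression_matrix(path, dataset_id = "toy")
  expect_identical(rownames(back$values), rownames(vals))
  expect_identical(colnames(back$values), colnames(vals))
  expect_equal(back$values, vals, tolerance = 1e-12)
  expect_identical(back$n_dropped, 0L)
})

test_that("duplicated gene rows are rejected with the offending identifier", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\t2", "gA\t3\t4", "gB\t5\t6"), path)
  expect_error(read_expression_matrix(path), "gA")
})

test_that("rows with missing or non-numeric cells are dropped and counted", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2\ts3",
               "gA\t1\t2\t3", "gB\t4\tNA\t6", "gC\t7\t8\tx", "gD\t1\t1\t1"),
             path)
  ds <- read_expression_matrix(path)
  expect_identical(rownames(ds$values), c("gA", "gD"))
  expect_identical(ds$n_dropped, 2L)
})

test_that("GCT headers are skipped", {
  path <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.2", "2\t2", "Name\tDescription\ts1\ts2",
               "gA\tdesc\t1\t2", "gB\tdesc\t3\t4"), path)
  ds <- read_expression_matrix(path)
  expect_identical(rownames(ds$values), c("gA", "gB"))
  expect_identical(colnames(ds$values), c("s1", "s2"))
})

test_that("unreadable or empty inputs are fatal", {
  expect_error(read_expression_matrix(file.path(tempdir(), "nope.tsv")),
               "nope.tsv")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene_id\ts1", path)
  expect_error(read_expression_matrix(path), "zero genes")
})

test_that("log-scale datasets are detected and exponentiated base 2", {
  m <- matrix(runif(12, 0, 12.3), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  m[1, 1] <- 12.3
  ds <- rescale_if_log(clic_dataset("log2", m))
  expect_true(ds$log_rescaled)
  expect_equal(ds$values, 2^m)

  m2 <- m * 500  # max 6150, clearly linear
  ds2 <- rescale_if_log(clic_dataset("lin", m2))
  expect_false(ds2$log_rescaled)
  expect_equal(ds2$values, m2)

  zeros <- clic_dataset("z", matrix(0, 2, 6, dimnames = list(
    c("g1", "g2"), paste0("s", 1:6))))
  expect_true(all(rescale_if_log(zeros)$values == 1))
})

test_that("rescaling is idempotent once values are on linear scale", {
  m <- matrix(runif(12, 0, 10), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  once <- rescale_if_log(clic_dataset("d", m))
  expect_true(max(once$values) >= 30)
  twice <- rescale_if_log(once)
  expect_equal(twice$values, once$values)
})

test_that("sample-count and magnitude filters match the removal rules", {
  mk <- function(ns, mx) {
    m <- matrix(runif(4 * ns, 1, mx), 4, ns,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:ns)))
    m[1, 1] <- mx
    clic_dataset("d", m)
  }
  expect_identical(apply_sample_filters(mk(5, 5000)), "too_few_samples")
  expect_identical(apply_sample_filters(mk(6, 900)), "low_max_expression")
  expect_identical(apply_sample_filters(mk(10, 20000)), "pass")
})

test_that("column-mean normalization preserves totals and relative values", {
  m <- matrix(c(5, 15, 10, 50), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  ds <- normalize_sample_means(clic_dataset("d", m))
  expect_equal(unname(colMeans(ds$values)), c(20, 20))
  # relative values within columns preserved
  expect_equal(ds$values[2, 1] / ds$values[1, 1], 3)

  eq <- matrix(c(1, 3, 2, 2), 2, 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(normalize_sample_means(clic_dataset("d", eq))$values, eq)

  z <- matrix(c(0, 0, 1, 2), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(normalize_sample_means(clic_dataset("d", z)), "mean zero")
})

test_that("column means agree to 1e-9 relative tolerance after normalization", {
  set.seed(4)
  m <- matrix(rexp(600, 1 / 1000), 30, 20,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:20)))
  ds <- normalize_sample_means(clic_dataset("d", m))
  mu <- colMeans(ds$values)
  expect_lt(diff(range(mu)) / mean(mu), 1e-9)
})

test_that("compendium preprocessing fills the manifest and caches round-trip", {
  tc <- get_tiny_comp()
  comp <- tc$comp
  expect_s3_class(comp, "clic_compendium")
  expect_identical(nrow(comp$manifest), 10L)
  expect_true(all(comp$manifest$qc_status == "pass"))
  expect_identical(length(comp$datasets), 10L)

  # a too-small dataset is excluded with the right status
  small <- clic_dataset("small", matrix(
    runif(20, 1, 2000), 4, 5,
    dimnames = list(paste0("g", 1:4), paste0("s", 1:5))))
  comp2 <- build_compendium(c(tc$sim$datasets[1:2], list(small)))
  expect_identical(
    comp2$manifest$qc_status[comp2$manifest$dataset_id == "small"],
    "too_few_samples")
  expect_false("small" %in% names(comp2$datasets))

  path <- withr::local_tempfile(fileext = ".rds")
  write_compendium(comp, path)
  expect_equal(read_compendium(path)$manifest, comp$manifest)
})
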