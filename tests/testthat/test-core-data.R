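test_that("spatial_dataset enforces its invariants", {
  X <- matrix(1:12, 4, 3)
  co <- cbind(runif(4), runif(4))
  ds <- spatial_dataset(X, co)
  expect_s3_class(ds, "spatial_dataset")
  expect_equal(n_cells(ds), 4L)
  expect_equal(n_genes(ds), 3L)

  expect_error(spatial_dataset(X, cbind(co, 1)), "exactly 2 columns")
  expect_error(spatial_dataset(X, co[1:3, ]), "mismatch \\(3 vs 4\\)")
  co_na <- co; co_na[2, 1] <- NA
  expect_error(spatial_dataset(X, co_na), "NaN/NA")
  expect_error(spatial_dataset(X[1, , drop = FALSE], co[1, , drop = FALSE]),
               "at least 2 cells")
})

test_that("coordinates are aligned to expression rows by identifier", {
  X <- matrix(rpois(12, 5), 4, 3,
              dimnames = list(paste0("c", 1:4), paste0("g", 1:3)))
  co <- cbind(x = 1:4, y = 5:8)
  rownames(co) <- paste0("c", 4:1)        # reversed order on disk
  ds <- spatial_dataset(X, co)
  expect_equal(unname(ds$coords["c1", "x"]), 4)
  expect_equal(unname(ds$coords["c4", "x"]), 1)
})

test_that("csv_pair loading works and mismatches are hard errors", {
  td <- withr::local_tempdir()
  X <- matrix(rpois(12, 5), 4, 3,
              dimnames = list(paste0("c", 1:4), paste0("g", 1:3)))
  ef <- file.path(td, "expr.csv")
  write.csv(as.data.frame(X), ef)
  cf <- file.path(td, "coords.csv")
  write.csv(data.frame(cell_id = paste0("c", 1:4), x = 1:4, y = 4:1), cf,
            row.names = FALSE)
  ds <- read_spatial_dataset(ef, "csv_pair", coords_path = cf)
  expect_equal(n_cells(ds), 4L)
  expect_equal(n_genes(ds), 3L)
  expect_equal(unname(ds$expression), unname(X))

  write.csv(data.frame(cell_id = paste0("c", 1:3), x = 1:3, y = 3:1), cf,
            row.names = FALSE)
  expect_error(read_spatial_dataset(ef, "csv_pair", coords_path = cf),
               "mismatch \\(3 vs 4\\)")
  write.csv(data.frame(cell_id = paste0("c", 1:4), a = 1:4), cf,
            row.names = FALSE)
  expect_error(read_spatial_dataset(ef, "csv_pair", coords_path = cf),
               "missing coordinates.*'x'")
})

test_that("mtx_dir loading requires all member files", {
  td <- withr::local_tempdir()
  m <- Matrix::Matrix(matrix(rpois(15, 3), 3, 5), sparse = TRUE) # genes x cells
  Matrix::writeMM(m, file.path(td, "matrix.mtx"))
  writeLines(paste0("bc", 1:5), file.path(td, "barcodes.tsv"))
  writeLines(paste0("g", 1:3), file.path(td, "features.tsv"))
  expect_error(read_spatial_dataset(td, "mtx_dir"), "missing coordinates")
  write.csv(data.frame(cell_id = paste0("bc", 1:4), x = 1:4, y = 1:4),
            file.path(td, "coords.csv"), row.names = FALSE)
  expect_error(read_spatial_dataset(td, "mtx_dir"), "mismatch \\(4 vs 5\\)")
  write.csv(data.frame(cell_id = paste0("bc", 1:5), x = 1:5, y = 1:5),
            file.path(td, "coords.csv"), row.names = FALSE)
  ds <- read_spatial_dataset(td, "mtx_dir")
  expect_equal(dim(ds$expression), c(5L, 3L))
})

test_that("h5sd container round-trips expression and coordinates", {
  td <- withr::local_tempdir()
  sim <- toy_sim(60)
  f <- file.path(td, "ds.h5sd")
  write_spatial_dataset(sim$dataset, f, "h5sd")
  back <- read_spatial_dataset(f, "h5sd")
  expect_equal(back$expression, sim$dataset$expression, tolerance = 1e-6)
  expect_equal(back$coords, sim$dataset$coords, tolerance = 1e-6)
  expect_equal(back$cell_type, sim$dataset$cell_type)
  # second round trip is exact relative to the first read
  f2 <- file.path(td, "ds2.h5sd")
  write_spatial_dataset(back, f2, "h5sd")
  back2 <- read_spatial_dataset(f2, "h5sd")
  expect_equal(back2$expression, back$expression)
})

test_that("total-count normalization and log1p behave as stated", {
  X <- matrix(5, 4, 10)
  co <- cbind(runif(4), runif(4))
  ds <- spatial_dataset(X, co)
  pp <- preprocess(ds, preprocess_config(n_hvg = NULL, log1p = FALSE))
  expect_equal(unname(rowSums(pp$expression)), rep(1e4, 4))

  zero <- spatial_dataset(matrix(0, 4, 5), co)
  pz <- preprocess(zero, preprocess_config(normalize_total = FALSE,
                                           n_hvg = NULL))
  expect_true(all(pz$expression == 0))

  expect_error(preprocess(spatial_dataset(matrix(-1, 4, 5), co),
                          preprocess_config(n_hvg = NULL)), "nonnegative")
})

test_that("HVG selection keeps exactly n_hvg genes ranked by dispersion", {
  set.seed(11)
  n <- 80; m <- 50
  # genes with widely varying dispersion
  X <- sapply(seq_len(m), function(j) rnbinom(n, mu = 5, size = 50 / j))
  ds <- spatial_dataset(X, cbind(runif(n), runif(n)))
  cfgp <- preprocess_config(normalize_total = FALSE, log1p = FALSE, n_hvg = 20L)
  pp <- preprocess(ds, cfgp)
  expect_equal(n_genes(pp), 20L)
  # brute-force dispersion ranking on the same matrix
  disp <- apply(X, 2, var) / colMeans(X)
  expected <- sort(colnames(ds$expression)[order(disp, decreasing = TRUE)[1:20]])
  expect_setequal(colnames(pp$expression), expected)
  expect_error(preprocess(ds, preprocess_config(normalize_total = FALSE,
                                                log1p = FALSE, n_hvg = 60L)),
               "exceeds gene count")
})

test_that("preprocess is idempotent on already-normalized data", {
  sim <- toy_sim(60)
  cfgp <- preprocess_config(log1p = FALSE, n_hvg = NULL)
  once <- preprocess(sim$dataset, cfgp)
  twice <- preprocess(once, cfgp)
  expect_equal(twice$expression, once$expression, tolerance = 1e-12)
  expect_equal(twice$coords, once$coords)
})

test_that("per-cell results are written as aligned CSV columns", {
  td <- withr::local_tempdir()
  sim <- toy_sim(60)
  f <- file.path(td, "cells.csv")
  out <- write_cell_results(sim$dataset, list(tau = sim$true_time), f)
  back <- read.csv(f)
  expect_equal(back$tau, sim$true_time, tolerance = 1e-8)
  expect_equal(back$cell_id, sim$dataset$cell_ids)
})
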