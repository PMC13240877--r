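#' Construct a spatial expression dataset
#'
#' The universal input container for the package: an expression matrix
#' (cells/spots in rows, genes in columns) paired with 2-D spatial
#' coordinates, plus optional per-cell annotations.
#'
#' @param expression numeric matrix, n cells x m genes; nonnegative counts or
#'   normalized values. A sparse `Matrix` is accepted and densified.
#' @param coords numeric matrix or data frame with exactly two columns (x, y).
#' @param cell_type optional character/factor vector of per-cell labels.
#' @param section optional per-cell section / timepoint label.
#' @param gene_names optional gene identifiers (defaults to colnames).
#' @param cell_ids optional cell identifiers (defaults to rownames). When both
#'   expression and coords carry identifiers the coordinates are re-aligned to
#'   the expression rows by identifier.
#'
#' @return An object of class `spatial_dataset` with fields `expression`,
#'   `coords`, `cell_type`, `section`, `gene_names`, `cell_ids`.
#' @export
spatial_dataset <- function(expression, coords, cell_type = NULL,
                            section = NULL, gene_names = NULL,
                            cell_ids = NULL) {
  expression <- as.matrix(expression)
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) {
    stop(sprintf(
      "coords must have exactly 2 columns (x, y); got %d. 3-D or other coordinate layouts are not supported.",
      ncol(coords)), call. = FALSE)
  }
  if (nrow(expression) < 2L) stop("need at least 2 cells", call. = FALSE)
  if (anyNA(coords)) stop("NaN/NA in coords", call. = FALSE)
  cell_ids <- cell_ids %||% rownames(expression) %||%
    paste0("cell_", seq_len(nrow(expression)))
  gene_names <- gene_names %||% colnames(expression) %||%
    paste0("gene_", seq_len(ncol(expression)))
  if (!is.null(rownames(coords)) && !is.null(cell_ids) &&
      all(cell_ids %in% rownames(coords)) &&
      nrow(coords) == length(cell_ids)) {
    coords <- coords[cell_ids, , drop = FALSE]
  }
  if (nrow(expression) != nrow(coords)) {
    stop(sprintf("coordinate/expression mismatch (%d vs %d)",
                 nrow(coords), nrow(expression)), call. = FALSE)
  }
  if (!is.null(cell_type) && length(cell_type) != nrow(expression)) {
    stop("cell_type length must equal number of cells", call. = FALSE)
  }
  if (!is.null(section) && length(section) != nrow(expression)) {
    stop("section length must equal number of cells", call. = FALSE)
  }
  rownames(expression) <- cell_ids
  colnames(expression) <- gene_names
  rownames(coords) <- cell_ids
  colnames(coords) <- c("x", "y")
  structure(
    list(expression = expression, coords = coords,
         cell_type = if (!is.null(cell_type)) as.character(cell_type),
         section = if (!is.null(section)) as.character(section),
         gene_names = gene_names, cell_ids = cell_ids),
    class = "spatial_dataset")
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("spatial_dataset: %d cells x %d genes\n",
              nrow(x$expression), ncol(x$expression)))
  if (!is.null(x$cell_type)) {
    cat("  cell types:", paste(utils::head(unique(x$cell_type), 8), collapse = ", "), "\n")
  }
  if (!is.null(x$section)) {
    cat("  sections:", paste(unique(x$section), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of cells / genes in a dataset
#' @param ds a `spatial_dataset`
#' @return integer
#' @export
n_cells <- function(ds) nrow(ds$expression)

#' @rdname n_cells
#' @export
n_genes <- function(ds) ncol(ds$expression)

#' Read a spatial dataset from disk
#'
#' Supported layouts:
#' \describe{
#'   \item{`csv_pair`}{`path` is an expression CSV (cells in rows, genes in
#'     columns, first column = cell id) and `coords_path` a CSV with columns
#'     `cell_id, x, y`.}
#'   \item{`mtx_dir`}{`path` is a directory holding `matrix.mtx` (genes x
#'     cells, MatrixMarket), `barcodes.tsv`, `features.tsv` and
#'     `coords.csv`/`coords.tsv` with columns `cell_id, x, y`.}
#'   \item{`h5sd`}{an HDF5 container written by [write_spatial_dataset()]
#'     (anndata-like layout: `/X`, `/obs`, `/var/name`, `/obsm/spatial`).}
#' }
#' Coordinates are aligned to expression rows by cell identifier; file order
#' is the fallback when identifiers are absent.
#'
#' @param path main file or directory (see above).
#' @param fmt one of `"csv_pair"`, `"mtx_dir"`, `"h5sd"`.
#' @param coords_path coordinates CSV for `csv_pair`.
#' @return a [spatial_dataset()]
#' @export
read_spatial_dataset <- function(path, fmt = c("csv_pair", "mtx_dir", "h5sd"),
                                 coords_path = NULL) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop(sprintf("path not found: %s", path), call. = FALSE)
  switch(fmt,
    csv_pair = {
      if (is.null(coords_path)) {
        stop("csv_pair requires coords_path (CSV with columns cell_id, x, y)",
             call. = FALSE)
      }
      expr <- utils::read.csv(path, row.names = 1, check.names = FALSE)
      cc <- read_coords_table(coords_path)
      build_from_parts(as.matrix(expr), cc)
    },
    mtx_dir = {
      mtx <- file.path(path, "matrix.mtx")
      bc <- file.path(path, "barcodes.tsv")
      ft <- file.path(path, "features.tsv")
      for (f in c(mtx, bc, ft)) {
        if (!file.exists(f)) stop(sprintf("mtx_dir missing %s", basename(f)), call. = FALSE)
      }
      cfile <- Filter(file.exists, file.path(path, c("coords.csv", "coords.tsv")))
      if (length(cfile) == 0L) {
        stop("missing coordinates: expected coords.csv or coords.tsv with columns (cell_id, x, y)",
             call. = FALSE)
      }
      m <- Matrix::readMM(mtx)          # genes x cells, cellranger convention
      barcodes <- readLines(bc)
      features <- read.delim(ft, header = FALSE)[[1]]
      expr <- t(as.matrix(m))
      rownames(expr) <- barcodes
      colnames(expr) <- features
      cc <- read_coords_table(cfile[[1]])
      build_from_parts(expr, cc)
    },
    h5sd = read_h5sd(path)
  )
}

read_coords_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  cc <- utils::read.csv(path, sep = sep, check.names = FALSE)
  need <- c("x", "y")
  if (!all(need %in% names(cc))) {
    stop(sprintf(
      "missing coordinates: file %s must contain columns 'x' and 'y' (and optionally 'cell_id')",
      basename(path)), call. = FALSE)
  }
  cc
}

build_from_parts <- function(expr, cc) {
  coords <- as.matrix(cc[, c("x", "y")])
  if ("cell_id" %in% names(cc)) rownames(coords) <- as.character(cc$cell_id)
  if (nrow(expr) != nrow(coords)) {
    stop(sprintf("coordinate/expression mismatch (%d vs %d)",
                 nrow(coords), nrow(expr)), call. = FALSE)
  }
  extra <- setdiff(names(cc), c("cell_id", "x", "y"))
  spatial_dataset(expr, coords,
                  cell_type = if ("cell_type" %in% extra) cc$cell_type,
                  section = if ("section" %in% extra) cc$section)
}

#' Write a spatial dataset to disk
#'
#' @param ds a [spatial_dataset()]
#' @param path output file (h5sd) or basename prefix (csv_pair writes
#'   `<path>_expression.csv` and `<path>_coords.csv`).
#' @param fmt `"h5sd"` or `"csv_pair"`.
#' @return `path`, invisibly.
#' @export
write_spatial_dataset <- function(ds, path, fmt = c("h5sd", "csv_pair")) {
  fmt <- match.arg(fmt)
  if (fmt == "csv_pair") {
    ef <- paste0(path, "_expression.csv")
    cf <- paste0(path, "_coords.csv")
    utils::write.csv(as.data.frame(ds$expression), ef)
    cc <- data.frame(cell_id = ds$cell_ids, x = ds$coords[, 1], y = ds$coords[, 2])
    if (!is.null(ds$cell_type)) cc$cell_type <- ds$cell_type
    if (!is.null(ds$section)) cc$section <- ds$section
    utils::write.csv(cc, cf, row.names = FALSE)
    return(invisible(path))
  }
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(ds$expression, path, "X")
  rhdf5::h5createGroup(path, "obs")
  rhdf5::h5write(ds$cell_ids, path, "obs/cell_id")
  if (!is.null(ds$cell_type)) rhdf5::h5write(ds$cell_type, path, "obs/cell_type")
  if (!is.null(ds$section)) rhdf5::h5write(ds$section, path, "obs/section")
  rhdf5::h5createGroup(path, "var")
  rhdf5::h5write(ds$gene_names, path, "var/name")
  rhdf5::h5createGroup(path, "obsm")
  rhdf5::h5write(ds$coords, path, "obsm/spatial")
  rhdf5::h5closeAll()
  invisible(path)
}

read_h5sd <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  cont <- rhdf5::h5ls(path)$name
  if (!"spatial" %in% cont) {
    stop("missing coordinates: container has no obsm/spatial slot", call. = FALSE)
  }
  X <- rhdf5::h5read(path, "X")
  coords <- rhdf5::h5read(path, "obsm/spatial")
  cell_ids <- as.character(rhdf5::h5read(path, "obs/cell_id"))
  genes <- as.character(rhdf5::h5read(path, "var/name"))
  ct <- if ("cell_type" %in% cont) as.character(rhdf5::h5read(path, "obs/cell_type"))
  sec <- if ("section" %in% cont) as.character(rhdf5::h5read(path, "obs/section"))
  spatial_dataset(X, coords, cell_type = ct, section = sec,
                  gene_names = genes, cell_ids = cell_ids)
}

#' Attach per-cell results and write them as a CSV table
#'
#' @param ds a [spatial_dataset()]
#' @param values named list of per-cell vectors (e.g. pseudotime, weights).
#' @param path output CSV path.
#' @return the assembled data frame, invisibly.
#' @export
write_cell_results <- function(ds, values, path) {
  stopifnot(all(vapply(values, length, 1L) == n_cells(ds)))
  out <- data.frame(cell_id = ds$cell_ids,
                    x = ds$coords[, 1], y = ds$coords[, 2])
  if (!is.null(ds$cell_type)) out$cell_type <- ds$cell_type
  if (!is.null(ds$section)) out$section <- ds$section
  for (nm in names(values)) out[[nm]] <- values[[nm]]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
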