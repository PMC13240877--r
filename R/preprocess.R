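#' Preprocessing configuration
#'
#' Standard expression preprocessing: total-count normalization to a fixed
#' target sum, log1p transform, dispersion-based selection of highly variable
#' genes, and optional unit-variance scaling.
#'
#' @param normalize_total normalize each cell to `target_sum` total counts.
#' @param target_sum per-cell total after normalization (default 1e4).
#' @param log1p apply `log(1 + x)`.
#' @param n_hvg number of highly variable genes to keep (`NULL` = keep all).
#' @param scale scale genes to unit variance after transformation.
#' @return a `preprocess_config` list
#' @export
preprocess_config <- function(normalize_total = TRUE, target_sum = 1e4,
                              log1p = TRUE, n_hvg = 2000L, scale = FALSE) {
  if (!is.null(n_hvg) && n_hvg < 1L) stop("n_hvg must be >= 1", call. = FALSE)
  structure(list(normalize_total = normalize_total, target_sum = target_sum,
                 log1p = log1p, n_hvg = n_hvg, scale = scale),
            class = "preprocess_config")
}

#' Preprocess a spatial dataset
#'
#' @param ds a [spatial_dataset()] with nonnegative expression when
#'   total-count normalization is enabled.
#' @param cfg a [preprocess_config()].
#' @return a new [spatial_dataset()]; coordinates are unchanged; when HVG
#'   selection is enabled the gene dimension is reduced to `n_hvg`.
#' @export
preprocess <- function(ds, cfg = preprocess_config()) {
  X <- ds$expression
  if (isTRUE(cfg$normalize_total)) {
    if (any(X < 0)) stop("expression must be nonnegative for total-count normalization",
                         call. = FALSE)
    rs <- rowSums(X)
    rs[rs == 0] <- 1
    X <- X / rs * cfg$target_sum
  }
  if (isTRUE(cfg$log1p)) X <- log1p(X)
  if (!is.null(cfg$n_hvg) && cfg$n_hvg < ncol(X)) {
    keep <- order(gene_dispersion(X), decreasing = TRUE)[seq_len(cfg$n_hvg)]
    X <- X[, sort(keep), drop = FALSE]
  } else if (!is.null(cfg$n_hvg) && cfg$n_hvg > ncol(X)) {
    stop(sprintf("n_hvg (%d) exceeds gene count (%d)", cfg$n_hvg, ncol(X)),
         call. = FALSE)
  }
  if (isTRUE(cfg$scale)) {
    sds <- apply(X, 2L, stats::sd)
    sds[sds == 0] <- 1
    X <- sweep(X, 2L, sds, "/")
  }
  spatial_dataset(X, ds$coords, cell_type = ds$cell_type,
                  section = ds$section, cell_ids = ds$cell_ids)
}

#' Per-gene dispersion (variance / mean) used for HVG ranking
#'
#' @param X expression matrix (cells x genes).
#' @return numeric vector of length `ncol(X)`; zero-mean genes score 0.
#' @export
gene_dispersion <- function(X) {
  mu <- colMeans(X)
  v <- apply(X, 2L, stats::var)
  d <- ifelse(mu > 0, v / mu, 0)
  d[!is.finite(d)] <- 0
  d
}
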