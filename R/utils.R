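#' @keywords internal
"_PACKAGE"

#' @importFrom stats dist kmeans prcomp quantile median rnorm runif rbinom
#'   rnbinom cor sd predict wilcox.test setNames
#' @importFrom utils head tail read.csv write.csv read.delim write.table
#' @importFrom methods as
NULL

# Pairwise Euclidean distance as a dense matrix. Kept internal; n here is at
# most a few thousand so the dense form is fine.
pairwise_dist <- function(x) {
  as.matrix(stats::dist(x))
}

# Row-wise log-sum-exp, numerically safe for very negative entries
# (cost/gamma terms reach -1e7 with the diagonal penalty).
row_logsumexp <- function(m) {
  mx <- matrixStats::rowMaxs(m)
  mx + log(rowSums(exp(m - mx)))
}

col_logsumexp <- function(m) {
  mx <- matrixStats::colMaxs(m)
  mx + log(colSums(exp(m - rep(mx, each = nrow(m)))))
}

# k-nearest-neighbour indices (self excluded), rows of `query` against `ref`.
# RANN does the heavy lifting; falls back to brute force for tiny n.
knn_indices <- function(ref, k, query = NULL) {
  self_query <- is.null(query)
  if (self_query) query <- ref
  k_eff <- min(k + self_query, nrow(ref))
  nn <- RANN::nn2(ref, query, k = k_eff)$nn.idx
  if (self_query) {
    # drop the self column (first occurrence of the row's own index)
    out <- matrix(NA_integer_, nrow(nn), k_eff - 1L)
    for (i in seq_len(nrow(nn))) {
      row <- nn[i, ]
      row <- row[row != i]
      length(row) <- k_eff - 1L
      out[i, ] <- row
    }
    out[, seq_len(min(k, ncol(out))), drop = FALSE]
  } else {
    nn
  }
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
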