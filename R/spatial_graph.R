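#' Estimate the alpha-complex radius from k-nearest-neighbour distances
#'
#' The scale delta is the average, over all points, of the mean distance to
#' each point's k nearest neighbours.
#'
#' @param coords n x 2 coordinate matrix.
#' @param k neighbour count (default 6, a typical spot-neighbourhood size on
#'   hexagonal arrays); requires `n > k >= 1`.
#' @return positive scalar delta.
#' @export
estimate_radius_delta <- function(coords, k = 6L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k < 1L || n <= k) stop("need n > k >= 1", call. = FALSE)
  idx <- knn_indices(coords, k)
  d <- vapply(seq_len(n), function(i) {
    mean(sqrt(rowSums((coords[idx[i, ], , drop = FALSE] -
                         matrix(coords[i, ], length(idx[i, ]), 2, byrow = TRUE))^2)))
  }, 0)
  if (any(d == 0)) warning("duplicate points contribute zero distance to delta")
  delta <- mean(d)
  if (delta <= 0) stop("degenerate coordinates", call. = FALSE)
  delta
}

#' Build the alpha-complex spatial adjacency graph
#'
#' Computes the Delaunay triangulation of the spot coordinates and keeps an
#' edge when its alpha-filtration radius is at most `delta`: Gabriel edges
#' (empty diametral disk) have filtration |ij|/2; otherwise the filtration is
#' the smallest circumradius of the Delaunay triangles sharing the edge. This
#' is the 1-skeleton of the alpha complex at scale delta, i.e. the
#' radius-restricted Voronoi adjacency.
#'
#' Degenerate geometry (collinear points, duplicates) cannot support a
#' Delaunay/Voronoi structure; such inputs fall back to a symmetric k-NN
#' graph with a warning.
#'
#' @param coords n x 2 coordinate matrix (n >= 3).
#' @param delta positive radius; see [estimate_radius_delta()].
#' @param fallback_k neighbour count of the k-NN fallback graph.
#' @return an object of class `spatial_graph`: sparse symmetric binary
#'   adjacency (`adjacency`), `radius_delta`, `n_edges`, and the construction
#'   `method` ("alpha" or "knn_fallback").
#' @export
build_alpha_adjacency <- function(coords, delta, fallback_k = 6L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  if (delta <= 0) stop("delta must be positive", call. = FALSE)
  degenerate <- any(duplicated(coords)) || coord_rank(coords) < 2L
  edges <- NULL
  if (!degenerate) {
    edges <- tryCatch(alpha_edges(coords, delta), error = function(e) NULL)
  }
  method <- "alpha"
  if (is.null(edges)) {
    warning("degenerate geometry; falling back to symmetric k-NN graph")
    method <- "knn_fallback"
    k <- min(fallback_k, n - 1L)
    idx <- knn_indices(coords, k)
    edges <- cbind(rep(seq_len(n), each = k), as.vector(t(idx)))
    edges <- edges[!is.na(edges[, 2]), , drop = FALSE]
  }
  A <- Matrix::sparseMatrix(
    i = c(edges[, 1], edges[, 2]), j = c(edges[, 2], edges[, 1]),
    x = 1, dims = c(n, n), use.last.ij = TRUE)
  A <- Matrix::drop0(A)
  A@x[] <- 1
  Matrix::diag(A) <- 0
  A <- Matrix::drop0(A)
  structure(list(adjacency = A, radius_delta = delta,
                 n_edges = Matrix::nnzero(A) / 2, method = method),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("spatial_graph (%s): %d nodes, %d edges, delta = %.4g\n",
              x$method, nrow(x$adjacency), x$n_edges, x$radius_delta))
  invisible(x)
}

coord_rank <- function(coords) {
  cc <- sweep(coords, 2L, colMeans(coords))
  qr(cc)$rank
}

# Delaunay edges with their alpha-filtration radii, thresholded at delta.
alpha_edges <- function(coords, delta) {
  dd <- deldir::deldir(coords[, 1], coords[, 2], suppressMsge = TRUE)
  seg <- dd$delsgs
  e1 <- pmin(seg$ind1, seg$ind2)
  e2 <- pmax(seg$ind1, seg$ind2)
  filt <- alpha_filtration(coords, e1, e2, dd)
  keep <- filt <= delta
  cbind(e1[keep], e2[keep])
}

# Filtration radius for each Delaunay edge.
alpha_filtration <- function(coords, e1, e2, dd) {
  n_e <- length(e1)
  mid <- (coords[e1, , drop = FALSE] + coords[e2, , drop = FALSE]) / 2
  half <- sqrt(rowSums((coords[e1, , drop = FALSE] -
                          coords[e2, , drop = FALSE])^2)) / 2
  # Gabriel test: no third point strictly inside the diametral disk. The
  # 3 nearest points to the midpoint include at most the 2 endpoints, so the
  # nearest non-endpoint is always among them.
  nn <- RANN::nn2(coords, mid, k = min(3L, nrow(coords)))
  gabriel <- vapply(seq_len(n_e), function(ei) {
    other <- nn$nn.idx[ei, ] != e1[ei] & nn$nn.idx[ei, ] != e2[ei]
    if (!any(other)) return(TRUE)
    min(nn$nn.dists[ei, other]) >= half[ei] * (1 - 1e-12)
  }, TRUE)
  filt <- half
  if (any(!gabriel)) {
    tri <- deldir::triang.list(dd)
    # circumradius per triangle, and an edge-key -> min circumradius map
    edge_r <- new.env(parent = emptyenv())
    for (tr in tri) {
      p <- as.matrix(tr[, c("x", "y")])
      idx <- tr$ptNum
      R <- circumradius(p)
      for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
        key <- paste(sort(idx[pair]), collapse = "_")
        old <- edge_r[[key]]
        edge_r[[key]] <- if (is.null(old)) R else min(old, R)
      }
    }
    for (ei in which(!gabriel)) {
      key <- paste(c(e1[ei], e2[ei]), collapse = "_")
      r_tri <- edge_r[[key]]
      if (!is.null(r_tri)) filt[ei] <- r_tri
    }
  }
  filt
}

circumradius <- function(p) {
  a <- sqrt(sum((p[1, ] - p[2, ])^2))
  b <- sqrt(sum((p[2, ] - p[3, ])^2))
  cc <- sqrt(sum((p[3, ] - p[1, ])^2))
  area2 <- abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
                 (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2]))
  if (area2 < .Machine$double.eps) return(Inf)
  a * b * cc / (2 * area2)
}

#' Graph degree per node
#' @param graph a `spatial_graph`
#' @return integer vector
#' @export
graph_degree <- function(graph) {
  as.integer(Matrix::rowSums(graph$adjacency != 0))
}

#' Export the edge list as a 2-column TSV (0-based indices)
#' @param graph a `spatial_graph`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_edge_list <- function(graph, path) {
  A <- methods::as(Matrix::triu(graph$adjacency), "TsparseMatrix")
  utils::write.table(data.frame(i = A@i, j = A@j), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
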