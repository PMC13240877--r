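#' Gaussian-kernel spatial density per cell
#'
#' `rho_hat_i = exp( (1/(n b)) * sum_j K(||s_i - s_j|| / b) )` with
#' `K(u) = (1/sqrt(2 pi)) exp(-u^2/2)` the standardized Gaussian kernel; the
#' sum includes the self term `j = i`. The exponential transform raises the
#' contrast between high- and low-density regions while compressing the
#' dynamic range of the raw kernel sum.
#'
#' @param coords n x 2 coordinates.
#' @param bandwidth kernel bandwidth `b` (> 0); defaults to twice the median
#'   nearest-neighbour distance.
#' @return a `density_field` with `rho_hat` (> 0), the `bandwidth`, and
#'   `rho = NULL` until [normalize_density()] is applied.
#' @export
estimate_density <- function(coords, bandwidth = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(bandwidth)) bandwidth <- default_bandwidth(coords)
  if (bandwidth <= 0) stop("bandwidth must be positive", call. = FALSE)
  D <- if (n > 1L) pairwise_dist(coords) else matrix(0, 1, 1)
  K <- stats::dnorm(D / bandwidth)
  rho_hat <- unname(exp(rowSums(K) / (n * bandwidth)))
  structure(list(rho_hat = rho_hat, rho = NULL, bandwidth = bandwidth,
                 epsilon = 1e-10),
            class = "density_field")
}

#' Default density bandwidth: twice the median nearest-neighbour distance
#' @param coords n x 2 coordinates
#' @return positive scalar
#' @export
default_bandwidth <- function(coords) {
  nn <- knn_indices(as.matrix(coords), 1L)
  d <- sqrt(rowSums((coords - coords[nn[, 1], , drop = FALSE])^2))
  b <- 2 * stats::median(d)
  if (!is.finite(b) || b <= 0) b <- 1
  b
}

#' Min-max normalize the density field
#'
#' `rho_i = (rho_hat_i - min) / (max - min + eps)` with `eps = 1e-10`; the
#' densest cell maps to (essentially) 1 and the sparsest to 0. A constant
#' field maps to all zeros.
#'
#' @param field a `density_field` from [estimate_density()].
#' @return the field with `rho` filled in.
#' @export
normalize_density <- function(field) {
  r <- field$rho_hat
  field$rho <- (r - min(r)) / (max(r) - min(r) + field$epsilon)
  field
}

#' Map normalized density to the spatial fusion weight
#'
#' The reverse-correlation map `alpha_i = alpha_min + (1 - rho_i) *
#' (alpha_max - alpha_min)`: the densest regions approach `alpha_min`
#' (embedding-dominated cost) and the sparsest approach `alpha_max`
#' (space-dominated cost).
#'
#' @param rho normalized densities in \[0, 1\].
#' @param alpha_min,alpha_max weight bounds, `0 <= alpha_min <= alpha_max <= 1`.
#' @return numeric vector of weights.
#' @export
map_density_to_alpha <- function(rho, alpha_min = 0.2, alpha_max = 0.8) {
  if (alpha_min > alpha_max) stop("alpha_min must be <= alpha_max", call. = FALSE)
  if (alpha_min < 0 || alpha_max > 1) stop("alpha bounds must lie in [0, 1]", call. = FALSE)
  alpha_min + (1 - rho) * (alpha_max - alpha_min)
}

#' Flag low-confidence cells
#'
#' Low local density can be a technical artifact rather than biology. A cell
#' is flagged when it fails any of three geometric/neighbourhood criteria:
#' (1) tissue edge: vertex of the convex hull (its Voronoi cell is
#' unbounded); (2) hole-adjacent: mean distance to its graph neighbours
#' exceeds `hole_factor` times the global median neighbour distance;
#' (3) unreliable connectivity: spatial-graph degree below `min_degree`.
#'
#' @param coords n x 2 coordinates.
#' @param graph the [build_alpha_adjacency()] graph on the same coordinates.
#' @param hole_factor multiple of the median neighbour distance defining a
#'   hole-like neighbourhood (default 3).
#' @param min_degree minimum reliable graph degree (default 2).
#' @return logical mask, `TRUE` for low-confidence cells.
#' @export
detect_low_confidence <- function(coords, graph, hole_factor = 3,
                                  min_degree = 2L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  hull <- grDevices::chull(coords)
  on_edge <- seq_len(n) %in% hull
  deg <- graph_degree(graph)
  A <- graph$adjacency
  D <- pairwise_dist(coords)
  mean_nb <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] != 0)
    if (length(nb)) mean_nb[i] <- mean(D[i, nb])
  }
  med <- stats::median(mean_nb, na.rm = TRUE)
  holey <- !is.na(mean_nb) & mean_nb > hole_factor * med
  low_deg <- deg < min_degree
  on_edge | holey | low_deg
}

#' Density-adaptive weights with low-confidence protection
#'
#' Convenience wrapper: estimates and normalizes the density field, maps it
#' to `alpha`, and overrides flagged low-confidence cells with the fixed
#' conservative weight `alpha_prot` (default `alpha_min`, i.e.
#' embedding-dominated, since unreliable density should not recruit extra
#' spatial weight).
#'
#' @param coords n x 2 coordinates.
#' @param graph the spatial graph (for the protection criteria).
#' @param alpha_min,alpha_max weight bounds.
#' @param alpha_prot fixed weight assigned to protected cells.
#' @param bandwidth density bandwidth (`NULL` = default).
#' @param hole_factor,min_degree see [detect_low_confidence()].
#' @return a `weight_map`: `alpha`, `alpha_tilde`, `protected`, `rho`,
#'   plus the bounds used.
#' @export
adaptive_weights <- function(coords, graph, alpha_min = 0.2, alpha_max = 0.8,
                             alpha_prot = alpha_min, bandwidth = NULL,
                             hole_factor = 3, min_degree = 2L) {
  field <- normalize_density(estimate_density(coords, bandwidth))
  alpha <- map_density_to_alpha(field$rho, alpha_min, alpha_max)
  protected <- detect_low_confidence(coords, graph, hole_factor, min_degree)
  alpha_tilde <- ifelse(protected, alpha_prot, alpha)
  structure(list(alpha = alpha, alpha_tilde = alpha_tilde,
                 protected = protected, rho = field$rho,
                 rho_hat = field$rho_hat, bandwidth = field$bandwidth,
                 alpha_min = alpha_min, alpha_max = alpha_max,
                 alpha_prot = alpha_prot),
            class = "weight_map")
}

#' Fuse embedding and spatial distances into the transport cost
#'
#' Both distance matrices are max-normalized to \[0, 1\]
#' (`ds(i,j) = ||s_i - s_j|| / max`, `dg(i,j) = ||z_i - z_j|| / max`), then
#' combined per source cell: `M_ij = alpha_tilde_i * ds(i,j) +
#' (1 - alpha_tilde_i) * dg(i,j)`. Because the weight is indexed by the row
#' (source) cell, `M` is in general asymmetric.
#'
#' @param Z n x d joint embedding.
#' @param coords n x 2 spatial coordinates.
#' @param alpha_tilde per-cell weights in \[0, 1\] (scalar recycled).
#' @return a `fused_cost` with `ds`, `dg`, `M`.
#' @export
fuse_distances <- function(Z, coords, alpha_tilde) {
  n <- nrow(coords)
  if (length(alpha_tilde) == 1L) alpha_tilde <- rep(alpha_tilde, n)
  if (any(alpha_tilde < 0 | alpha_tilde > 1)) {
    stop("alpha_tilde must lie in [0, 1]", call. = FALSE)
  }
  ds <- pairwise_dist(coords)
  if (max(ds) == 0) stop("degenerate normalization: all coordinates identical",
                         call. = FALSE)
  ds <- ds / max(ds)
  dg <- pairwise_dist(Z)
  if (max(dg) > 0) dg <- dg / max(dg)
  M <- alpha_tilde * ds + (1 - alpha_tilde) * dg
  structure(list(ds = ds, dg = dg, M = M, alpha_tilde = alpha_tilde),
            class = "fused_cost")
}
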