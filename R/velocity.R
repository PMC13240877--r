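#' Dual-modality neighbour sets
#'
#' Per-cell union of the spatial k-NN set (size `kp`, on coordinates) and the
#' embedding k-NN set (size `ke`, on the joint embedding); self is excluded.
#'
#' @param coords n x 2 coordinates.
#' @param Z n x d joint embedding.
#' @param kp,ke neighbour counts (>= 0, `kp + ke >= 1`, both < n).
#' @return a `neighbor_sets` list with `spatial`, `embed`, `union` (lists of
#'   index vectors).
#' @export
neighbor_union <- function(coords, Z, kp = 15L, ke = 15L) {
  n <- nrow(coords)
  if (kp < 0L || ke < 0L || kp + ke < 1L) stop("need kp, ke >= 0 and kp + ke >= 1", call. = FALSE)
  if (kp >= n || ke >= n) stop("kp and ke must be smaller than n", call. = FALSE)
  sp_idx <- if (kp > 0L) knn_indices(as.matrix(coords), kp) else NULL
  em_idx <- if (ke > 0L) knn_indices(as.matrix(Z), ke) else NULL
  spatial <- lapply(seq_len(n), function(i) if (kp > 0L) sp_idx[i, ] else integer(0))
  embed <- lapply(seq_len(n), function(i) if (ke > 0L) em_idx[i, ] else integer(0))
  uni <- lapply(seq_len(n), function(i) sort(union(spatial[[i]], embed[[i]])))
  structure(list(spatial = spatial, embed = embed, union = uni, kp = kp, ke = ke),
            class = "neighbor_sets")
}

#' Per-cell velocity vectors
#'
#' `v_i = (1/|N_i|) * sum_{j in N_i} gamma_ij * (s_j - s_i)/(||s_j - s_i|| + eps)`
#' where `gamma_ij = +p_ij` when `tau_j >= tau_i` and `-p_ij` otherwise, and
#' `p_ij = P_ij / sum_{k in N_i} P_ik` is the transition probability
#' row-normalized over the neighbour set. Unit direction vectors toward
#' later-pseudotime neighbours therefore add, and toward earlier neighbours
#' subtract, in proportion to transition strength.
#'
#' @param neighbors a [neighbor_union()] result.
#' @param tm a `transition_matrix` (or plan matrix).
#' @param tau pseudotime vector (or a `pseudotime_result`).
#' @param coords n x 2 coordinates in which the velocity is expressed.
#' @param eps numerical stability constant (default 1e-10).
#' @return a `velocity_field` with `v` (n x 2), and the per-cell normalized
#'   probabilities over neighbours.
#' @export
cell_velocity <- function(neighbors, tm, tau, coords, eps = 1e-10) {
  P <- if (inherits(tm, "transition_matrix")) tm$P else as.matrix(tm)
  if (inherits(tau, "pseudotime_result")) tau <- tau$tau
  coords <- as.matrix(coords)
  n <- nrow(coords)
  v <- matrix(0, n, 2)
  p_norm <- vector("list", n)
  for (i in seq_len(n)) {
    Ni <- neighbors$union[[i]]
    if (length(Ni) == 0L) next
    tot <- sum(P[i, Ni])
    if (tot <= 0) {
      warning(sprintf("cell %d has zero total neighbour probability; v = 0", i))
      next
    }
    p <- P[i, Ni] / tot
    p_norm[[i]] <- stats::setNames(p, Ni)
    dvec <- coords[Ni, , drop = FALSE] -
      matrix(coords[i, ], length(Ni), 2, byrow = TRUE)
    len <- sqrt(rowSums(dvec^2)) + eps
    gam <- ifelse(tau[Ni] >= tau[i], p, -p)
    v[i, ] <- colSums(dvec / len * gam) / length(Ni)
  }
  structure(list(v = v, p_norm = p_norm, eps = eps), class = "velocity_field")
}

#' Interpolate per-cell velocities onto a regular grid
#'
#' Builds a `floor(b_res * Q)` square grid over the coordinate bounding box
#' and averages cell velocities with an adaptive Gaussian kernel
#' `phi(d) = exp(-d^2/(2 sigma^2))`:
#' `v_g = sum_k phi(||g - s_k||) v_k / max(1, sum_k phi(||g - s_k||))`,
#' with `sigma = ((Xmax-Xmin) + (Ymax-Ymin))/2 * 1/(floor(b*Q) - 1) * e`.
#'
#' @param field a [cell_velocity()] result.
#' @param coords n x 2 cell coordinates.
#' @param b_res base grid resolution (default 50).
#' @param Q density scaling factor (default 1.0).
#' @param e global smoothing coefficient (default 0.5).
#' @return a `grid_field` with `grid_points` (g x 2), `grid_v` (g x 2),
#'   grid axes `gx`/`gy`, and `sigma`.
#' @export
grid_interpolate <- function(field, coords, b_res = 50L, Q = 1.0, e = 0.5) {
  coords <- as.matrix(coords)
  res <- floor(b_res * Q)
  if (res < 2L) stop("grid resolution floor(b_res * Q) must be at least 2", call. = FALSE)
  xr <- range(coords[, 1]); yr <- range(coords[, 2])
  sigma <- ((xr[2] - xr[1]) + (yr[2] - yr[1])) / 2 * (1 / (res - 1)) * e
  if (sigma <= 0) sigma <- 1e-6
  gx <- seq(xr[1], xr[2], length.out = res)
  gy <- seq(yr[1], yr[2], length.out = res)
  gp <- as.matrix(expand.grid(x = gx, y = gy))
  d2 <- outer(rowSums(gp^2), rowSums(coords^2), "+") - 2 * gp %*% t(coords)
  phi <- exp(-pmax(d2, 0) / (2 * sigma^2))
  denom <- pmax(1, rowSums(phi))
  gv <- (phi %*% field$v) / denom
  structure(list(grid_points = gp, grid_v = gv, gx = gx, gy = gy,
                 sigma = sigma, b_res = b_res, Q = Q, e = e),
            class = "grid_field")
}

#' Streamlines of a grid velocity field
#'
#' Integrates the bilinearly interpolated grid field with fourth-order
#' Runge-Kutta from seeds placed every `seed_stride` grid cells. Integration
#' stops when the trajectory leaves the bounding box, the local speed drops
#' below `v_floor` (a fraction of the maximum grid speed), or `max_steps` is
#' reached. An all-zero field yields no streamlines.
#'
#' @param grid a [grid_interpolate()] result.
#' @param seed_stride grid-cell stride between seeds (default 2).
#' @param max_steps RK4 step cap per streamline (default 500).
#' @param step_frac RK4 step as a fraction of the grid spacing (default 0.5).
#' @param v_floor relative speed floor (default 1e-3).
#' @param min_points streamlines shorter than this are dropped (default 3).
#' @return list of polylines (matrices with columns x, y).
#' @export
streamlines <- function(grid, seed_stride = 2L, max_steps = 500L,
                        step_frac = 0.5, v_floor = 1e-3, min_points = 3L) {
  vmax <- max(sqrt(rowSums(grid$grid_v^2)))
  if (vmax == 0) return(list())
  floor_abs <- v_floor * vmax
  hx <- diff(grid$gx[1:2]); hy <- diff(grid$gy[1:2])
  h <- step_frac * min(hx, hy)
  interp <- function(p) bilinear_v(grid, p)
  out <- list()
  for (ix in seq(1L, length(grid$gx), by = seed_stride)) {
    for (iy in seq(1L, length(grid$gy), by = seed_stride)) {
      p <- c(grid$gx[ix], grid$gy[iy])
      line <- integrate_rk4(p, interp, h, max_steps, floor_abs,
                            range(grid$gx), range(grid$gy))
      if (nrow(line) >= min_points) out[[length(out) + 1L]] <- line
    }
  }
  out
}

bilinear_v <- function(grid, p) {
  gx <- grid$gx; gy <- grid$gy
  nx <- length(gx); ny <- length(gy)
  if (p[1] < gx[1] || p[1] > gx[nx] || p[2] < gy[1] || p[2] > gy[ny]) {
    return(NULL)
  }
  i <- min(max(findInterval(p[1], gx), 1L), nx - 1L)
  j <- min(max(findInterval(p[2], gy), 1L), ny - 1L)
  tx <- (p[1] - gx[i]) / (gx[i + 1] - gx[i])
  ty <- (p[2] - gy[j]) / (gy[j + 1] - gy[j])
  # grid_points were built with x varying fastest
  id <- function(ii, jj) (jj - 1L) * nx + ii
  v00 <- grid$grid_v[id(i, j), ]; v10 <- grid$grid_v[id(i + 1L, j), ]
  v01 <- grid$grid_v[id(i, j + 1L), ]; v11 <- grid$grid_v[id(i + 1L, j + 1L), ]
  (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
}

integrate_rk4 <- function(p0, interp, h, max_steps, floor_abs, xr, yr) {
  pts <- matrix(NA_real_, max_steps + 1L, 2L)
  pts[1L, ] <- p0
  p <- p0
  np <- 1L
  for (s in seq_len(max_steps)) {
    k1 <- interp(p); if (is.null(k1) || sqrt(sum(k1^2)) < floor_abs) break
    k2 <- interp(p + h / 2 * k1); if (is.null(k2)) break
    k3 <- interp(p + h / 2 * k2); if (is.null(k3)) break
    k4 <- interp(p + h * k3); if (is.null(k4)) break
    p <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (p[1] < xr[1] || p[1] > xr[2] || p[2] < yr[1] || p[2] > yr[2]) break
    np <- np + 1L
    pts[np, ] <- p
  }
  pts <- pts[seq_len(np), , drop = FALSE]
  colnames(pts) <- c("x", "y")
  pts
}

#' Render pseudotime and streamlines to a static figure
#'
#' Cells are drawn at their spatial positions colored by pseudotime, with the
#' streamline field overlaid.
#'
#' @param ds a [spatial_dataset()].
#' @param tau pseudotime (vector or `pseudotime_result`).
#' @param lines output of [streamlines()] (optional).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
plot_trajectory_map <- function(ds, tau, lines = NULL, path) {
  if (inherits(tau, "pseudotime_result")) tau <- tau$tau
  grDevices::png(path, width = 900, height = 800, res = 120)
  on.exit(grDevices::dev.off(), add = TRUE)
  pal <- grDevices::hcl.colors(100, "viridis")
  cols <- pal[pmax(1L, ceiling(tau * 99 + 1e-9))]
  graphics::plot(ds$coords, col = cols, pch = 16, cex = 0.7,
                 xlab = "x", ylab = "y", main = "pseudo-spatiotemporal map")
  if (!is.null(lines)) {
    for (ln in lines) graphics::lines(ln, col = grDevices::adjustcolor("grey20", 0.5))
  }
  invisible(path)
}

#' Export a grid field and its streamlines as JSON
#'
#' @param grid a [grid_interpolate()] result.
#' @param lines optional [streamlines()] output.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_field_json <- function(grid, lines = NULL, path) {
  out <- list(sigma = grid$sigma, b_res = grid$b_res, Q = grid$Q, e = grid$e,
              grid_points = unname(as.matrix(grid$grid_points)),
              grid_v = unname(as.matrix(grid$grid_v)))
  if (!is.null(lines)) {
    out$streamlines <- lapply(lines, function(l) unname(as.matrix(l)))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
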