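#' Configuration of the synthetic spatial-trajectory simulator
#'
#' The simulator emulates branching developmental processes laid out in
#' tissue space: per cell it draws a ground-truth time `t` in \[0, 1\] and a
#' branch, generates expression from branch-specific smooth gene programs of
#' `t` (sigmoidal marker activation, shared developmental programs,
#' housekeeping genes, negative-binomial count noise), and maps `(t, branch)`
#' to 2-D coordinates with Gaussian positional jitter.
#'
#' Topologies: `linear` (one path), `bifurcating` (shared trunk, two
#' branches), `trifurcating` (three branches), `dual_path` (two spatially and
#' temporally independent paths). Spatial patterns: `linear_map`
#' (branch-specific rays), `nonlinear_map` (curved branch paths), `radial`
#' (outward motion from a common origin). With `n_sections > 1` cells are
#' partitioned into consecutive time windows, each shifted into its own
#' coordinate frame (a multi-section, multi-timepoint design).
#'
#' @param topology one of `"linear"`, `"bifurcating"`, `"trifurcating"`,
#'   `"dual_path"`.
#' @param spatial_pattern one of `"linear_map"`, `"nonlinear_map"`, `"radial"`.
#' @param n_cells number of cells (>= 50; default 500).
#' @param n_genes number of genes (default 200).
#' @param n_marker_genes_per_branch marker genes per branch (default 10).
#' @param noise_sd count-noise level; negative-binomial dispersion is
#'   `size = 1/noise_sd^2` (default 0.3).
#' @param n_sections 1 for single-section; > 1 for the multi-section design.
#' @param branch_time_shift for `dual_path` only: the second path emerges at
#'   this time (its cells draw `t ~ U(shift, 1)`), emulating a
#'   later-arising lineage (default 0 = synchronous paths).
#' @param seed RNG seed.
#' @return a `sim_config`
#' @export
sim_config <- function(topology = c("linear", "bifurcating", "trifurcating",
                                    "dual_path"),
                       spatial_pattern = c("linear_map", "nonlinear_map",
                                           "radial"),
                       n_cells = 500L, n_genes = 200L,
                       n_marker_genes_per_branch = 10L, noise_sd = 0.3,
                       n_sections = 1L, branch_time_shift = 0,
                       seed = 1L) {
  topology <- match.arg(topology)
  spatial_pattern <- match.arg(spatial_pattern)
  if (n_cells < 50L) stop("n_cells must be >= 50", call. = FALSE)
  branches <- switch(topology, linear = 1L, bifurcating = 2L,
                     trifurcating = 3L, dual_path = 2L)
  if (n_genes < n_marker_genes_per_branch * branches) {
    stop("n_genes must be >= n_marker_genes_per_branch * branches", call. = FALSE)
  }
  structure(list(topology = topology, spatial_pattern = spatial_pattern,
                 n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_marker_genes_per_branch = as.integer(n_marker_genes_per_branch),
                 noise_sd = noise_sd, n_sections = as.integer(n_sections),
                 branch_time_shift = branch_time_shift,
                 seed = as.integer(seed), branches = branches),
            class = "sim_config")
}

sigmoid_curve <- function(t, center, width) 1 / (1 + exp(-(t - center) / width))

#' Simulate a spatial-trajectory dataset with ground truth
#'
#' @param cfg a [sim_config()].
#' @return a `sim_result`: `dataset` (a [spatial_dataset()] with cell-type
#'   and, when multi-section, section labels), `true_time` in \[0, 1\],
#'   `true_branch`, `true_direction` (n x 2 unit tangent vectors), and an
#'   `unspliced` count layer leading the spliced counts by a small time lag.
#' @export
simulate_trajectory <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_cells
  B <- cfg$branches
  t_split <- if (cfg$topology %in% c("bifurcating", "trifurcating")) 0.35 else 0
  t <- stats::runif(n)
  branch <- if (cfg$topology == "dual_path") {
    b <- sample(c("path_1", "path_2"), n, replace = TRUE)
    if (cfg$branch_time_shift > 0) {
      p2 <- b == "path_2"
      t[p2] <- cfg$branch_time_shift + t[p2] * (1 - cfg$branch_time_shift)
    }
    b
  } else if (B == 1L) {
    rep("branch_1", n)
  } else {
    ifelse(t < t_split, "trunk",
           sample(paste0("branch_", seq_len(B)), n, replace = TRUE))
  }
  branch_names <- if (cfg$topology == "dual_path") {
    paste0("path_", seq_len(B))
  } else paste0("branch_", seq_len(B))

  mu <- sim_expression_means(t, branch, branch_names, cfg, t_split)
  size <- 1 / cfg$noise_sd^2
  counts <- matrix(stats::rnbinom(length(mu$spliced), mu = mu$spliced,
                                  size = size),
                   n, cfg$n_genes, dimnames = dimnames(mu$spliced))
  unspliced <- matrix(stats::rnbinom(length(mu$unspliced), mu = mu$unspliced,
                                     size = size),
                      n, cfg$n_genes, dimnames = dimnames(mu$spliced))

  geo <- sim_coordinates(t, branch, branch_names, cfg, t_split)
  section <- NULL
  if (cfg$n_sections > 1L) {
    brk <- cut(t, breaks = seq(0, 1, length.out = cfg$n_sections + 1L),
               include.lowest = TRUE, labels = FALSE)
    section <- paste0("T", brk)
    geo$coords[, 1] <- geo$coords[, 1] + (brk - 1L) * 2.5 * geo$scale
  }
  cell_type <- ifelse(t < 0.15, "origin",
                      ifelse(t < 0.6, paste0("mid_", branch),
                             paste0("late_", branch)))
  ds <- spatial_dataset(counts, geo$coords, cell_type = cell_type,
                        section = section)
  structure(list(dataset = ds, true_time = t, true_branch = branch,
                 true_direction = geo$direction, unspliced = unspliced,
                 config = cfg),
            class = "sim_result")
}

# Smooth branch-specific mean programs; the unspliced layer leads by a lag.
sim_expression_means <- function(t, branch, branch_names, cfg, t_split,
                                 lag = 0.1) {
  n <- length(t)
  B <- length(branch_names)
  nm <- cfg$n_marker_genes_per_branch
  n_marker <- nm * B
  n_prog <- min(30L, cfg$n_genes - n_marker)
  n_hk <- cfg$n_genes - n_marker - n_prog
  gene_names <- c(
    unlist(lapply(branch_names, function(b) paste0("marker_", b, "_", seq_len(nm)))),
    if (n_prog > 0) paste0("prog_", seq_len(n_prog)),
    if (n_hk > 0) paste0("hk_", seq_len(n_hk)))

  mean_at <- function(tt) {
    M <- matrix(0.2, n, cfg$n_genes, dimnames = list(NULL, gene_names))
    col <- 0L
    for (b in branch_names) {
      on_b <- branch == b
      for (g in seq_len(nm)) {
        col <- col + 1L
        cen <- t_split + (1 - t_split) * (g - 0.5) / nm
        M[on_b, col] <- M[on_b, col] +
          8 * sigmoid_curve(tt[on_b], cen, 0.08)
      }
    }
    if (n_prog > 0) {
      for (g in seq_len(n_prog)) {
        col <- col + 1L
        cen <- (g - 0.5) / n_prog
        amp <- 6
        curve <- sigmoid_curve(tt, cen, 0.1)
        if (g %% 2 == 0) curve <- 1 - curve   # half the programs switch off
        M[, col] <- M[, col] + amp * curve
      }
    }
    if (n_hk > 0) M[, col + seq_len(n_hk)] <- 2
    M
  }
  list(spliced = mean_at(t), unspliced = mean_at(pmin(t + lag, 1)))
}

unit_vec <- function(theta) cbind(cos(theta), sin(theta))

# Spatial layout of (t, branch); returns coords, unit tangent directions and
# the tissue scale.
sim_coordinates <- function(t, branch, branch_names, cfg, t_split) {
  n <- length(t)
  L <- 100
  jitter_sd <- 0.03 * L
  B <- length(branch_names)
  theta_b <- switch(as.character(B),
                    "1" = 0,
                    "2" = c(-pi / 5, pi / 5),
                    c(-pi / 4, 0, pi / 4))
  names(theta_b) <- branch_names
  coords <- matrix(0, n, 2)
  direction <- matrix(0, n, 2)

  if (cfg$spatial_pattern == "radial") {
    spread <- pi / (2.5 * B)
    theta_i <- numeric(n)
    for (i in seq_len(n)) {
      base <- if (branch[i] %in% names(theta_b)) theta_b[[branch[i]]] else 0
      w <- if (branch[i] == "trunk") pi / 3 else spread
      theta_i[i] <- base + stats::runif(1, -w, w)
    }
    coords <- t * L * unit_vec(theta_i)
    direction <- unit_vec(theta_i)
  } else {
    curv <- if (cfg$spatial_pattern == "nonlinear_map") 0.6 else 0
    split_pos <- c(t_split * L, curv * t_split^2 * L)
    # independent dual paths run from separate origins in opposite directions
    origin_b <- list(path_1 = c(0, 0), path_2 = c(2.6 * L, 0.8 * L))
    angle_b <- c(path_1 = 0, path_2 = pi)
    for (i in seq_len(n)) {
      if (cfg$topology == "dual_path") {
        th <- angle_b[[branch[i]]]
        o <- origin_b[[branch[i]]]
        s <- t[i]
      } else if (branch[i] == "trunk") {
        th <- 0; o <- c(0, 0); s <- t[i]
      } else {
        th <- theta_b[[branch[i]]]
        o <- split_pos
        s <- t[i] - t_split
      }
      u <- c(cos(th), sin(th)); up <- c(-sin(th), cos(th))
      coords[i, ] <- o + s * L * u + curv * (s^2) * L * up
      dvec <- L * u + 2 * curv * s * L * up
      direction[i, ] <- dvec / sqrt(sum(dvec^2))
    }
  }
  coords <- coords + matrix(stats::rnorm(2 * n, sd = jitter_sd), n, 2)
  list(coords = coords, direction = direction, scale = L)
}

#' The five benchmark simulation designs
#'
#' Convenience constructor mirroring the benchmark suite: a bifurcating
#' design, trifurcating designs with linear and nonlinear spatial patterns,
#' an independent dual-path design, and a multi-section multi-timepoint
#' design.
#'
#' @param n_cells,seed forwarded to [sim_config()].
#' @return named list of `sim_config` objects.
#' @export
benchmark_designs <- function(n_cells = 500L, seed = 1L) {
  list(
    bifurcating = sim_config("bifurcating", "linear_map", n_cells = n_cells, seed = seed),
    trifurcating_linear = sim_config("trifurcating", "linear_map", n_cells = n_cells, seed = seed),
    trifurcating_nonlinear = sim_config("trifurcating", "nonlinear_map", n_cells = n_cells, seed = seed),
    dual_path = sim_config("dual_path", "linear_map", n_cells = n_cells, seed = seed),
    multisection = sim_config("dual_path", "linear_map", n_cells = n_cells,
                              n_sections = 4L, branch_time_shift = 0.3,
                              seed = seed)
  )
}
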