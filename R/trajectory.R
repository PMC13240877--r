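#' Select the start-cell set
#'
#' Two strategies based on prior knowledge: by cell type (all cells carrying
#' a given label) or by coordinate (the k nearest cells to a known
#' morphogenesis-center position; ties broken by lowest cell index).
#'
#' @param ds a [spatial_dataset()].
#' @param mode `"by_type"` or `"by_coord"`.
#' @param target_type label defining the start population (`by_type`).
#' @param center length-2 coordinate of the morphogenesis center (`by_coord`).
#' @param k number of neighbours around `center` (`by_coord`).
#' @return a `start_set` with `indices` (1-based) and the selection mode.
#' @export
select_start <- function(ds, mode = c("by_type", "by_coord"),
                         target_type = NULL, center = NULL, k = 10L) {
  mode <- match.arg(mode)
  if (mode == "by_type") {
    if (is.null(ds$cell_type)) stop("dataset has no cell_type labels", call. = FALSE)
    if (is.null(target_type) || !target_type %in% ds$cell_type) {
      stop(sprintf("cell type '%s' not present; available: %s",
                   target_type %||% "<missing>",
                   paste(unique(ds$cell_type), collapse = ", ")), call. = FALSE)
    }
    idx <- which(ds$cell_type == target_type)
  } else {
    if (is.null(center) || length(center) != 2L) {
      stop("by_coord requires a length-2 center", call. = FALSE)
    }
    if (k > n_cells(ds)) stop("k exceeds number of cells", call. = FALSE)
    d <- sqrt((ds$coords[, 1] - center[1])^2 + (ds$coords[, 2] - center[2])^2)
    idx <- order(d, seq_along(d))[seq_len(k)]   # stable tie-break by index
  }
  structure(list(indices = sort(idx), mode = mode,
                 target_type = target_type, center = center, k = k),
            class = "start_set")
}

#' Pseudotime by probability accumulation from the start set
#'
#' Accumulates the transport mass each cell receives from the start set,
#' `O_i = sum_{j in S} P_ji`, ranks cells by ascending `O` (stable tie-break
#' by cell index) and normalizes ranks to `tau_i = r_i / (N - 1)` in
#' \[0, 1\]. With `orient = "auto"` (default) the scale is flipped
#' (`tau <- 1 - tau`) whenever the mean tau of the start cells is >= 0.5, so
#' that tau ~ 0 always marks the initial state; `orient = "raw"` keeps the
#' raw ascending-rank convention.
#'
#' @param tm a `transition_matrix` (or plain plan).
#' @param start a [select_start()] result or an integer index vector.
#' @param orient `"auto"` or `"raw"`.
#' @return a `pseudotime_result` with `O`, integer ranks `r`, `tau`, the
#'   start set, and whether the orientation was flipped.
#' @export
pseudotime <- function(tm, start, orient = c("auto", "raw")) {
  orient <- match.arg(orient)
  P <- if (inherits(tm, "transition_matrix")) tm$P else as.matrix(tm)
  idx <- if (inherits(start, "start_set")) start$indices else as.integer(start)
  if (length(idx) == 0L) stop("start set is empty", call. = FALSE)
  n <- nrow(P)
  O <- colSums(P[idx, , drop = FALSE])
  if (max(O) - min(O) < .Machine$double.eps) {
    warning("accumulated probabilities are constant; ranking falls back to cell index")
  }
  r <- rank(O, ties.method = "first") - 1L
  flipped <- FALSE
  if (orient == "auto" && mean(r[idx] / (n - 1)) >= 0.5) {
    r <- (n - 1L) - r
    flipped <- TRUE
  }
  tau <- r / (n - 1)
  structure(list(O = O, r = r, tau = tau, start = start, flipped = flipped),
            class = "pseudotime_result")
}

#' Least-action path between two cells
#'
#' Builds a directed graph whose edge set is the union of the spatial-graph
#' edges and each cell's top-q transition partners, with edge cost
#' `-log(P_ij / max(P))`, and returns the minimum-cost (least-action) path
#' from `source` to `sink`.
#'
#' @param tm a `transition_matrix`.
#' @param source,sink cell indices (1-based), `source != sink`.
#' @param graph optional `spatial_graph` whose edges are added to the
#'   candidate set.
#' @param q number of top transition partners kept per cell (default 30).
#' @return a `lineage_path` with ordered `waypoints` and accumulated `cost`.
#' @export
least_action_path <- function(tm, source, sink, graph = NULL, q = 30L) {
  if (source == sink) stop("source and sink must differ", call. = FALSE)
  P <- if (inherits(tm, "transition_matrix")) tm$P else as.matrix(tm)
  n <- nrow(P)
  q <- min(q, n - 1L)
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    o <- order(P[i, ], decreasing = TRUE)
    o <- o[o != i][seq_len(q)]
    keep[i, o] <- TRUE
  }
  if (!is.null(graph)) keep <- keep | (as.matrix(graph$adjacency) != 0)
  diag(keep) <- FALSE
  keep <- keep & P > 0          # zero-probability transitions are inadmissible
  w <- -log(pmax(P, .Machine$double.xmin) / max(P))
  edges <- which(keep, arr.ind = TRUE)
  gg <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2],
               weight = w[edges]),
    directed = TRUE, vertices = data.frame(name = seq_len(n)))
  sp <- suppressWarnings(igraph::shortest_paths(
    gg, from = as.character(source), to = as.character(sink),
    mode = "out", output = "vpath"))
  path <- as.integer(igraph::as_ids(sp$vpath[[1]]))
  if (length(path) < 2L) {
    comp <- igraph::components(gg, mode = "weak")$membership
    stop(sprintf("sink %d unreachable from source %d (components %s vs %s)",
                 sink, source, comp[as.character(source)],
                 comp[as.character(sink)]), call. = FALSE)
  }
  cost <- sum(w[cbind(path[-length(path)], path[-1])])
  structure(list(waypoints = path, cost = cost, source = source, sink = sink),
            class = "lineage_path")
}

#' Score pseudotime-dependent genes by penalized-spline trend fits
#'
#' For each gene, fits `expression ~ s(tau)` with a penalized regression
#' spline and reports the deviance explained as the trend score, together
#' with the smoothed prediction on a regular tau grid. Genes are returned
#' ranked by score; constant genes score 0.
#'
#' @param ds a [spatial_dataset()].
#' @param tau pseudotime vector (or a `pseudotime_result`).
#' @param lineage optional `lineage_path`; when given, only cells on the
#'   path's waypoints are used (at least 20 required).
#' @param n_splines spline basis dimension (default 6).
#' @param grid_size number of tau grid points for the fitted curves.
#' @return list with `scores` (data frame: gene, score, rank) and `curves`
#'   (grid_size x genes matrix of fitted values), plus the `tau_grid`.
#' @export
trend_genes <- function(ds, tau, lineage = NULL, n_splines = 6L,
                        grid_size = 100L) {
  if (inherits(tau, "pseudotime_result")) tau <- tau$tau
  cells <- if (!is.null(lineage)) lineage$waypoints else seq_len(n_cells(ds))
  if (length(cells) < 20L) stop("need at least 20 cells on the lineage", call. = FALSE)
  X <- ds$expression[cells, , drop = FALSE]
  tt <- tau[cells]
  grid <- seq(min(tt), max(tt), length.out = grid_size)
  m <- ncol(X)
  scores <- numeric(m)
  curves <- matrix(NA_real_, grid_size, m,
                   dimnames = list(NULL, colnames(X)))
  for (j in seq_len(m)) {
    y <- X[, j]
    if (stats::sd(y) == 0) { scores[j] <- 0; curves[, j] <- y[1]; next }
    fit <- mgcv::gam(y ~ s(tt, k = n_splines))
    dev <- summary(fit)$dev.expl
    scores[j] <- if (is.finite(dev)) max(dev, 0) else 0
    curves[, j] <- as.numeric(stats::predict(fit, newdata = data.frame(tt = grid)))
  }
  ord <- order(scores, decreasing = TRUE)
  list(scores = data.frame(gene = colnames(X), score = scores,
                           rank = rank(-scores, ties.method = "first")),
       curves = curves, tau_grid = grid, ranked_genes = colnames(X)[ord])
}

#' Rank-correlation agreement between pseudotime and ground truth
#'
#' @param tau inferred pseudotime.
#' @param truth ground-truth developmental time (same length).
#' @return named vector `c(spearman, kendall)`; `NaN` with a warning when an
#'   input is constant.
#' @export
evaluate_pseudotime <- function(tau, truth) {
  stopifnot(length(tau) == length(truth))
  if (stats::sd(tau) == 0 || stats::sd(truth) == 0) {
    warning("constant input; correlation undefined")
    return(c(spearman = NaN, kendall = NaN))
  }
  c(spearman = stats::cor(tau, truth, method = "spearman"),
    kendall = stats::cor(tau, truth, method = "kendall"))
}

#' Write lineage paths as JSON (one path per line object)
#' @param paths list of `lineage_path` objects
#' @param path output file
#' @return `path`, invisibly
#' @export
write_paths <- function(paths, path) {
  out <- lapply(paths, function(p) list(waypoints = p$waypoints, cost = p$cost))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
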