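#' Build a shared embedding across sections / timepoints
#'
#' Cells from all sections are concatenated row-wise on their common gene
#' namespace, normalized (total-count + log1p), highly variable genes are
#' selected batch-aware (dispersion ranks averaged across sections), and the
#' result is reduced by PCA followed by 2-D UMAP. The shared space places all
#' sections in one coordinate system while preserving biological continuity;
#' no cross-section transition probabilities are ever computed.
#'
#' @param sections list of [spatial_dataset()] objects sharing (at least part
#'   of) a gene namespace.
#' @param n_hvg highly variable genes to keep (default 2000).
#' @param n_pcs principal components (default 30).
#' @param n_neighbors,min_dist UMAP parameters (defaults 30, 0.3).
#' @param seed RNG seed.
#' @return a `shared_embedding`: `umap_coords` (n_total x 2), `pca` scores,
#'   `section_index` (per-cell section id), `cell_section` (list of row
#'   ranges per section), and the input sections.
#' @export
build_shared_embedding <- function(sections, n_hvg = 2000L, n_pcs = 30L,
                                   n_neighbors = 30L, min_dist = 0.3,
                                   seed = 2025L) {
  stopifnot(length(sections) >= 1L)
  genes <- Reduce(intersect, lapply(sections, function(s) s$gene_names))
  if (length(genes) == 0L) {
    stop("sections share no genes (intersection size 0)", call. = FALSE)
  }
  full <- unique(unlist(lapply(sections, function(s) s$gene_names)))
  if (length(genes) < length(full)) {
    warning(sprintf("gene namespaces differ; proceeding on the %d-gene intersection",
                    length(genes)))
  }
  norm_list <- lapply(sections, function(s) {
    X <- s$expression[, genes, drop = FALSE]
    rs <- rowSums(X); rs[rs == 0] <- 1
    log1p(X / rs * 1e4)
  })
  # batch-aware HVG: average dispersion ranks across sections
  if (length(sections) > 1L) {
    ranks <- vapply(norm_list, function(X) rank(-gene_dispersion(X)),
                    numeric(length(genes)))
    hvg_order <- order(rowMeans(ranks))
  } else {
    hvg_order <- order(gene_dispersion(norm_list[[1]]), decreasing = TRUE)
  }
  keep <- sort(hvg_order[seq_len(min(n_hvg, length(genes)))])
  Xall <- do.call(rbind, lapply(norm_list, function(X) X[, keep, drop = FALSE]))
  n_total <- nrow(Xall)
  section_index <- rep(seq_along(sections),
                       vapply(sections, n_cells, 1L))
  set.seed(seed)
  n_pcs <- min(n_pcs, ncol(Xall) - 1L, n_total - 1L)
  pca <- if (n_pcs >= 0.5 * min(dim(Xall))) {
    Xc <- scale(Xall, center = TRUE, scale = FALSE)
    sv <- svd(Xc, nu = n_pcs, nv = 0)
    sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs, n_pcs)
  } else {
    irlba::prcomp_irlba(Xall, n = n_pcs, center = TRUE, scale. = FALSE)$x
  }
  um <- uwot::umap(pca, n_neighbors = min(n_neighbors, n_total - 1L),
                   min_dist = min_dist, n_threads = 1L)
  offsets <- c(0L, cumsum(vapply(sections, n_cells, 1L)))
  cell_rows <- lapply(seq_along(sections),
                      function(i) (offsets[i] + 1L):offsets[i + 1L])
  structure(list(umap_coords = um, pca = pca,
                 section_index = section_index, cell_rows = cell_rows,
                 sections = sections, genes_used = genes[keep]),
            class = "shared_embedding")
}

#' Single-section inference given an externally supplied embedding
#'
#' The per-section core of the multi-section strategy: spatial graph from the
#' section's own coordinates, density-adaptive fusion of the section's
#' spatial distances with distances in the supplied embedding, Sinkhorn
#' transport, pseudotime, and velocity expressed in the embedding
#' coordinates (for cross-section comparability).
#'
#' @param ds the section's [spatial_dataset()].
#' @param Z embedding coordinates for this section's cells (e.g. shared UMAP
#'   rows).
#' @param start a [select_start()] result or integer start indices.
#' @param alpha_min,alpha_max,alpha_prot,gamma,d_diag,kp,ke pipeline
#'   parameters (see [run_config()]).
#' @param delta_k neighbour count for the alpha-radius estimate.
#' @param ablation fusion ablation mode (see [run_config()]).
#' @return list with `tm`, `pt`, `vf` (velocity in embedding coordinates),
#'   `graph`, `weights`.
#' @export
infer_section <- function(ds, Z, start, alpha_min = 0.2, alpha_max = 0.8,
                          alpha_prot = alpha_min, gamma = 0.1, d_diag = 1e6,
                          kp = 15L, ke = 15L, delta_k = 6L,
                          ablation = "full") {
  coords <- ds$coords
  delta <- estimate_radius_delta(coords, k = min(delta_k, n_cells(ds) - 1L))
  graph <- build_alpha_adjacency(coords, delta)
  fus <- fuse_for_ablation(Z, coords, graph, ablation, alpha_min, alpha_max,
                           alpha_prot)
  cost <- build_cost_with_diagonal(fus$M, d_diag)
  tm <- sinkhorn_transition(cost, gamma = gamma)
  pt <- pseudotime(tm, start)
  # spatial neighbours from the section's own coordinates, embedding
  # neighbours from the shared space; displacement vectors in shared space
  nb <- neighbor_union(coords, Z, kp = min(kp, n_cells(ds) - 1L),
                       ke = min(ke, n_cells(ds) - 1L))
  vf <- cell_velocity(nb, tm, pt, Z)
  list(tm = tm, pt = pt, vf = vf, graph = graph, weights = fus$wm,
       embed_coords = Z)
}

# Shared fusion logic across the pipeline and the section core.
fuse_for_ablation <- function(Z, coords, graph, ablation, alpha_min,
                              alpha_max, alpha_prot) {
  wm <- NULL
  if (ablation == "no_fusion_module" || ablation == "no_spatial_reuse") {
    if (ablation == "no_spatial_reuse") {
      wm <- adaptive_weights(coords, graph, alpha_min, alpha_max, alpha_prot)
    }
    fused <- fuse_distances(Z, coords, 0)   # M = dg
  } else if (ablation == "no_adaptive_density") {
    fused <- fuse_distances(Z, coords, (alpha_min + alpha_max) / 2)
  } else {
    wm <- adaptive_weights(coords, graph, alpha_min, alpha_max, alpha_prot)
    fused <- fuse_distances(Z, coords, wm$alpha_tilde)
  }
  list(M = fused, wm = wm)
}

#' Per-section trajectory inference in a shared embedding space
#'
#' Runs [infer_section()] independently for every section, using each
#' section's rows of the shared embedding as its embedding coordinates.
#' Sections with fewer than 10 cells are skipped with a warning; a missing
#' start specification is an error naming the section.
#'
#' @param shared a [build_shared_embedding()] result.
#' @param starts list (one element per section) of start indices or
#'   `start_set` objects, indexed within each section.
#' @param ... forwarded to [infer_section()].
#' @return list of per-section results (see [infer_section()]); skipped
#'   sections carry `NULL`.
#' @export
per_section_inference <- function(shared, starts, ...) {
  k <- length(shared$sections)
  if (length(starts) != k) {
    missing_idx <- if (length(starts) < k) (length(starts) + 1L):k else integer(0)
    stop(sprintf("missing start specification for section(s): %s",
                 paste(missing_idx, collapse = ", ")), call. = FALSE)
  }
  out <- vector("list", k)
  for (i in seq_len(k)) {
    ds <- shared$sections[[i]]
    if (is.null(starts[[i]])) {
      stop(sprintf("missing start specification for section %d", i), call. = FALSE)
    }
    if (n_cells(ds) < 10L) {
      warning(sprintf("section %d has fewer than 10 cells; skipped", i))
      next
    }
    Z <- shared$umap_coords[shared$cell_rows[[i]], , drop = FALSE]
    out[[i]] <- infer_section(ds, Z, starts[[i]], ...)
  }
  out
}

#' Aggregate per-section velocity fields on a unified grid
#'
#' Pools every section's cells (at their shared-embedding coordinates) and
#' velocity vectors, then interpolates one grid field spanning the shared
#' space.
#'
#' @param results output of [per_section_inference()].
#' @param b_res,Q,e grid parameters (see [grid_interpolate()]).
#' @return a `grid_field` over the shared space.
#' @export
aggregate_fields <- function(results, b_res = 50L, Q = 1.0, e = 0.5) {
  results <- Filter(Negate(is.null), results)
  stopifnot(length(results) >= 1L)
  coords <- do.call(rbind, lapply(results, function(r) r$embed_coords))
  v <- do.call(rbind, lapply(results, function(r) r$vf$v))
  grid_interpolate(structure(list(v = v), class = "velocity_field"),
                   coords, b_res = b_res, Q = Q, e = e)
}

#' Globally projected pseudotime across ordered sections
#'
#' Sections are interpreted as consecutive time windows (in list order);
#' each cell's global pseudotime is `(section_rank - 1 + tau_within) /
#' n_sections`, mapping every section's local ordering into one global
#' \[0, 1\] scale.
#'
#' @param results output of [per_section_inference()].
#' @return numeric vector over all cells of all (non-skipped) sections, in
#'   concatenation order.
#' @export
global_pseudotime <- function(results) {
  ok <- !vapply(results, is.null, TRUE)
  k <- sum(ok)
  out <- lapply(seq_along(results), function(i) {
    if (!ok[i]) return(numeric(0))
    rk <- sum(ok[seq_len(i)])
    (rk - 1 + results[[i]]$pt$tau) / k
  })
  unlist(out)
}
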