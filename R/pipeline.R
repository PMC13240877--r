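#' End-to-end run configuration
#'
#' Nests every module's parameters and fixes the ablation mode and the seed,
#' which propagates to every stochastic component (masking, weight
#' initialization, sampling, K-means, PCA).
#'
#' Ablation modes: `full` (the complete method); `no_spatial_reuse` drops
#' the explicit spatial-distance term from the fused cost (`M = dg`);
#' `no_adaptive_density` fixes the fusion weight at the constant
#' `(alpha_min + alpha_max)/2`; `no_embedding` replaces the learned joint
#' embedding with a PCA of the (preprocessed) expression matrix;
#' `no_cluster_loss` removes the clustering term from the fine-tuning stage;
#' `no_fusion_module` removes the adaptive explicit spatial fusion entirely
#' (`M = dg`, no density estimation) while keeping the embedding term.
#'
#' @param seed integer seed (default 1).
#' @param ablation one of the modes above.
#' @param preprocess a [preprocess_config()] (`NULL` to skip preprocessing).
#' @param encoder an [encoder_config()]; its seed is overridden by `seed`.
#' @param weights a [loss_weights()].
#' @param delta_k neighbour count for the alpha-radius estimate.
#' @param alpha_min,alpha_max,alpha_prot density-weight bounds and the
#'   protected-cell weight.
#' @param bandwidth density bandwidth (`NULL` = data-driven default).
#' @param gamma entropy regularization coefficient.
#' @param d_diag diagonal self-transition penalty.
#' @param kp,ke velocity neighbour counts (spatial / embedding).
#' @param b_res,Q,e velocity grid parameters.
#' @param compute_streamlines integrate streamlines after gridding.
#' @param output_dir when non-`NULL`, per-cell results, figures and logs are
#'   written there.
#' @param verbose log stage timings to stderr.
#' @return a `run_config`
#' @export
run_config <- function(seed = 1L, ablation = c("full", "no_spatial_reuse",
                                               "no_adaptive_density",
                                               "no_embedding",
                                               "no_cluster_loss",
                                               "no_fusion_module"),
                       preprocess = preprocess_config(),
                       encoder = encoder_config(), weights = loss_weights(),
                       delta_k = 6L, alpha_min = 0.2, alpha_max = 0.8,
                       alpha_prot = alpha_min, bandwidth = NULL,
                       gamma = 0.1, d_diag = 1e6, kp = 15L, ke = 15L,
                       b_res = 50L, Q = 1.0, e = 0.5,
                       compute_streamlines = TRUE, output_dir = NULL,
                       verbose = FALSE) {
  ablation <- match.arg(ablation)
  encoder$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), ablation = ablation,
                 preprocess = preprocess, encoder = encoder,
                 weights = weights, delta_k = delta_k,
                 alpha_min = alpha_min, alpha_max = alpha_max,
                 alpha_prot = alpha_prot, bandwidth = bandwidth,
                 gamma = gamma, d_diag = d_diag, kp = kp, ke = ke,
                 b_res = b_res, Q = Q, e = e,
                 compute_streamlines = compute_streamlines,
                 output_dir = output_dir, verbose = verbose),
            class = "run_config")
}

# Hash of the serialized configuration; recorded in every output so
# identical hashes imply identical runs. Output location and verbosity do
# not affect results and are excluded.
config_hash <- function(cfg) {
  cfg$output_dir <- NULL
  cfg$verbose <- NULL
  raw <- as.integer(serialize(cfg, NULL, version = 2))
  h <- 5381
  for (b in raw) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

stage_log <- function(cfg, stage, t0, extra = "") {
  if (isTRUE(cfg$verbose)) {
    message(sprintf("[%s] %.2fs %s", stage,
                    as.numeric(Sys.time()) - t0, extra))
  }
}

#' Run the full trajectory-inference pipeline on one section
#'
#' Executes preprocessing, spatial-graph construction, joint-embedding
#' training (or its ablation), density-adaptive cost fusion, entropic
#' optimal transport, pseudotime, velocity and (optionally) streamlines.
#'
#' @param ds a [spatial_dataset()].
#' @param start a [select_start()] result, integer indices, or a function
#'   `f(ds)` returning either (evaluated after preprocessing).
#' @param cfg a [run_config()].
#' @return a `trajectory_bundle`: the preprocessed dataset, `graph`,
#'   `embedding` (`joint_embedding` or PCA matrix), `weights`, `fused`,
#'   `tm`, `pt`, `vf`, `grid`, `streamlines`, `config`, `config_hash`.
#' @export
run_pipeline <- function(ds, start, cfg = run_config()) {
  t0 <- as.numeric(Sys.time())
  hash <- config_hash(cfg)
  pp <- if (!is.null(cfg$preprocess)) {
    p <- cfg$preprocess
    if (!is.null(p$n_hvg)) p$n_hvg <- min(p$n_hvg, n_genes(ds))
    preprocess(ds, p)
  } else ds
  stage_log(cfg, "preprocess", t0, sprintf("%d x %d -> %d x %d",
                                           n_cells(ds), n_genes(ds),
                                           n_cells(pp), n_genes(pp)))
  if (is.function(start)) start <- start(pp)

  delta <- estimate_radius_delta(pp$coords, k = min(cfg$delta_k, n_cells(pp) - 1L))
  graph <- build_alpha_adjacency(pp$coords, delta)
  stage_log(cfg, "graph", t0, sprintf("%d edges, delta %.3g", graph$n_edges, delta))

  emb <- NULL
  if (cfg$ablation == "no_embedding") {
    Z <- pca_embedding(pp, d = cfg$encoder$hf + cfg$encoder$hg,
                       seed = cfg$seed)
  } else {
    w <- cfg$weights
    if (cfg$ablation == "no_cluster_loss") w$lambda_cluster <- 0
    emb <- fit_joint_embedding(pp, graph, cfg$encoder, w)
    Z <- emb$Z
  }
  stage_log(cfg, "embedding", t0, sprintf("Z: %d x %d", nrow(Z), ncol(Z)))

  fus <- fuse_for_ablation(Z, pp$coords, graph, cfg$ablation,
                           cfg$alpha_min, cfg$alpha_max, cfg$alpha_prot)
  cost <- build_cost_with_diagonal(fus$M, cfg$d_diag)
  tm <- sinkhorn_transition(cost, gamma = cfg$gamma)
  stage_log(cfg, "transport", t0, sprintf("%d iterations", tm$n_iter))

  pt <- pseudotime(tm, start)
  nb <- neighbor_union(pp$coords, Z, kp = min(cfg$kp, n_cells(pp) - 1L),
                       ke = min(cfg$ke, n_cells(pp) - 1L))
  vf <- cell_velocity(nb, tm, pt, pp$coords)
  grid <- grid_interpolate(vf, pp$coords, b_res = cfg$b_res, Q = cfg$Q,
                           e = cfg$e)
  sl <- if (isTRUE(cfg$compute_streamlines)) streamlines(grid) else NULL
  stage_log(cfg, "trajectory", t0, "")

  bundle <- structure(
    list(dataset = pp, graph = graph, embedding = emb, Z = Z,
         weights = fus$wm, fused = fus$M, tm = tm, pt = pt, vf = vf,
         grid = grid, streamlines = sl, config = cfg, config_hash = hash),
    class = "trajectory_bundle")
  if (!is.null(cfg$output_dir)) write_bundle(bundle, cfg$output_dir)
  bundle
}

#' @export
print.trajectory_bundle <- function(x, ...) {
  cat(sprintf("trajectory_bundle [%s, seed %d, hash %s]: %d cells, tau in [%.2f, %.2f]\n",
              x$config$ablation, x$config$seed, x$config_hash,
              n_cells(x$dataset), min(x$pt$tau), max(x$pt$tau)))
  invisible(x)
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vals <- list(tau = bundle$pt$tau,
               O = bundle$pt$O,
               v_x = bundle$vf$v[, 1], v_y = bundle$vf$v[, 2])
  if (!is.null(bundle$weights)) {
    vals$rho <- bundle$weights$rho
    vals$alpha_tilde <- bundle$weights$alpha_tilde
    vals$protected <- bundle$weights$protected
  }
  write_cell_results(bundle$dataset, vals, file.path(dir, "cells.csv"))
  if (!is.null(bundle$embedding)) {
    utils::write.csv(as.data.frame(bundle$Z),
                     file.path(dir, "embedding.csv"), row.names = FALSE)
  }
  jsonlite::write_json(
    list(config_hash = bundle$config_hash, seed = bundle$config$seed,
         ablation = bundle$config$ablation,
         n_cells = n_cells(bundle$dataset),
         sinkhorn_iterations = bundle$tm$n_iter,
         converged = bundle$tm$converged),
    file.path(dir, "run.json"), auto_unbox = TRUE)
  plot_trajectory_map(bundle$dataset, bundle$pt, bundle$streamlines,
                      file.path(dir, "trajectory.png"))
  invisible(dir)
}

#' Benchmark the pipeline (and its ablations) on simulated designs
#'
#' For every (design, mode, seed) triple the design is simulated, the
#' pipeline is run with start cells taken from the ground-truth origin
#' (the earliest-time cells, the prior knowledge a user would supply), and
#' Spearman/Kendall correlations between inferred pseudotime and true time
#' are recorded. Multi-section designs run the per-section shared-embedding
#' strategy and report the mean within-section correlation.
#'
#' @param designs named list of [sim_config()] objects (see
#'   [benchmark_designs()]).
#' @param modes character vector of ablation modes.
#' @param seeds integer seeds.
#' @param n_hvg,epochs optional overrides scaling the runs.
#' @return data frame with columns design, mode, seed, spearman, kendall.
#' @export
run_benchmark <- function(designs, modes = "full", seeds = 1L,
                          n_hvg = NULL, epochs = NULL) {
  if (length(modes) == 0L || length(designs) == 0L) {
    return(data.frame(design = character(0), mode = character(0),
                      seed = integer(0), spearman = numeric(0),
                      kendall = numeric(0)))
  }
  rows <- list()
  for (dn in names(designs)) {
    for (mode in modes) {
      for (sd_ in seeds) {
        scfg <- designs[[dn]]
        scfg$seed <- as.integer(sd_)
        res <- benchmark_one(scfg, mode, sd_, n_hvg = n_hvg, epochs = epochs)
        rows[[length(rows) + 1L]] <-
          data.frame(design = dn, mode = mode, seed = sd_,
                     spearman = res[["spearman"]], kendall = res[["kendall"]])
      }
    }
  }
  do.call(rbind, rows)
}

benchmark_one <- function(scfg, mode, seed, n_hvg = NULL, epochs = NULL) {
  sim <- simulate_trajectory(scfg)
  if (scfg$n_sections > 1L) {
    return(benchmark_multisection(sim, mode, seed))
  }
  enc <- encoder_config()
  if (!is.null(epochs)) {
    enc$epochs_pretrain <- enc$epochs_finetune <- as.integer(epochs)
  }
  cfg <- run_config(seed = seed, ablation = mode, encoder = enc,
                    preprocess = preprocess_config(n_hvg = n_hvg %||% 2000L),
                    compute_streamlines = FALSE)
  start <- truth_start(sim)
  bundle <- run_pipeline(sim$dataset, start, cfg)
  evaluate_pseudotime(bundle$pt$tau, sim$true_time)
}

# Start-cell prior: the earliest 10% of cells by ground-truth time (the
# stand-in for the biological prior knowledge a user supplies). With
# per_branch = TRUE the earliest cells of every lineage are included — the
# multi-lineage analogue of specifying one start population per lineage.
truth_start <- function(sim, frac = 0.1, cells = seq_along(sim$true_time),
                        per_branch = FALSE) {
  tt <- sim$true_time[cells]
  if (!per_branch) return(which(tt <= stats::quantile(tt, frac)))
  br <- sim$true_branch[cells]
  sort(unlist(lapply(unique(br), function(b) {
    w <- which(br == b)
    w[tt[w] <= stats::quantile(tt[w], frac)]
  })))
}

benchmark_multisection <- function(sim, mode, seed) {
  sections <- split_sections(sim$dataset)
  shared <- if (mode == "no_embedding") {
    sh <- build_shared_embedding(sections, seed = seed)
    sh$umap_coords <- sh$pca[, 1:2]
    sh
  } else build_shared_embedding(sections, seed = seed)
  sec_ids <- sections_order(sim$dataset)
  starts <- lapply(sec_ids, function(sid) {
    cells <- which(sim$dataset$section == sid)
    truth_start(sim, cells = cells, per_branch = TRUE)
  })
  res <- per_section_inference(shared, starts, ablation = mode)
  cors <- vapply(seq_along(res), function(i) {
    cells <- which(sim$dataset$section == sec_ids[i])
    evaluate_pseudotime(res[[i]]$pt$tau, sim$true_time[cells])[["spearman"]]
  }, 0)
  ken <- vapply(seq_along(res), function(i) {
    cells <- which(sim$dataset$section == sec_ids[i])
    evaluate_pseudotime(res[[i]]$pt$tau, sim$true_time[cells])[["kendall"]]
  }, 0)
  c(spearman = mean(cors), kendall = mean(ken))
}

sections_order <- function(ds) {
  ids <- unique(ds$section)
  ids[order(ids)]
}

#' Split a multi-section dataset into per-section datasets
#' @param ds a [spatial_dataset()] with section labels
#' @return named list of [spatial_dataset()], in section-label order
#' @export
split_sections <- function(ds) {
  if (is.null(ds$section)) stop("dataset has no section labels", call. = FALSE)
  ids <- sections_order(ds)
  stats::setNames(lapply(ids, function(sid) {
    sel <- ds$section == sid
    spatial_dataset(ds$expression[sel, , drop = FALSE],
                    ds$coords[sel, , drop = FALSE],
                    cell_type = ds$cell_type[sel],
                    section = ds$section[sel],
                    cell_ids = ds$cell_ids[sel])
  }), ids)
}

#' Summarize a benchmark table as mean +/- sd per design and mode
#' @param tab output of [run_benchmark()]
#' @return aggregated data frame
#' @export
summarize_benchmark <- function(tab) {
  agg <- stats::aggregate(cbind(spearman, kendall) ~ design + mode, tab,
                          function(x) c(mean = mean(x), sd = stats::sd(x)))
  out <- data.frame(design = agg$design, mode = agg$mode,
                    spearman_mean = agg$spearman[, "mean"],
                    spearman_sd = agg$spearman[, "sd"],
                    kendall_mean = agg$kendall[, "mean"],
                    kendall_sd = agg$kendall[, "sd"])
  out[order(out$design, out$mode), ]
}

#' Run a manifest-driven multi-section analysis
#'
#' The manifest is a TSV with columns `section_id`, `expression_path`,
#' `coords_path`, `start_spec`; `start_spec` is either `type:<label>` or
#' `coord:<x>,<y>,<k>`. Sections are read, embedded jointly, and inferred
#' per section.
#'
#' @param manifest_path path to the manifest TSV.
#' @param ... forwarded to [infer_section()].
#' @return list with `shared`, `results`, `global_tau`.
#' @export
run_multisection_manifest <- function(manifest_path, ...) {
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("section_id", "expression_path", "coords_path", "start_spec")
  if (!all(need %in% names(man))) {
    stop(sprintf("manifest must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  sections <- lapply(seq_len(nrow(man)), function(i) {
    read_spatial_dataset(man$expression_path[i], "csv_pair",
                         coords_path = man$coords_path[i])
  })
  names(sections) <- man$section_id
  shared <- build_shared_embedding(sections)
  starts <- lapply(seq_len(nrow(man)), function(i) {
    parse_start_spec(man$start_spec[i], sections[[i]])
  })
  results <- per_section_inference(shared, starts, ...)
  list(shared = shared, results = results,
       global_tau = global_pseudotime(results))
}

parse_start_spec <- function(spec, ds) {
  if (startsWith(spec, "type:")) {
    select_start(ds, "by_type", target_type = sub("^type:", "", spec))
  } else if (startsWith(spec, "coord:")) {
    parts <- as.numeric(strsplit(sub("^coord:", "", spec), ",")[[1]])
    select_start(ds, "by_coord", center = parts[1:2], k = as.integer(parts[3]))
  } else {
    stop(sprintf("unrecognized start_spec '%s'", spec), call. = FALSE)
  }
}
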