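#' Encoder configuration
#'
#' Hyperparameters of the dual-path encoder: a two-layer ReLU MLP mapping the
#' masked expression matrix to a feature embedding `Zf` (n x hf), and a
#' two-layer variational graph convolutional encoder producing the spatial
#' embedding `Zg` (n x hg) from `Zf` and the spatial graph. The joint
#' embedding is the column concatenation `Z = [Zf || Zg]`.
#'
#' @param h hidden width of both the encoder MLP and the reconstruction
#'   decoder.
#' @param hf feature-embedding dimension (must be < number of genes).
#' @param hg graph-embedding dimension.
#' @param seed RNG seed fixing weight initialization, masking, sampling and
#'   K-means (default 2025).
#' @param epochs_pretrain,epochs_finetune epochs of the two training stages.
#' @param lr Adam learning rate.
#' @param n_clusters number of K-means clusters initializing the clustering
#'   loss in the fine-tuning stage.
#' @param mask_fraction fraction of cells whose expression rows are replaced
#'   by learnable mask tokens during training.
#' @return an `encoder_config` list
#' @export
encoder_config <- function(h = 64L, hf = 32L, hg = 32L, seed = 2025L,
                           epochs_pretrain = 200L, epochs_finetune = 200L,
                           lr = 1e-3, n_clusters = 8L, mask_fraction = 0.2) {
  structure(list(h = as.integer(h), hf = as.integer(hf), hg = as.integer(hg),
                 seed = as.integer(seed),
                 epochs_pretrain = as.integer(epochs_pretrain),
                 epochs_finetune = as.integer(epochs_finetune),
                 lr = lr, n_clusters = as.integer(n_clusters),
                 mask_fraction = mask_fraction),
            class = "encoder_config")
}

#' Loss-term weights for the two training stages
#'
#' Pre-training minimizes `lambda_rec * Lrec + lambda_gcn * Lgcn +
#' lambda_self * Lself`; fine-tuning replaces the mask term by the clustering
#' term (`lambda_cluster * Lcluster`).
#'
#' @param lambda_rec weight of the full-matrix reconstruction loss (default 10).
#' @param lambda_gcn weight of the variational graph autoencoder loss
#'   (adjacency cross-entropy + KL; default 0.1).
#' @param lambda_self weight of the masked-row token loss (default 1).
#' @param lambda_cluster weight of the deep-embedded clustering loss (default 1).
#' @return a `loss_weights` list
#' @export
loss_weights <- function(lambda_rec = 10, lambda_gcn = 0.1,
                         lambda_self = 1, lambda_cluster = 1) {
  stopifnot(lambda_rec >= 0, lambda_gcn >= 0, lambda_self >= 0,
            lambda_cluster >= 0)
  structure(list(lambda_rec = lambda_rec, lambda_gcn = lambda_gcn,
                 lambda_self = lambda_self, lambda_cluster = lambda_cluster),
            class = "loss_weights")
}

#' Mask the expression matrix with learnable tokens
#'
#' Randomly selects `round(mask_fraction * n)` cells; their expression rows
#' are replaced by per-cell learnable token vectors (initialized small
#' Gaussian, updated during training). Unmasked rows pass through unchanged.
#'
#' @param X n x m expression matrix.
#' @param mask_fraction fraction in (0, 1); must leave at least one masked and
#'   one unmasked row.
#' @param seed RNG seed; the same seed reproduces the same mask set.
#' @return list with `X_prime` (masked matrix), `mask_set` (row indices),
#'   `tokens` (n x m token matrix; only masked rows are meaningful).
#' @export
mask_expression <- function(X, mask_fraction = 0.2, seed = 2025L) {
  n <- nrow(X)
  n_mask <- round(mask_fraction * n)
  if (n_mask < 1L || n_mask >= n) {
    stop(sprintf("mask_fraction %.3f yields |U| = %d of n = %d",
                 mask_fraction, n_mask, n), call. = FALSE)
  }
  set.seed(seed)
  U <- sort(sample.int(n, n_mask))
  tokens <- matrix(stats::rnorm(n * ncol(X), sd = 0.01), n, ncol(X))
  Xp <- X
  Xp[U, ] <- tokens[U, ]
  list(X_prime = Xp, mask_set = U, tokens = tokens)
}

#' Symmetric normalization of an adjacency matrix with self-loops
#'
#' Returns `D^{-1/2} (A + I) D^{-1/2}` where `D` is the degree matrix of
#' `A + I`; the self-loop guarantees every degree is at least 1, so isolated
#' nodes are safe.
#'
#' @param A sparse symmetric binary adjacency.
#' @return sparse normalized matrix.
#' @export
normalize_adjacency <- function(A) {
  n <- nrow(A)
  At <- A + Matrix::Diagonal(n)
  d <- Matrix::rowSums(At)
  Dm <- Matrix::Diagonal(n, 1 / sqrt(d))
  methods::as(Dm %*% At %*% Dm, "CsparseMatrix")
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

# All learnable parameters; initialization is fully determined by the seed.
init_embed_params <- function(n, m, cfg) {
  set.seed(cfg$seed)
  d <- cfg$hf + cfg$hg
  list(
    W1 = glorot(m, cfg$h),       b1 = matrix(0, 1, cfg$h),
    W2 = glorot(cfg$h, cfg$hf),  b2 = matrix(0, 1, cfg$hf),
    W0 = glorot(cfg$hf, cfg$hg),
    Wmu = glorot(cfg$hg, cfg$hg),
    Wsg = glorot(cfg$hg, cfg$hg),
    D1 = glorot(d, cfg$h),       c1 = matrix(0, 1, cfg$h),
    D2 = glorot(cfg$h, m),       c2 = matrix(0, 1, m)
  )
}

#' Feature-embedding encoder forward pass
#'
#' `Zf = ReLU(ReLU(X' W1 + b1) W2 + b2)`; the ReLU output guarantees a
#' nonnegative embedding.
#'
#' @param X_prime masked expression matrix (n x m).
#' @param params parameter list holding `W1, b1, W2, b2` (see
#'   [fit_joint_embedding()]); hand-set matrices are accepted.
#' @return n x hf nonnegative matrix `Zf`.
#' @export
encode_features <- function(X_prime, params) {
  check_finite(X_prime, "encoder input")
  H1 <- relu(sweep(X_prime %*% params$W1, 2L, params$b1, "+"))
  relu(sweep(H1 %*% params$W2, 2L, params$b2, "+"))
}

#' Variational graph encoder forward pass
#'
#' Two-layer GCN with symmetric normalization `D^{-1/2}(A+I)D^{-1/2}`:
#' a ReLU propagation layer followed by separate linear heads for the
#' posterior mean and log standard deviation. With `sample = TRUE` the
#' embedding is drawn by the reparameterization `Zg = mu + eps * exp(log_sigma)`;
#' with `sample = FALSE` (inference mode) `Zg = mu`.
#'
#' @param Zf feature embedding (n x hf).
#' @param graph a `spatial_graph` (or a sparse adjacency matrix).
#' @param params parameter list holding `W0, Wmu, Wsg`.
#' @param sample draw a reparameterized sample instead of returning the mean.
#' @param eps optional fixed n x hg noise matrix (used by training; drawn from
#'   the current RNG state when `NULL` and `sample = TRUE`).
#' @return list with `mu`, `log_sigma`, `Zg`.
#' @export
encode_graph_vgae <- function(Zf, graph, params, sample = FALSE, eps = NULL) {
  A <- if (inherits(graph, "spatial_graph")) graph$adjacency else graph
  S <- normalize_adjacency(A)
  G1 <- relu(as.matrix(S %*% (Zf %*% params$W0)))
  SG1 <- as.matrix(S %*% G1)
  mu <- SG1 %*% params$Wmu
  lsig <- clamp(SG1 %*% params$Wsg, -8, 8)
  if (anyNA(mu) || anyNA(lsig)) stop("NaN in graph propagation", call. = FALSE)
  Zg <- if (isTRUE(sample)) {
    if (is.null(eps)) eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
    mu + eps * exp(lsig)
  } else mu
  list(mu = mu, log_sigma = lsig, Zg = Zg)
}

clamp <- function(x, lo, hi) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

softplus <- function(x) {
  a <- abs(x)
  (x + a) / 2 + log1p(exp(-a))
}
sigmoid <- function(x) 1 / (1 + exp(-x))

add_bias <- function(X, b) X + rep(b, each = nrow(X))

# Precomputed structure of the VGAE cross-entropy target (A + I): linear
# indices of its positive entries in the dense n x n layout, the positive
# class weight, and the normalization constant.
bce_target <- function(A) {
  n <- nrow(A)
  At <- A + Matrix::Diagonal(n)
  Ti <- methods::as(At, "TsparseMatrix")
  idx <- (Ti@j) * n + Ti@i + 1L
  n_pos <- length(idx)
  list(idx = idx, n_pos = n_pos,
       pos_w = (n * n - n_pos) / n_pos,
       norm = n * n / (2 * (n * n - n_pos)))
}

# Full forward pass; returns every intermediate needed by the backward pass.
embed_forward <- function(params, X, U, S, bce, cfg, w, eps,
                          stage = c("pretrain", "finetune"),
                          centers = NULL, Ptarget = NULL) {
  stage <- match.arg(stage)
  n <- nrow(X); m <- ncol(X)
  Xp <- X
  Xp[U, ] <- params$tokens
  pre1 <- add_bias(Xp %*% params$W1, params$b1); H1 <- relu(pre1)
  pre2 <- add_bias(H1 %*% params$W2, params$b2); Zf <- relu(pre2)
  SZfW0 <- as.matrix(S %*% (Zf %*% params$W0)); G1 <- relu(SZfW0)
  SG1 <- as.matrix(S %*% G1)
  mu <- SG1 %*% params$Wmu
  lsig_raw <- SG1 %*% params$Wsg
  lsig <- clamp(lsig_raw, -8, 8)
  sig <- exp(lsig)
  Zg <- mu + eps * sig
  Z <- cbind(Zf, Zg)
  pre_d <- add_bias(Z %*% params$D1, params$c1); R1 <- relu(pre_d)
  Xhat <- add_bias(R1 %*% params$D2, params$c2)

  L_rec <- sum((Xhat - X)^2) / (n * m)
  # VGAE: positively reweighted cross-entropy on A + I, plus KL to N(0, I);
  # positive entries are addressed sparsely through bce$idx
  logits <- tcrossprod(Zg)
  sp <- softplus(logits)                 # softplus(-x) = softplus(x) - x
  sp_pos <- sp[bce$idx]
  L_bce <- bce$norm / (n * n) *
    (bce$pos_w * (sum(sp_pos) - sum(logits[bce$idx])) +
       (sum(sp) - sum(sp_pos)))
  L_kl <- -0.5 / n * sum(1 + 2 * lsig - mu^2 - sig^2)
  L_gcn <- L_bce + L_kl
  L_self <- if (stage == "pretrain") {
    sum((X[U, , drop = FALSE] - params$tokens)^2) / (length(U) * m)
  } else 0
  L_clu <- 0; Qmat <- NULL; Umat <- NULL
  if (stage == "finetune") {
    dz2 <- outer(rowSums(Z^2), rowSums(centers^2), "+") -
      2 * Z %*% t(centers)
    Umat <- 1 / (1 + pmax(dz2, 0))
    Qmat <- Umat / rowSums(Umat)
    L_clu <- sum(Ptarget * (log(Ptarget + 1e-12) - log(Qmat + 1e-12))) / n
  }
  total <- w$lambda_rec * L_rec + w$lambda_gcn * L_gcn +
    (if (stage == "pretrain") w$lambda_self * L_self else
       w$lambda_cluster * L_clu)
  list(Xp = Xp, pre1 = pre1, H1 = H1, pre2 = pre2, Zf = Zf, SZfW0 = SZfW0,
       G1 = G1, SG1 = SG1, mu = mu, lsig_raw = lsig_raw, lsig = lsig,
       sig = sig, Zg = Zg, Z = Z, pre_d = pre_d, R1 = R1, Xhat = Xhat,
       logits = logits, Qmat = Qmat, Umat = Umat,
       losses = c(total = total, rec = L_rec, gcn = L_gcn,
                  self = L_self, cluster = L_clu))
}

# Hand-derived backward pass; returns gradients for every parameter.
embed_backward <- function(params, fw, X, U, S, bce, cfg, w, eps,
                           stage = "pretrain", centers = NULL,
                           Ptarget = NULL) {
  n <- nrow(X); m <- ncol(X)
  g <- list()

  # reconstruction branch
  dXhat <- w$lambda_rec * 2 * (fw$Xhat - X) / (n * m)
  g$c2 <- matrix(colSums(dXhat), 1)
  g$D2 <- crossprod(fw$R1, dXhat)
  dR1 <- tcrossprod(dXhat, params$D2)
  dpre_d <- dR1 * (fw$pre_d > 0)
  g$c1 <- matrix(colSums(dpre_d), 1)
  g$D1 <- crossprod(fw$Z, dpre_d)
  dZ <- tcrossprod(dpre_d, params$D1)

  # clustering branch (fine-tune)
  if (stage == "finetune") {
    Wm <- (Ptarget - fw$Qmat) * fw$Umat              # n x K
    dZ_clu <- (2 / n) * (fw$Z * rowSums(Wm) - Wm %*% centers)
    dZ <- dZ + w$lambda_cluster * dZ_clu
    g$centers <- w$lambda_cluster * (-2 / n) *
      (t(Wm) %*% fw$Z - centers * colSums(Wm))
  }

  dZf <- dZ[, seq_len(cfg$hf), drop = FALSE]
  dZg <- dZ[, cfg$hf + seq_len(cfg$hg), drop = FALSE]

  # adjacency reconstruction (BCE with logits); positives patched sparsely
  cb <- w$lambda_gcn * bce$norm / (n * n)
  sg <- sigmoid(fw$logits)
  dlogit <- cb * sg
  dlogit[bce$idx] <- cb * (sg[bce$idx] * bce$pos_w - bce$pos_w)
  dZg <- dZg + dlogit %*% fw$Zg + crossprod(dlogit, fw$Zg)

  # KL
  dmu <- w$lambda_gcn * fw$mu / n
  dlsig <- w$lambda_gcn * (fw$sig^2 - 1) / n

  # reparameterization
  dmu <- dmu + dZg
  dlsig <- dlsig + dZg * eps * fw$sig
  dlsig <- dlsig * (fw$lsig_raw > -8 & fw$lsig_raw < 8)   # clamp mask

  g$Wmu <- crossprod(fw$SG1, dmu)
  g$Wsg <- crossprod(fw$SG1, dlsig)
  dSG1 <- tcrossprod(dmu, params$Wmu) + tcrossprod(dlsig, params$Wsg)
  dG1 <- as.matrix(S %*% dSG1)                             # S symmetric
  dpre_g <- dG1 * (fw$SZfW0 > 0)
  SZf <- as.matrix(S %*% fw$Zf)
  g$W0 <- crossprod(SZf, dpre_g)
  dZf <- dZf + as.matrix(S %*% tcrossprod(dpre_g, params$W0))

  # feature encoder
  dpre2 <- dZf * (fw$pre2 > 0)
  g$b2 <- matrix(colSums(dpre2), 1)
  g$W2 <- crossprod(fw$H1, dpre2)
  dH1 <- tcrossprod(dpre2, params$W2)
  dpre1 <- dH1 * (fw$pre1 > 0)
  g$b1 <- matrix(colSums(dpre1), 1)
  g$W1 <- crossprod(fw$Xp, dpre1)
  dXp <- tcrossprod(dpre1, params$W1)

  # mask tokens: flow from the encoder plus the direct token loss
  dtok <- dXp[U, , drop = FALSE]
  if (stage == "pretrain") {
    dtok <- dtok + w$lambda_self * 2 *
      (params$tokens - X[U, , drop = FALSE]) / (length(U) * m)
  }
  g$tokens <- dtok
  g
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Pre-train the joint embedding
#'
#' Stage one of the two-stage training: minimizes
#' `lambda_rec * Lrec + lambda_gcn * Lgcn + lambda_self * Lself` by Adam,
#' where `Lrec` is the mean-squared reconstruction of the full expression
#' matrix from a two-layer decoder on `Z`, `Lgcn` is the variational graph
#' autoencoder objective (weighted adjacency cross-entropy plus KL), and
#' `Lself` pulls each masked cell's learnable token toward its true
#' expression row. All randomness (mask, initialization, sampling) is fixed
#' by `cfg$seed`.
#'
#' @param ds a [spatial_dataset()]; its expression matrix is used as-is
#'   (preprocess first).
#' @param graph the [build_alpha_adjacency()] spatial graph.
#' @param cfg an [encoder_config()].
#' @param weights a [loss_weights()].
#' @return a `joint_embedding` object with fields `Zf`, `Zg`, `Z` (inference
#'   mode, `Zg = mu`), `mu`, `log_sigma`, per-epoch `losses`, and the trained
#'   `params`.
#' @export
pretrain <- function(ds, graph, cfg = encoder_config(),
                     weights = loss_weights()) {
  X <- ds$expression
  n <- nrow(X); m <- ncol(X)
  if (cfg$hf >= m) stop("hf must be < number of genes", call. = FALSE)
  msk <- mask_expression(X, cfg$mask_fraction, cfg$seed)
  params <- init_embed_params(n, m, cfg)
  params$tokens <- msk$tokens[msk$mask_set, , drop = FALSE]
  S <- normalize_adjacency(graph$adjacency)
  bce <- bce_target(graph$adjacency)
  st <- adam_init(params)
  rec <- vector("list", cfg$epochs_pretrain)
  set.seed(cfg$seed + 1L)    # sampling stream, distinct from init stream
  for (ep in seq_len(cfg$epochs_pretrain)) {
    eps <- matrix(stats::rnorm(n * cfg$hg), n, cfg$hg)
    fw <- embed_forward(params, X, msk$mask_set, S, bce, cfg, weights,
                        eps, stage = "pretrain")
    if (!is.finite(fw$losses[["total"]])) {
      stop(sprintf("training diverged at epoch %d", ep), call. = FALSE)
    }
    gr <- embed_backward(params, fw, X, msk$mask_set, S, bce, cfg,
                         weights, eps, stage = "pretrain")
    upd <- adam_step(params, gr, st, cfg$lr)
    params <- upd$params; st <- upd$state
    rec[[ep]] <- c(epoch = ep, fw$losses)
  }
  finalize_embedding(params, X, msk, S, graph, cfg, weights,
                     losses = do.call(rbind, rec), stage = "pretrain")
}

finalize_embedding <- function(params, X, msk, S, graph, cfg, weights,
                               losses, stage) {
  Xp <- X
  Xp[msk$mask_set, ] <- params$tokens
  Zf <- encode_features(Xp, params)
  enc <- encode_graph_vgae(Zf, graph, params, sample = FALSE)
  structure(list(Zf = Zf, Zg = enc$Zg, Z = cbind(Zf, enc$Zg),
                 mu = enc$mu, log_sigma = enc$log_sigma,
                 losses = as.data.frame(losses), params = params,
                 mask = msk, cfg = cfg, weights = weights, stage = stage),
            class = "joint_embedding")
}

#' @export
print.joint_embedding <- function(x, ...) {
  cat(sprintf("joint_embedding (%s): %d cells, Z = [Zf(%d) || Zg(%d)], final loss %.4g\n",
              x$stage, nrow(x$Z), ncol(x$Zf), ncol(x$Zg),
              tail(x$losses$total, 1)))
  invisible(x)
}

#' Fine-tune the embedding with a clustering objective
#'
#' Stage two: K-means (k = `cfg$n_clusters`, seeded) initializes cluster
#' centers on the pre-trained embedding, then
#' `lambda_rec * Lrec + lambda_gcn * Lgcn + lambda_cluster * Lcluster` is
#' minimized, where `Lcluster` is the deep-embedded-clustering KL divergence
#' between Student-t soft assignments and their sharpened targets. The mask
#' token loss is dropped in this stage.
#'
#' @param emb the result of [pretrain()].
#' @param ds,graph,cfg,weights as in [pretrain()].
#' @param target_update_every epochs between refreshes of the sharpened
#'   target distribution.
#' @return an updated `joint_embedding`.
#' @export
finetune_with_clustering <- function(emb, ds, graph, cfg = emb$cfg,
                                     weights = emb$weights,
                                     target_update_every = 10L) {
  X <- ds$expression
  n <- nrow(X)
  if (cfg$n_clusters > n) stop("n_clusters exceeds number of cells", call. = FALSE)
  params <- emb$params
  msk <- emb$mask
  S <- normalize_adjacency(graph$adjacency)
  bce <- bce_target(graph$adjacency)
  set.seed(cfg$seed + 2L)
  km <- stats::kmeans(emb$Z, centers = cfg$n_clusters, nstart = 5L)
  params$centers <- km$centers
  st <- adam_init(params)
  rec <- vector("list", cfg$epochs_finetune)
  Ptarget <- NULL
  set.seed(cfg$seed + 3L)
  for (ep in seq_len(cfg$epochs_finetune)) {
    eps <- matrix(stats::rnorm(n * cfg$hg), n, cfg$hg)
    if (is.null(Ptarget) || (ep - 1L) %% target_update_every == 0L) {
      Ptarget <- dec_target(params, X, msk$mask_set, S, cfg)
    }
    fw <- embed_forward(params, X, msk$mask_set, S, bce, cfg, weights,
                        eps, stage = "finetune", centers = params$centers,
                        Ptarget = Ptarget)
    if (!is.finite(fw$losses[["total"]])) {
      stop(sprintf("training diverged at epoch %d", ep), call. = FALSE)
    }
    gr <- embed_backward(params, fw, X, msk$mask_set, S, bce, cfg,
                         weights, eps, stage = "finetune",
                         centers = params$centers, Ptarget = Ptarget)
    upd <- adam_step(params, gr, st, cfg$lr)
    params <- upd$params; st <- upd$state
    rec[[ep]] <- c(epoch = ep, fw$losses)
  }
  finalize_embedding(params, X, msk, S, graph, cfg, weights,
                     losses = do.call(rbind, rec), stage = "finetune")
}

# Sharpened DEC target computed from the current inference-mode embedding.
dec_target <- function(params, X, U, S, cfg) {
  Xp <- X
  Xp[U, ] <- params$tokens
  Zf <- encode_features(Xp, params)
  G1 <- relu(as.matrix(S %*% (Zf %*% params$W0)))
  mu <- as.matrix(S %*% G1) %*% params$Wmu
  Z <- cbind(Zf, mu)
  dz2 <- outer(rowSums(Z^2), rowSums(params$centers^2), "+") -
    2 * Z %*% t(params$centers)
  Umat <- 1 / (1 + pmax(dz2, 0))
  Q <- Umat / rowSums(Umat)
  P <- Q^2 / matrix(colSums(Q), nrow(Q), ncol(Q), byrow = TRUE)
  P / rowSums(P)
}

#' Fit the joint embedding (pre-train then fine-tune)
#'
#' @inheritParams pretrain
#' @param finetune run the clustering fine-tuning stage (stage two).
#' @return a `joint_embedding`
#' @export
fit_joint_embedding <- function(ds, graph, cfg = encoder_config(),
                                weights = loss_weights(), finetune = TRUE) {
  emb <- pretrain(ds, graph, cfg, weights)
  if (isTRUE(finetune) && cfg$epochs_finetune > 0L) {
    emb <- finetune_with_clustering(emb, ds, graph, cfg, weights)
  }
  emb
}

#' Principal-component embedding of raw expression
#'
#' Bypasses both encoders: the ablation variant that uses only raw gene
#' information. Returns the top `d` principal components of the expression
#' matrix.
#'
#' @param ds a [spatial_dataset()]
#' @param d number of components (defaults to hf + hg of the default encoder).
#' @param seed seed for the truncated SVD.
#' @return n x d score matrix.
#' @export
pca_embedding <- function(ds, d = 64L, seed = 2025L) {
  X <- scale(ds$expression, center = TRUE, scale = FALSE)
  d <- min(d, ncol(X) - 1L, nrow(X) - 1L)
  set.seed(seed)
  if (d >= 0.5 * min(dim(X))) {
    sv <- svd(X, nu = d, nv = 0)
    sv$u %*% diag(sv$d[seq_len(d)], d, d)
  } else {
    sv <- irlba::irlba(X, nv = d)
    sv$u %*% diag(sv$d, d, d)
  }
}

#' Save / load a trained embedding checkpoint
#'
#' Stores the trained encoder parameters, configuration, mask and loss
#' history as one archive so an embedding can be reloaded without retraining.
#'
#' @param emb a `joint_embedding`.
#' @param path checkpoint path (RDS archive).
#' @return `path`, invisibly.
#' @export
save_embedding <- function(emb, path) {
  stopifnot(inherits(emb, "joint_embedding"))
  saveRDS(emb, path)
  invisible(path)
}

#' @rdname save_embedding
#' @return `load_embedding`: the restored `joint_embedding`.
#' @export
load_embedding <- function(path) {
  emb <- readRDS(path)
  stopifnot(inherits(emb, "joint_embedding"))
  emb
}
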