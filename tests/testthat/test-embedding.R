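test_that("masking replaces exactly the sampled rows and is seed-stable", {
  X <- matrix(rnorm(4 * 6), 4, 6)
  m1 <- mask_expression(X, 0.5, seed = 1)
  expect_length(m1$mask_set, 2L)
  m2 <- mask_expression(X, 0.5, seed = 1)
  expect_identical(m1$mask_set, m2$mask_set)
  # unmasked rows pass through bitwise
  un <- setdiff(1:4, m1$mask_set)
  expect_identical(m1$X_prime[un, ], X[un, ])
  expect_false(identical(m1$X_prime[m1$mask_set, ], X[m1$mask_set, ]))
  expect_error(mask_expression(X, 0.01), "\\|U\\| = 0")
  expect_error(mask_expression(X, 0.99), "\\|U\\| = 4")
})

test_that("feature encoder computes the two-layer ReLU map", {
  # hand-set 2x2 weights on a 1x2 input (computed by hand)
  params <- list(W1 = matrix(c(1, 0.5, -1, 1), 2, 2),
                 b1 = matrix(c(0.1, -0.2), 1),
                 W2 = matrix(c(1, -2), 2, 1),
                 b2 = matrix(0.3, 1))
  X <- matrix(c(1, 2), 1, 2)
  # pre1 = (2.1, 0.8); Zf = relu(2.1 - 1.6 + 0.3) = 0.8
  expect_equal(encode_features(X, params), matrix(0.8, 1, 1))

  # zero input with zero biases gives zero output of shape (n, hf)
  p0 <- list(W1 = matrix(rnorm(6), 3, 2), b1 = matrix(0, 1, 2),
             W2 = matrix(rnorm(4), 2, 2), b2 = matrix(0, 1, 2))
  Z0 <- encode_features(matrix(0, 5, 3), p0)
  expect_equal(Z0, matrix(0, 5, 2))
  expect_true(all(encode_features(matrix(rnorm(15), 5, 3), p0) >= 0))
  expect_error(encode_features(matrix(c(1, NA), 1, 2), p0), "non-finite")
})

test_that("graph encoder uses the symmetric-normalized propagation", {
  # 3-node path graph, identity weight matrices: mu = S relu(S Zf)
  A <- Matrix::sparseMatrix(i = c(1, 2, 2, 3), j = c(2, 1, 3, 2), x = 1,
                            dims = c(3, 3))
  S <- as.matrix(normalize_adjacency(A))
  S_hand <- matrix(0, 3, 3)
  S_hand[1, 1] <- 1 / 2; S_hand[3, 3] <- 1 / 2; S_hand[2, 2] <- 1 / 3
  S_hand[1, 2] <- S_hand[2, 1] <- 1 / sqrt(6)
  S_hand[2, 3] <- S_hand[3, 2] <- 1 / sqrt(6)
  expect_equal(S, S_hand, tolerance = 1e-12)

  Zf <- matrix(c(1, 0, 2, -1, 1, 0), 3, 2)
  params <- list(W0 = diag(2), Wmu = diag(2), Wsg = matrix(0, 2, 2))
  enc <- encode_graph_vgae(Zf, A, params, sample = FALSE)
  G1 <- pmax(S_hand %*% Zf, 0)
  expect_equal(enc$mu, S_hand %*% G1, tolerance = 1e-12)
  expect_equal(enc$Zg, enc$mu)
  # zero-weighted log-sigma head: sampling collapses onto the mean
  enc_s <- encode_graph_vgae(Zf, A, params, sample = TRUE,
                             eps = matrix(rnorm(6), 3, 2) * 0)
  expect_equal(enc_s$Zg, enc$mu)

  # single node with no edges: propagation reduces to a plain linear layer
  A1 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(1, 1))
  e1 <- encode_graph_vgae(matrix(c(1, 2), 1, 2), A1, params)
  expect_equal(e1$mu, matrix(c(1, 2), 1, 2))
})

test_that("analytic gradients match finite differences in both stages", {
  set.seed(42)
  n <- 8; m <- 6
  X <- matrix(abs(rnorm(n * m)), n, m)
  g <- build_alpha_adjacency(matrix(runif(n * 2, 0, 10), n, 2), delta = 6)
  cfg <- encoder_config(h = 5, hf = 3, hg = 3, seed = 7, mask_fraction = 0.25)
  msk <- mask_expression(X, cfg$mask_fraction, cfg$seed)
  params <- spotempo:::init_embed_params(n, m, cfg)
  params$tokens <- msk$tokens[msk$mask_set, , drop = FALSE]
  params$centers <- matrix(rnorm(2 * (cfg$hf + cfg$hg)), 2)
  S <- normalize_adjacency(g$adjacency)
  bce <- spotempo:::bce_target(g$adjacency)
  w <- loss_weights()
  eps <- matrix(rnorm(n * cfg$hg), n, cfg$hg)
  Pt <- spotempo:::dec_target(params, X, msk$mask_set, S, cfg)
  h <- 1e-6
  for (stg in c("pretrain", "finetune")) {
    lf <- function(p) {
      spotempo:::embed_forward(p, X, msk$mask_set, S, bce, cfg, w, eps, stg,
                               centers = p$centers,
                               Ptarget = Pt)$losses[["total"]]
    }
    fw <- spotempo:::embed_forward(params, X, msk$mask_set, S, bce, cfg, w,
                                   eps, stg, centers = params$centers,
                                   Ptarget = Pt)
    gr <- spotempo:::embed_backward(params, fw, X, msk$mask_set, S, bce, cfg,
                                    w, eps, stg, centers = params$centers,
                                    Ptarget = Pt)
    for (nm in names(gr)) {
      for (trial in 1:3) {
        i <- sample(length(params[[nm]]), 1)
        p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + h
        p3 <- params; p3[[nm]][i] <- p3[[nm]][i] - h
        num <- (lf(p2) - lf(p3)) / (2 * h)
        expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                     label = sprintf("%s grad of %s", stg, nm))
      }
    }
  }
})

test_that("loss weights enter the objective linearly", {
  set.seed(1)
  n <- 10; m <- 8
  X <- matrix(abs(rnorm(n * m)), n, m)
  g <- build_alpha_adjacency(matrix(runif(n * 2, 0, 10), n, 2), delta = 6)
  cfg <- encoder_config(h = 5, hf = 3, hg = 3, seed = 3)
  msk <- mask_expression(X, 0.2, cfg$seed)
  params <- spotempo:::init_embed_params(n, m, cfg)
  params$tokens <- msk$tokens[msk$mask_set, , drop = FALSE]
  S <- normalize_adjacency(g$adjacency)
  bce <- spotempo:::bce_target(g$adjacency)
  eps <- matrix(rnorm(n * cfg$hg), n, cfg$hg)
  fw <- function(w) spotempo:::embed_forward(params, X, msk$mask_set, S, bce,
                                             cfg, w, eps, "pretrain")$losses
  l_full <- fw(loss_weights())
  l_noself <- fw(loss_weights(lambda_self = 0))
  expect_equal(l_noself[["total"]],
               10 * l_noself[["rec"]] + 0.1 * l_noself[["gcn"]])
  expect_equal(l_full[["total"]] - l_noself[["total"]], l_full[["self"]])
})

test_that("pretraining reduces the loss and is deterministic under a seed", {
  sim <- toy_sim(100)
  ds <- preprocess(sim$dataset, preprocess_config(n_hvg = NULL))
  g <- build_alpha_adjacency(ds$coords, estimate_radius_delta(ds$coords))
  cfg <- fast_encoder(seed = 2025, epochs = 40)
  emb <- pretrain(ds, g, cfg)
  expect_lt(tail(emb$losses$total, 1), emb$losses$total[1])
  expect_equal(ncol(emb$Z), cfg$hf + cfg$hg)
  expect_true(all(emb$Zf >= 0))
  expect_identical(emb$Z, cbind(emb$Zf, emb$Zg))
  emb2 <- pretrain(ds, g, cfg)
  expect_equal(tail(emb2$losses$total, 1), tail(emb$losses$total, 1),
               tolerance = 1e-10)
  expect_equal(emb2$Z, emb$Z, tolerance = 1e-12)
})

test_that("clustering fine-tune runs and keeps the embedding contract", {
  sim <- toy_sim(100, topology = "trifurcating")
  ds <- preprocess(sim$dataset, preprocess_config(n_hvg = NULL))
  g <- build_alpha_adjacency(ds$coords, estimate_radius_delta(ds$coords))
  cfg <- fast_encoder(seed = 4, epochs = 30)
  emb <- fit_joint_embedding(ds, g, cfg)
  expect_equal(emb$stage, "finetune")
  expect_equal(ncol(emb$Z), cfg$hf + cfg$hg)
  expect_true(all(is.finite(emb$Z)))
  expect_error(
    finetune_with_clustering(pretrain(ds, g, cfg),
                             ds, g, encoder_config(n_clusters = 1000L)),
    "n_clusters")
})

test_that("PCA fallback embedding has the requested dimensions", {
  sim <- toy_sim(80)
  Z <- pca_embedding(sim$dataset, d = 10, seed = 1)
  expect_equal(dim(Z), c(80L, 10L))
})
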