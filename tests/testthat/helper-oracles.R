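# Independent oracles used by the tests. These are deliberately naive
# implementations, written separately from the package internals.

# Naive Sinkhorn: alternating marginal scaling on K = exp(-C/gamma) in the
# ordinary domain (valid only for moderate costs).
naive_sinkhorn <- function(cost, gamma, a = NULL, b = NULL, tol = 1e-12,
                           max_iter = 50000L) {
  n <- nrow(cost)
  if (is.null(a)) a <- rep(1 / n, n)
  if (is.null(b)) b <- rep(1 / n, n)
  K <- exp(-cost / gamma)
  u <- rep(1, n); v <- rep(1, n)
  for (it in seq_len(max_iter)) {
    u <- a / as.vector(K %*% v)
    v <- b / as.vector(t(K) %*% u)
    P <- u * K * rep(v, each = n)
    if (max(abs(rowSums(P) - a)) < tol && max(abs(colSums(P) - b)) < tol) break
  }
  u * K * rep(v, each = n)
}

circum <- function(p1, p2, p3) {
  # circumcenter and radius of a triangle; NULL when degenerate
  d <- 2 * (p1[1] * (p2[2] - p3[2]) + p2[1] * (p3[2] - p1[2]) +
              p3[1] * (p1[2] - p2[2]))
  if (abs(d) < 1e-12) return(NULL)
  ux <- ((sum(p1^2)) * (p2[2] - p3[2]) + (sum(p2^2)) * (p3[2] - p1[2]) +
           (sum(p3^2)) * (p1[2] - p2[2])) / d
  uy <- ((sum(p1^2)) * (p3[1] - p2[1]) + (sum(p2^2)) * (p1[1] - p3[1]) +
           (sum(p3^2)) * (p2[1] - p1[1])) / d
  list(center = c(ux, uy), radius = sqrt(sum((p1 - c(ux, uy))^2)))
}

# Brute-force Delaunay triangles by the empty-circumcircle test over all
# point triples (general position assumed).
brute_delaunay_triangles <- function(coords) {
  n <- nrow(coords)
  tris <- list()
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    cc <- circum(coords[i, ], coords[j, ], coords[k, ])
    if (is.null(cc)) next
    d2 <- (coords[, 1] - cc$center[1])^2 + (coords[, 2] - cc$center[2])^2
    d2[c(i, j, k)] <- Inf
    if (min(d2) > cc$radius^2 * (1 - 1e-9)) {
      tris[[length(tris) + 1L]] <- c(i, j, k)
    }
  }
  tris
}

# Brute-force alpha-complex 1-skeleton at scale delta: Delaunay edges whose
# filtration radius (diametral radius if the diametral disk is empty,
# otherwise the smallest incident-triangle circumradius) is <= delta.
brute_alpha_edges <- function(coords, delta) {
  tris <- brute_delaunay_triangles(coords)
  edges <- unique(do.call(rbind, lapply(tris, function(tr) {
    rbind(sort(tr[c(1, 2)]), sort(tr[c(1, 3)]), sort(tr[c(2, 3)]))
  })))
  keep <- logical(nrow(edges))
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    mid <- (coords[i, ] + coords[j, ]) / 2
    rad <- sqrt(sum((coords[i, ] - coords[j, ])^2)) / 2
    d2 <- (coords[, 1] - mid[1])^2 + (coords[, 2] - mid[2])^2
    d2[c(i, j)] <- Inf
    filt <- if (min(d2) >= rad^2 * (1 - 1e-9)) {
      rad
    } else {
      min(vapply(tris, function(tr) {
        if (i %in% tr && j %in% tr) {
          circum(coords[tr[1], ], coords[tr[2], ], coords[tr[3], ])$radius
        } else Inf
      }, 0))
    }
    keep[r] <- filt <= delta
  }
  e <- edges[keep, , drop = FALSE]
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

edge_matrix <- function(graph) {
  A <- as.matrix(graph$adjacency)
  w <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  e <- cbind(w[, 1], w[, 2])
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

brute_knn <- function(X, k, i) {
  d <- sqrt(colSums((t(X) - X[i, ])^2))
  d[i] <- Inf
  order(d)[seq_len(k)]
}

# Kendall tau by explicit concordant/discordant pair counting.
brute_kendall <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
  }
  s / (n * (n - 1) / 2)
}

# Exhaustive least-cost path over all simple paths (tiny graphs only).
brute_best_path <- function(w, allowed, source, sink) {
  n <- nrow(w)
  best <- list(cost = Inf, path = NULL)
  rec <- function(path, cost) {
    last <- path[length(path)]
    if (last == sink) {
      if (cost < best$cost) best <<- list(cost = cost, path = path)
      return(invisible())
    }
    for (nxt in seq_len(n)) {
      if (nxt %in% path || !allowed[last, nxt]) next
      rec(c(path, nxt), cost + w[last, nxt])
    }
  }
  rec(source, 0)
  best
}

# Small deterministic dataset used across tests.
toy_sim <- function(n = 120L, topology = "linear", pattern = "linear_map",
                    seed = 7L, ...) {
  simulate_trajectory(sim_config(topology, pattern, n_cells = n,
                                 n_genes = 60L,
                                 n_marker_genes_per_branch = 5L,
                                 seed = seed, ...))
}

fast_encoder <- function(seed = 2025L, epochs = 30L) {
  encoder_config(h = 32L, hf = 8L, hg = 8L, seed = seed,
                 epochs_pretrain = epochs, epochs_finetune = epochs,
                 n_clusters = 4L)
}
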