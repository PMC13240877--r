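test_that("neighbour union merges the two k-NN modalities", {
  set.seed(14)
  co <- matrix(runif(20, 0, 10), 10, 2)
  Z <- matrix(rnorm(30), 10, 3)
  nb <- neighbor_union(co, Z, kp = 3, ke = 2)
  for (i in 1:10) {
    expect_setequal(nb$spatial[[i]], brute_knn(co, 3, i))
    expect_setequal(nb$embed[[i]], brute_knn(Z, 2, i))
    expect_setequal(nb$union[[i]], union(nb$spatial[[i]], nb$embed[[i]]))
    expect_false(i %in% nb$union[[i]])
  }
  # kp = 0: union is exactly the embedding set
  nb0 <- neighbor_union(co, Z, kp = 0, ke = 3)
  for (i in 1:10) expect_setequal(nb0$union[[i]], nb0$embed[[i]])
  # identical modalities nest: |union| = max(kp, ke)
  nb_same <- neighbor_union(co, co, kp = 2, ke = 4)
  for (i in 1:10) expect_length(nb_same$union[[i]], 4L)
  expect_error(neighbor_union(co, Z, kp = 10, ke = 2), "smaller than n")
  expect_error(neighbor_union(co, Z, kp = 0, ke = 0), "kp \\+ ke")
})

test_that("cell velocity matches the signed probability-weighted mean", {
  # single later neighbour due east with p = 1: unit east vector
  co <- rbind(c(0, 0), c(5, 0))
  nb <- list(union = list(2L, 1L))
  P <- matrix(c(0, 1, 1, 0) / 2, 2, 2)
  vf <- cell_velocity(nb, P, tau = c(0, 1), co)
  expect_equal(vf$v[1, ], c(1, 0), tolerance = 1e-9)

  # two symmetric later neighbours, equal p: exact cancellation
  co3 <- rbind(c(0, 0), c(3, 0), c(-3, 0))
  nb3 <- list(union = list(c(2L, 3L), integer(0), integer(0)))
  P3 <- matrix(0, 3, 3); P3[1, 2] <- P3[1, 3] <- 0.2
  vf3 <- cell_velocity(nb3, P3, tau = c(0, 1, 1), co3)
  expect_equal(vf3$v[1, ], c(0, 0), tolerance = 1e-12)
  expect_equal(vf3$v[2, ], c(0, 0))   # empty neighbour set -> zero vector

  # 5-cell mixed-ordering hand case, term-by-term
  set.seed(31)
  co5 <- matrix(runif(10, 0, 4), 5, 2)
  tau5 <- c(0.1, 0.9, 0.4, 0.2, 0.6)
  P5 <- matrix(runif(25, 0.01, 1), 5, 5); diag(P5) <- 0
  Ni <- c(2L, 3L, 5L)
  nb5 <- list(union = c(list(Ni), rep(list(integer(0)), 4)))
  vf5 <- cell_velocity(nb5, P5, tau5, co5)
  p <- P5[1, Ni] / sum(P5[1, Ni])
  hand <- c(0, 0)
  for (k in seq_along(Ni)) {
    j <- Ni[k]
    dvec <- co5[j, ] - co5[1, ]
    gam <- if (tau5[j] >= tau5[1]) p[k] else -p[k]
    hand <- hand + gam * dvec / (sqrt(sum(dvec^2)) + 1e-10)
  }
  expect_equal(vf5$v[1, ], hand / 3, tolerance = 1e-12)
})

test_that("flipping pseudotime negates every velocity vector exactly", {
  sim <- toy_sim(80, pattern = "radial")
  co <- sim$dataset$coords
  set.seed(6)
  Z <- matrix(rnorm(80 * 4), 80, 4)
  nb <- neighbor_union(co, Z, 5, 5)
  P <- matrix(runif(6400, 0.001, 1), 80, 80); diag(P) <- 0
  tau <- sim$true_time
  # strict inequality everywhere so the tie branch cannot differ under a flip
  v1 <- cell_velocity(nb, P, tau, co)$v
  v2 <- cell_velocity(nb, P, 1 - tau, co)$v
  ties <- any(vapply(seq_len(80), function(i) {
    any(tau[nb$union[[i]]] == tau[i])
  }, TRUE))
  if (!ties) expect_equal(v2, -v1, tolerance = 1e-12)
})

test_that("grid interpolation follows the adaptive-kernel formula", {
  # printed-default arithmetic on the unit square: sigma = 1/98
  co <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  vf <- structure(list(v = matrix(c(1, 0), 4, 2, byrow = TRUE)),
                  class = "velocity_field")
  gr <- grid_interpolate(vf, co, b_res = 50, Q = 1.0, e = 0.5)
  expect_equal(gr$sigma, 1 / 98)
  expect_equal(dim(gr$grid_points), c(2500L, 2L))

  # two cells sharing v: every grid vector is parallel to v with magnitude
  # bounded by the kernel weight
  one <- structure(list(v = matrix(c(1, 0), 2, 2, byrow = TRUE)),
                   class = "velocity_field")
  g1 <- grid_interpolate(one, rbind(c(0, 0), c(1, 1)), b_res = 10)
  expect_true(all(abs(g1$grid_v[, 2]) < 1e-12))
  expect_true(all(g1$grid_v[, 1] >= 0 & g1$grid_v[, 1] <= 1))

  # uniform velocity over a dense grid of cells: interior grid vectors ~ v
  dense <- as.matrix(expand.grid(x = seq(0, 1, 0.05), y = seq(0, 1, 0.05)))
  vu <- structure(list(v = matrix(c(0.3, -0.2), nrow(dense), 2, byrow = TRUE)),
                  class = "velocity_field")
  gu <- grid_interpolate(vu, dense, b_res = 10, e = 2)
  interior <- gu$grid_points[, 1] > 0.2 & gu$grid_points[, 1] < 0.8 &
    gu$grid_points[, 2] > 0.2 & gu$grid_points[, 2] < 0.8
  expect_true(all(abs(gu$grid_v[interior, 1] - 0.3) < 0.05))
  expect_true(all(abs(gu$grid_v[interior, 2] + 0.2) < 0.05))
  # convex-combination bound where the kernel mass exceeds 1
  expect_true(all(sqrt(rowSums(gu$grid_v^2)) <=
                    max(sqrt(rowSums(vu$v^2))) + 1e-9))

  expect_error(grid_interpolate(one, rbind(c(0, 0), c(1, 1)), b_res = 1),
               "at least 2")
})

test_that("streamlines integrate the expected geometries", {
  co <- as.matrix(expand.grid(x = seq(0, 1, 0.1), y = seq(0, 1, 0.1)))
  east <- structure(list(v = matrix(c(1, 0), nrow(co), 2, byrow = TRUE)),
                    class = "velocity_field")
  gr <- grid_interpolate(east, co, b_res = 20, e = 2)
  sl <- streamlines(gr, seed_stride = 5)
  expect_gt(length(sl), 0)
  for (ln in sl) {
    expect_lt(diff(range(ln[, "y"])), 1e-6)          # horizontal lines
    expect_true(all(diff(ln[, "x"]) > 0))            # moving east
  }

  # pure rotation: curvature sign is constant along each arc
  rot <- structure(list(v = cbind(-(co[, 2] - 0.5), co[, 1] - 0.5)),
                   class = "velocity_field")
  gv <- grid_interpolate(rot, co, b_res = 20, e = 2)
  sr <- streamlines(gv, seed_stride = 6, max_steps = 100)
  expect_gt(length(sr), 0)
  long <- sr[vapply(sr, nrow, 1L) > 10]
  for (ln in long) {
    d1 <- diff(ln[, 1]); d2 <- diff(ln[, 2])
    cross <- d1[-length(d1)] * d2[-1] - d2[-length(d2)] * d1[-1]
    expect_true(all(cross >= -1e-12) || all(cross <= 1e-12))
  }

  zero <- structure(list(v = matrix(0, nrow(co), 2)), class = "velocity_field")
  gz <- grid_interpolate(zero, co, b_res = 10)
  expect_length(streamlines(gz), 0)
})
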