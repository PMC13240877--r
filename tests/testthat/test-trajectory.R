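test_that("start selection covers both strategies with stable ties", {
  X <- matrix(rpois(9, 5), 3, 3)
  co <- rbind(c(0, 0), c(2, 0), c(1, 5))
  ds <- spatial_dataset(X, co, cell_type = c("A", "A", "B"))
  s <- select_start(ds, "by_type", target_type = "A")
  expect_equal(s$indices, c(1L, 2L))
  expect_error(select_start(ds, "by_type", target_type = "Z"),
               "available: A, B")

  s2 <- select_start(ds, "by_coord", center = c(2, 0), k = 1)
  expect_equal(s2$indices, 2L)
  # center equidistant from cells 1 and 2: lowest index wins
  s3 <- select_start(ds, "by_coord", center = c(1, 0), k = 1)
  expect_equal(s3$indices, 1L)
  expect_error(select_start(ds, "by_coord", center = c(0, 0), k = 10), "k exceeds")
})

test_that("pseudotime follows the accumulation / rank / normalize chain", {
  # hand case: n = 3, start = {1}; O = first row of P
  P <- matrix(c(0, 0.3, 0.03,
                0.2, 0, 0.1,
                0.1, 0.05, 0), 3, 3, byrow = TRUE)
  pt <- pseudotime(P, 1L, orient = "raw")
  expect_equal(pt$O, c(0, 0.3, 0.03))       # column sums over start rows
  expect_equal(pt$r, c(0L, 2L, 1L))
  expect_equal(pt$tau, c(0, 1, 0.5))
  expect_setequal(pt$tau, c(0, 0.5, 1))

  # n = 2: tau is exactly {0, 1}
  pt2 <- pseudotime(matrix(c(0, 1, 1, 0) / 2, 2, 2), 1L, orient = "raw")
  expect_setequal(pt2$tau, c(0, 1))

  expect_warning(pseudotime(matrix(1 / 9, 3, 3), 1L), "constant")
})

test_that("tau is a bijection onto the rank grid and auto-orients", {
  set.seed(5)
  n <- 40
  P <- matrix(runif(n * n), n, n); P <- P / sum(P)
  pt <- pseudotime(P, 1:4)
  expect_setequal(pt$tau, (0:(n - 1)) / (n - 1))
  # auto orientation puts the start cells early
  expect_lt(mean(pt$tau[1:4]), 0.5)
  raw <- pseudotime(P, 1:4, orient = "raw")
  if (raw$flipped || pt$flipped) {
    expect_equal(sort(pt$tau), sort(raw$tau))
  }
  # flipping the start to the far end reverses the ordering statistic
  far <- order(pt$tau, decreasing = TRUE)[1:4]
  pt_rev <- pseudotime(P, far)
  expect_lt(cor(pt$tau, pt_rev$tau, method = "spearman"), 0)
})

test_that("least-action path picks the cheapest admissible route", {
  # 3-cell chain where only 1 -> 2 -> 3 has mass
  P <- matrix(1e-12, 3, 3)
  P[1, 2] <- 0.4; P[2, 3] <- 0.4
  lap <- least_action_path(P, 1, 3, q = 1)
  expect_equal(lap$waypoints, c(1L, 2L, 3L))

  # hand-set 4-cell plan: direct edge cheaper than any detour
  set.seed(9)
  P4 <- matrix(runif(16, 0.01, 0.05), 4, 4); diag(P4) <- 1e-12
  P4[1, 4] <- 0.5
  lap4 <- least_action_path(P4, 1, 4, q = 3)
  w <- -log(P4 / max(P4))
  allowed <- matrix(TRUE, 4, 4); diag(allowed) <- FALSE
  oracle <- brute_best_path(w, allowed, 1, 4)
  expect_equal(lap4$waypoints, oracle$path)
  expect_equal(lap4$cost, oracle$cost, tolerance = 1e-10)

  expect_error(least_action_path(P, 2, 2), "must differ")
  # unreachable sink: zero-probability transitions are inadmissible
  Pu <- matrix(0, 3, 3); Pu[2, 3] <- 0.5; Pu[3, 2] <- 0.5
  expect_error(least_action_path(Pu, 1, 2, q = 1), "unreachable")
})

test_that("LAP cost never increases when the candidate edge set grows", {
  set.seed(12)
  n <- 15
  P <- matrix(runif(n * n, 1e-4, 1e-2), n, n); diag(P) <- 1e-12
  costs <- vapply(c(2, 5, 14), function(q) {
    least_action_path(P, 1, n, q = q)$cost
  }, 0)
  expect_true(all(diff(costs) <= 1e-10))
})

test_that("trend scores separate structured genes from noise", {
  set.seed(21)
  n <- 200
  tau <- runif(n)
  X <- cbind(lin = 2 + 3 * tau,
             noise = rnorm(n),
             mono = 5 * plogis((tau - 0.5) / 0.1),
             const = rep(2, n))
  ds <- spatial_dataset(X, matrix(runif(n * 2), n, 2))
  tg <- trend_genes(ds, tau)
  sc <- setNames(tg$scores$score, tg$scores$gene)
  expect_gt(sc[["lin"]], 0.99)
  expect_lt(sc[["noise"]], 0.1)
  expect_equal(sc[["const"]], 0)
  # monotone gene: fitted endpoints ordered accordingly
  curve <- tg$curves[, "mono"]
  expect_lt(curve[1], curve[length(curve)])
  expect_equal(tg$scores$gene[tg$scores$rank == 1], "lin")
  expect_error(trend_genes(ds, tau, lineage = list(waypoints = 1:5)),
               "at least 20")
})

test_that("pseudotime evaluation returns both rank correlations", {
  tt <- runif(50)
  expect_equal(evaluate_pseudotime(tt, tt), c(spearman = 1, kendall = 1))
  expect_equal(evaluate_pseudotime(-tt, tt), c(spearman = -1, kendall = -1))
  x <- c(1, 2, 3, 5, 4)
  y <- c(1, 2, 3, 4, 5)
  expect_equal(evaluate_pseudotime(x, y)[["kendall"]], brute_kendall(x, y))
  expect_warning(r <- evaluate_pseudotime(rep(1, 5), 1:5), "constant")
  expect_true(all(is.nan(r)))
})
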