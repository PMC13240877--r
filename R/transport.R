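#' Apply the diagonal self-transition penalty to a fused cost
#'
#' Sets the diagonal of the cost matrix to a large constant `d_diag` so that
#' the transport plan cannot place mass on self-transitions. Off-diagonal
#' entries are untouched.
#'
#' @param M a `fused_cost` from [fuse_distances()], or a plain cost matrix
#'   normalized to \[0, 1\] off-diagonal.
#' @param d_diag diagonal penalty (default 1e6).
#' @return the cost matrix with the penalized diagonal.
#' @export
build_cost_with_diagonal <- function(M, d_diag = 1e6) {
  C <- if (inherits(M, "fused_cost")) M$M else as.matrix(M)
  off <- C; diag(off) <- -Inf
  if (d_diag <= max(off)) {
    warning("d_diag does not exceed the largest off-diagonal cost; self-transition suppression is ineffective")
  }
  diag(C) <- d_diag
  C
}

#' Entropy-regularized optimal transport by log-domain Sinkhorn
#'
#' Solves `min_P <P, M>_F + gamma * sum_ij P_ij log P_ij` subject to uniform
#' marginals `P 1 = a`, `P^T 1 = b`, `a = b = (1/n) 1`, by alternating dual
#' updates in the log domain (so a diagonal penalty of 1e6 at `gamma = 0.1`
#' cannot underflow). The returned plan is the joint coupling whose entries
#' sum to 1; each row sums to 1/n.
#'
#' @param cost finite n x n cost matrix (see [build_cost_with_diagonal()]).
#' @param gamma entropy regularization coefficient (> 0, default 0.1). Larger
#'   values give smoother plans, approaching the uniform plan.
#' @param tol maximum allowed marginal violation (default 1e-9).
#' @param max_iter iteration cap (default 10000).
#' @return a `transition_matrix`: the plan `P`, `gamma`, `d_diag`-penalized
#'   cost attributes, marginals `a`/`b`, iterations used `n_iter`, and a
#'   `converged` flag. Non-convergence warns instead of failing.
#' @export
sinkhorn_transition <- function(cost, gamma = 0.1, tol = 1e-9,
                                max_iter = 10000L) {
  cost <- as.matrix(cost)
  if (!all(is.finite(cost))) stop("cost must be finite", call. = FALSE)
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  n <- nrow(cost)
  a <- rep(1 / n, n); b <- rep(1 / n, n)
  la <- log(a); lb <- log(b)
  f <- rep(0, n); g <- rep(0, n)
  Cg <- cost / gamma
  converged <- FALSE
  it <- 0L
  viol <- Inf
  nr <- nrow(Cg)
  while (it < max_iter) {
    it <- it + 1L
    # f_i <- gamma * [log a_i - LSE_j((g_j - C_ij)/gamma)]
    f <- gamma * (la - row_logsumexp(rep(g / gamma, each = nr) - Cg))
    g <- gamma * (lb - col_logsumexp(f / gamma - Cg))
    if (it %% 10L == 0L || it == max_iter) {
      P <- exp(rep(g / gamma, each = nr) + (f / gamma - Cg))
      viol <- max(max(abs(rowSums(P) - a)), max(abs(colSums(P) - b)))
      if (viol < tol) { converged <- TRUE; break }
    }
  }
  P <- exp(rep(g / gamma, each = nr) + (f / gamma - Cg))
  if (!converged) {
    warning(sprintf("Sinkhorn did not reach tol %.1e in %d iterations (violation %.2e)",
                    tol, max_iter, viol))
  }
  structure(list(P = P, gamma = gamma, marginal_a = a, marginal_b = b,
                 n_iter = it, converged = converged,
                 marginal_violation = viol),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("transition_matrix: %d x %d, gamma = %g, %d iterations, %s (violation %.2e)\n",
              nrow(x$P), ncol(x$P), x$gamma, x$n_iter,
              if (x$converged) "converged" else "NOT converged",
              x$marginal_violation))
  invisible(x)
}

#' Row-stochastic view of a transport plan
#'
#' The raw plan's rows each sum to 1/n; consumers needing a true transition
#' probability from each cell rescale rows to sum to 1.
#'
#' @param tm a `transition_matrix` (or plain plan matrix).
#' @return row-stochastic matrix.
#' @export
row_normalize_plan <- function(tm) {
  P <- if (inherits(tm, "transition_matrix")) tm$P else as.matrix(tm)
  P / rowSums(P)
}

#' Threshold-sparsified export of a transport plan
#'
#' @param tm a `transition_matrix`.
#' @param path output path (MatrixMarket format).
#' @param threshold entries strictly below it are dropped (default 1e-12).
#' @return `path`, invisibly.
#' @export
write_plan <- function(tm, path, threshold = 1e-12) {
  P <- tm$P
  P[P < threshold] <- 0
  Matrix::writeMM(methods::as(Matrix::Matrix(P, sparse = TRUE), "CsparseMatrix"),
                  path)
  invisible(path)
}
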