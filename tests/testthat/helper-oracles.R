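# Independent oracles for the control solvers, built on the batch
# (stacked) formulation of the finite-horizon LQ problem rather than a
# Riccati recursion.

# Optimal first-step feedback map of a possibly time-varying LQ problem:
# minimize sum_k x_k' Qk x_k + u_k' R u_k + x_N' QN x_N over open-loop
# controls, by stacking x = H x0 + G u and solving the normal equations.
# Returns the matrix mapping x0 to the optimal u_0 (equals -F_0 of the
# dynamic-programming solution by certainty equivalence).
batch_lqr_first_step <- function(A_list, B_list, Q_list, QN, R, N) {
  n <- nrow(QN); m <- ncol(B_list[[1]])
  # state stack covers x_1..x_N
  H <- matrix(0, n * N, n)
  G <- matrix(0, n * N, m * N)
  Phi <- diag(n)
  for (k in 1:N) {
    rows <- (k - 1) * n + 1:n
    # x_k = A_{k-1} x_{k-1} + B_{k-1} u_{k-1}
    Phi <- A_list[[k]] %*% Phi
    H[rows, ] <- Phi
    for (j in 1:k) {
      Mj <- B_list[[j]]
      if (j < k) for (l in (j + 1):k) Mj <- A_list[[l]] %*% Mj
      G[rows, (j - 1) * m + 1:m] <- Mj
    }
  }
  Qbar <- matrix(0, n * N, n * N)
  for (k in 1:N) {
    rows <- (k - 1) * n + 1:n
    Qbar[rows, rows] <- if (k == N) QN + Q_list[[k]] else Q_list[[k]]
  }
  Rbar <- kronecker(diag(N), R)
  U <- -solve(crossprod(G, Qbar %*% G) + Rbar, crossprod(G, Qbar %*% H))
  U[1:m, , drop = FALSE]   # u_0 = U0 x0
}

# first-step best-response gain of player "self" to a frozen partner gain
# sequence F_other, with the alpha-weighted partner control cost folded
# into the running state cost
best_response_first_gain <- function(A, B_self, B_other, F_other,
                                     Q_self, QN_self, R_self, R_other,
                                     alpha, N) {
  A_list <- lapply(1:N, function(k) A - B_other %*% F_other[[k]])
  # Q_list indexes x_1..x_N: the cost on x_k (k < N) is the running state
  # cost plus the alpha-weighted partner control cost at step k (partner
  # plays u = -F_other[[k+1]] x_k); the terminal matrix is added inside
  # the batch solver. Q_self/QN_self must already combine self + alpha *
  # partner state costs.
  Q_list <- lapply(1:N, function(k) {
    if (k == N) matrix(0, nrow(A), nrow(A)) else
      Q_self + alpha * crossprod(F_other[[k + 1]], R_other %*% F_other[[k + 1]])
  })
  -batch_lqr_first_step(A_list, lapply(1:N, function(k) B_self),
                        Q_list, QN_self, R_self, N)
}

# random small two-player game instance
random_game <- function(n = 3L, m = 2L, N = 4L, alpha = 0.5) {
  A <- matrix(stats::rnorm(n * n, sd = 0.5), n); diag(A) <- diag(A) + 0.5
  B1 <- matrix(stats::rnorm(n * m), n)
  B2 <- matrix(stats::rnorm(n * m), n)
  psd <- function() {M <- matrix(stats::rnorm(n * n), n); crossprod(M) / n}
  Q1N <- psd(); Q2N <- psd()
  R <- diag(stats::runif(m, 0.5, 2), m)
  zero <- matrix(0, n, n)
  dyn <- list(A = A, B1 = B1, B2 = B2)
  cost1 <- structure(list(Q = zero, QN = Q1N, R = R, alpha = alpha),
                     class = "cost_spec")
  cost2 <- structure(list(Q = zero, QN = Q2N, R = R, alpha = alpha),
                     class = "cost_spec")
  list(dyn = dyn, cost1 = cost1, cost2 = cost2, N = N)
}
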