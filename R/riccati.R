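#' Solve the finite-horizon Nash feedback gains of the two-player game
#'
#' Backward coupled-Riccati recursion for the linear-quadratic dynamic
#' game in which controller i minimizes the joint cost
#' `J_i + alpha_i J_j` and plays a linear state feedback
#' `u_i = -F_i x`. At each time step, given the two value matrices of the
#' following step, the pair of gains solves the coupled stationarity
#' conditions
#' `F1 = (R11 + B1' P1 B1)^{-1} B1' P1 (A - B2 F2)` (and symmetrically
#' for F2), found by fixed-point iteration initialized from the previous
#' step's gains; the value matrices are then propagated through the
#' jointly closed loop. The result is a feedback Nash equilibrium: each
#' gain sequence is the optimal LQR response to the plant with the
#' partner's policy frozen and the alpha-weighted partner control cost
#' folded into the running state cost.
#'
#' @param dyn a [build_dynamics()] object (or any list with conformable
#'   `A`, `B1`, `B2`).
#' @param cost1,cost2 `"cost_spec"` objects from [build_costs()].
#' @param horizon_steps number of control steps N; gains are indexed
#'   0..N-1 (list positions 1..N).
#' @param tol convergence tolerance on the per-step gain change.
#' @param max_iter maximum fixed-point iterations per step.
#' @param damping step size in (0, 1] of the fixed-point update; 1 is the
#'   plain iteration.
#' @return Object of class `"feedback_gains"`: list with gain sequences
#'   `F1`, `F2` (lists of N matrices), `partner_representation = TRUE`,
#'   and the solver residual.
#' @seealso [solve_decoupled_gains()] for the no-partner-representation
#'   policy.
#' @export
solve_nash_gains <- function(dyn, cost1, cost2, horizon_steps,
                             tol = 1e-10, max_iter = 500L, damping = 1) {
  A <- dyn$A; B1 <- dyn$B1; B2 <- dyn$B2
  N <- as.integer(horizon_steps)
  stopifnot(N >= 1L)
  a1 <- cost1$alpha; a2 <- cost2$alpha
  R11 <- cost1$R; R22 <- cost2$R
  P1 <- cost1$QN + a1 * cost2$QN
  P2 <- cost2$QN + a2 * cost1$QN
  Q1run <- cost1$Q + a1 * cost2$Q
  Q2run <- cost2$Q + a2 * cost1$Q

  F1s <- vector("list", N); F2s <- vector("list", N)
  F1 <- matrix(0, ncol(B1), nrow(A)); F2 <- matrix(0, ncol(B2), nrow(A))
  worst <- 0
  for (k in N:1) {
    P1B1 <- P1 %*% B1; P2B2 <- P2 %*% B2
    G1 <- solve(R11 + crossprod(B1, P1B1))   # (R + B'PB)^{-1}, 2x2
    G2 <- solve(R22 + crossprod(B2, P2B2))
    B1tP1 <- t(P1B1); B2tP2 <- t(P2B2)
    B1tP1A <- B1tP1 %*% A; B2tP2A <- B2tP2 %*% A
    B1tP1B2 <- B1tP1 %*% B2; B2tP2B1 <- B2tP2 %*% B1
    it <- 0L; delta <- Inf
    while (delta > tol && it < max_iter) {
      F1n <- G1 %*% (B1tP1A - B1tP1B2 %*% F2)
      F2n <- G2 %*% (B2tP2A - B2tP2B1 %*% F1n)
      if (damping < 1) {
        F1n <- F1 + damping * (F1n - F1)
        F2n <- F2 + damping * (F2n - F2)
      }
      delta <- max(max(abs(F1n - F1)), max(abs(F2n - F2)))
      F1 <- F1n; F2 <- F2n
      it <- it + 1L
    }
    if (delta > tol)
      stop(sprintf(paste0("coupled Riccati fixed point did not converge at ",
                          "step %d: residual %.3e after %d iterations"),
                   k - 1L, delta, it), call. = FALSE)
    worst <- max(worst, delta)
    F1s[[k]] <- F1; F2s[[k]] <- F2
    Acl <- A - B1 %*% F1 - B2 %*% F2
    P1 <- Q1run + crossprod(F1, R11 %*% F1) + a1 * crossprod(F2, R22 %*% F2) +
      crossprod(Acl, P1 %*% Acl)
    P2 <- Q2run + crossprod(F2, R22 %*% F2) + a2 * crossprod(F1, R11 %*% F1) +
      crossprod(Acl, P2 %*% Acl)
    P1 <- (P1 + t(P1)) / 2
    P2 <- (P2 + t(P2)) / 2
  }
  structure(list(F1 = F1s, F2 = F2s, partner_representation = TRUE,
                 residual = worst, horizon_steps = N),
            class = "feedback_gains")
}

# time-varying finite-horizon LQR backward recursion (single player)
lqr_gains <- function(A, B, Q, QN, R, N) {
  P <- QN
  Fs <- vector("list", N)
  for (k in N:1) {
    PB <- P %*% B
    Fk <- solve(R + crossprod(B, PB), t(PB) %*% A)
    Fs[[k]] <- Fk
    Acl <- A - B %*% Fk
    P <- Q + crossprod(Fk, R %*% Fk) + crossprod(Acl, P %*% Acl)
    P <- (P + t(P)) / 2
  }
  Fs
}

#' Solve decoupled (no partner representation) feedback gains
#'
#' Each controller's policy is the single-player finite-horizon LQR
#' solution computed under the assumption that the partner does not act
#' (`F_partner = 0`). Both controllers' decoupled gains are returned so
#' the simulator can roll out a pair in which neither represents the
#' other; the `partner_representation` flag is `FALSE`, which also makes
#' each controller's state estimator predict a zero partner command.
#'
#' @inheritParams solve_nash_gains
#' @return `"feedback_gains"` object with `partner_representation = FALSE`.
#' @export
solve_decoupled_gains <- function(dyn, cost1, cost2, horizon_steps) {
  N <- as.integer(horizon_steps)
  stopifnot(N >= 1L)
  F1s <- lqr_gains(dyn$A, dyn$B1, cost1$Q, cost1$QN, cost1$R, N)
  F2s <- lqr_gains(dyn$A, dyn$B2, cost2$Q, cost2$QN, cost2$R, N)
  structure(list(F1 = F1s, F2 = F2s, partner_representation = FALSE,
                 residual = 0, horizon_steps = N),
            class = "feedback_gains")
}

#' Solve the feedback gains prescribed by a policy hypothesis
#'
#' Dispatches to [solve_nash_gains()] for the three
#' partner-representation hypotheses (with alpha 0, 1 or 0.5) and to
#' [solve_decoupled_gains()] for the no-representation hypothesis.
#'
#' @param dyn a [build_dynamics()] object.
#' @param condition one of [conditions()].
#' @param hypothesis one of [hypotheses()] or a [policy_hypothesis()].
#' @param params a [model_params()] object.
#' @return `"feedback_gains"` object.
#' @export
solve_policy_gains <- function(dyn, condition, hypothesis, params) {
  if (is.character(hypothesis)) hypothesis <- policy_hypothesis(hypothesis)
  cs <- build_costs(condition, hypothesis, params)
  if (hypothesis$partner_representation)
    solve_nash_gains(dyn, cs$cost1, cs$cost2, params$horizon_steps)
  else
    solve_decoupled_gains(dyn, cs$cost1, cs$cost2, params$horizon_steps)
}
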