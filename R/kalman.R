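#' Precompute time-varying Kalman gain sequences
#'
#' Standard discrete-time Kalman covariance recursion for the delayed
#' observation model: prior covariance `S- = A S A' + W`, gain
#' `K = S- C' (C S- C' + V)^{-1}`, posterior `S = (I - K C) S-`. The
#' process noise `W` acts on the current base-state block only (history
#' slots are exact copies).
#'
#' @param dyn a [build_dynamics()] object.
#' @param C observation matrix (one controller's, from
#'   [build_observation()]).
#' @param V measurement noise covariance (positive definite).
#' @param W process noise covariance on the augmented state; if `NULL`,
#'   built from `params$process_noise_sd` on the base block.
#' @param params a [model_params()] object (for defaults).
#' @param horizon_steps number of steps.
#' @param S0 initial state covariance; default `1e-4 * I`.
#' @return List with `K` (list of gain matrices) and `S` (list of
#'   posterior covariances).
#' @export
compute_kalman_gains <- function(dyn, C, V, W = NULL, params = NULL,
                                 horizon_steps = NULL, S0 = NULL) {
  n <- nrow(dyn$A)
  if (is.null(W)) {
    stopifnot(!is.null(params))
    w <- numeric(n)
    w[1:BASE_DIM] <- params$process_noise_sd^2
    W <- diag(w, n)
  }
  if (is.null(horizon_steps)) horizon_steps <- params$horizon_steps
  if (is.null(S0)) S0 <- diag(1e-4, n)
  N <- as.integer(horizon_steps)
  S <- S0
  Ks <- vector("list", N); Ss <- vector("list", N)
  for (k in seq_len(N)) {
    Sm <- dyn$A %*% S %*% t(dyn$A) + W
    Sm <- (Sm + t(Sm)) / 2
    CS <- C %*% Sm
    innov <- CS %*% t(C) + V
    K <- t(solve(innov, CS))   # Sm C' innov^{-1}
    if (!all(is.finite(K)))
      stop("singular innovation covariance in Kalman recursion at step ", k,
           call. = FALSE)
    S <- Sm - K %*% CS
    S <- (S + t(S)) / 2
    Ks[[k]] <- K; Ss[[k]] <- S
  }
  list(K = Ks, S = Ss)
}

#' One step of the delayed-state Kalman estimator
#'
#' Propagates the previous posterior through the internal model with both
#' control inputs (efference copy of one's own command plus the predicted
#' partner command), then corrects with the innovation against the
#' delayed measurement.
#'
#' @param est list with field `xhat` (previous posterior estimate).
#' @param measurement observed vector `y = C x + noise`.
#' @param u_self own control input at this step.
#' @param u_partner_predicted predicted partner control input (zero for a
#'   controller without a partner representation).
#' @param dyn a [build_dynamics()] object.
#' @param C observation matrix for this controller.
#' @param K Kalman gain for this step.
#' @param B_self,B_partner input matrices of the internal model; default
#'   the plant's `B1`, `B2` for controller 1 (pass swapped for
#'   controller 2).
#' @return Updated list with fields `xhat` (posterior) and `xbar`
#'   (prior).
#' @export
kalman_step <- function(est, measurement, u_self, u_partner_predicted,
                        dyn, C, K, B_self = dyn$B1, B_partner = dyn$B2) {
  xbar <- as.vector(dyn$A %*% est$xhat + B_self %*% u_self +
                      B_partner %*% u_partner_predicted)
  innov <- measurement - as.vector(C %*% xbar)
  est$xbar <- xbar
  est$xhat <- xbar + as.vector(K %*% innov)
  est
}
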