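# State layout -------------------------------------------------------------
#
# The base state block holds 16 scalars; x is lateral (positive rightward),
# y is forward. The augmented state appends delay_steps history copies of
# the base block, oldest last, so delayed observations read the final slot.

BASE_DIM <- 16L

# named index into one base block
.base_idx <- c(p1x = 1L, p1y = 2L, v1x = 3L, v1y = 4L, f1x = 5L, f1y = 6L,
               p2x = 7L, p2y = 8L, v2x = 9L, v2y = 10L, f2x = 11L, f2y = 12L,
               ccx = 13L, ccy = 14L, tx = 15L, ty = 16L)

#' Index of named channels in the augmented state
#'
#' @param channel character vector of channel names, e.g. `"ccx"`,
#'   `"p1y"`; valid names are positions/velocities/forces of hand 1 and 2
#'   (`p1x` ... `f2y`), the center cursor (`ccx`, `ccy`) and the target
#'   (`tx`, `ty`).
#' @param slot history slot: 0 = current state, k = state k steps ago.
#' @return Integer indices into the augmented state vector.
#' @export
state_index <- function(channel, slot = 0L) {
  i <- .base_idx[channel]
  if (anyNA(i)) stop("unknown state channel: ",
                     paste(channel[is.na(i)], collapse = ", "), call. = FALSE)
  unname(i + BASE_DIM * as.integer(slot))
}

#' Build the discrete-time augmented dynamics
#'
#' Constructs the transition matrix `A` and the two control-input matrices
#' `B1`, `B2` of the jointly controlled reaching plant. Each hand is a
#' point mass (mass m, viscosity b) driven by a first-order muscle filter
#' (time constant tau); the center cursor integrates the mean of the two
#' hand velocities; the target block is constant under `A` (cursor/target
#' jumps are injected externally by the simulator). The base block is
#' augmented with `delay_steps` exact history copies so that sensory
#' observations can be read from the delayed slot.
#'
#' Discretization is forward Euler at `params$time_step` (the `exact`
#' flag switches to the matrix-exponential discretization of the base
#' block; the two agree to O(dt^2)).
#'
#' @param params a [model_params()] object.
#' @param exact logical; use exact (matrix exponential) discretization of
#'   the base block instead of forward Euler.
#' @return An object of class `"dynamics_spec"`: list with `A`, `B1`,
#'   `B2`, `time_step`, `delay_steps`, `n` (augmented dimension).
#' @examples
#' dyn <- build_dynamics(model_params())
#' dim(dyn$A)  # 192 x 192
#' @export
build_dynamics <- function(params, exact = FALSE) {
  stopifnot(inherits(params, "model_params"))
  dt <- params$time_step
  m <- params$hand_mass
  b <- params$viscosity
  tau <- params$muscle_time_constant
  nd <- params$delay_steps

  # continuous-time base dynamics xdot = Ac x + Bc1 u1 + Bc2 u2
  Ac <- matrix(0, BASE_DIM, BASE_DIM)
  for (hand in 1:2) {
    p <- state_index(paste0("p", hand, c("x", "y")))
    v <- state_index(paste0("v", hand, c("x", "y")))
    f <- state_index(paste0("f", hand, c("x", "y")))
    Ac[cbind(p, v)] <- 1                 # pdot = v
    Ac[cbind(v, v)] <- -b / m            # m vdot = -b v + f
    Ac[cbind(v, f)] <- 1 / m
    Ac[cbind(f, f)] <- -1 / tau          # tau fdot = u - f
    cc <- state_index(c("ccx", "ccy"))
    Ac[cbind(cc, v)] <- 0.5              # ccdot = (v1 + v2) / 2
  }
  Bc <- function(hand) {
    B <- matrix(0, BASE_DIM, 2L)
    f <- state_index(paste0("f", hand, c("x", "y")))
    B[cbind(f, 1:2)] <- 1 / tau
    B
  }

  if (exact) {
    # exact zero-order-hold discretization via the augmented exponential
    M <- rbind(cbind(Ac, Bc(1), Bc(2)), matrix(0, 4L, BASE_DIM + 4L))
    E <- expm_pade(M * dt)
    Ab <- E[1:BASE_DIM, 1:BASE_DIM, drop = FALSE]
    B1b <- E[1:BASE_DIM, BASE_DIM + (1:2), drop = FALSE]
    B2b <- E[1:BASE_DIM, BASE_DIM + (3:4), drop = FALSE]
  } else {
    Ab <- diag(BASE_DIM) + dt * Ac
    B1b <- dt * Bc(1)
    B2b <- dt * Bc(2)
  }

  n <- BASE_DIM * (nd + 1L)
  A <- matrix(0, n, n)
  A[1:BASE_DIM, 1:BASE_DIM] <- Ab
  if (nd > 0) {
    # history slot j receives a copy of slot j-1 (pure delay line)
    for (j in seq_len(nd)) {
      rows <- BASE_DIM * j + 1:BASE_DIM
      cols <- BASE_DIM * (j - 1L) + 1:BASE_DIM
      A[cbind(rows, cols)] <- 1
    }
  }
  B1 <- rbind(B1b, matrix(0, n - BASE_DIM, 2L))
  B2 <- rbind(B2b, matrix(0, n - BASE_DIM, 2L))

  structure(list(A = A, B1 = B1, B2 = B2, time_step = dt,
                 delay_steps = nd, n = n),
            class = "dynamics_spec")
}

# scaling-and-squaring Pade matrix exponential (small matrices only)
expm_pade <- function(X) {
  n <- nrow(X)
  s <- max(0L, ceiling(log2(max(1, norm(X, "1")))))
  X <- X / 2^s
  c_ <- 1; E <- diag(n); D <- diag(n); P <- diag(n); q <- 6L; sign <- -1
  for (k in seq_len(q)) {
    c_ <- c_ * (q - k + 1) / (k * (2 * q - k + 1))
    P <- X %*% P
    E <- E + c_ * P
    D <- D + sign * c_ * P
    sign <- -sign
  }
  E <- solve(D, E)
  for (k in seq_len(s)) E <- E %*% E
  E
}

#' Initial augmented state for a trial
#'
#' Hands start `start_offset` m to either side of the center cursor
#' (self at +x, partner at -x), at rest; targets `target_distance` m
#' forward. History slots are filled with copies of the initial base
#' block.
#'
#' @param params a [model_params()] object.
#' @return Numeric augmented state vector.
#' @export
initial_state <- function(params) {
  x0 <- numeric(BASE_DIM)
  x0[state_index(c("p1x", "p2x"))] <- c(params$start_offset, -params$start_offset)
  x0[state_index(c("tx", "ty"))] <- c(0, params$target_distance)
  rep(x0, params$delay_steps + 1L)
}

#' Build the delayed observation model
#'
#' Each controller observes, from the oldest delay slot (`delay_steps`
#' steps in the past): its own hand position, velocity and muscle force,
#' the partner's hand position and velocity (but not the partner's
#' force), the center-cursor position and the target position. The
#' measurement noise covariance is diagonal with the per-channel SDs from
#' `params`.
#'
#' @param params a [model_params()] object.
#' @return Object of class `"observation_spec"`: list with observation
#'   matrices `C1`, `C2` (14 x n), `delay_steps`, per-controller channel
#'   name vectors `channels1`, `channels2`, and the measurement noise
#'   covariance `V` (shared by both controllers).
#' @examples
#' obs <- build_observation(model_params())
#' obs$delay_steps            # 11
#' "f2x" %in% obs$channels1   # FALSE: partner force is not observed
#' @export
build_observation <- function(params) {
  stopifnot(inherits(params, "model_params"))
  nd <- params$delay_steps
  n <- BASE_DIM * (nd + 1L)
  chans <- function(own, other) {
    c(paste0("p", own, c("x", "y")), paste0("v", own, c("x", "y")),
      paste0("f", own, c("x", "y")),
      paste0("p", other, c("x", "y")), paste0("v", other, c("x", "y")),
      "ccx", "ccy", "tx", "ty")
  }
  Cmat <- function(ch) {
    C <- matrix(0, length(ch), n)
    C[cbind(seq_along(ch), state_index(ch, slot = nd))] <- 1
    C
  }
  ch1 <- chans(1, 2); ch2 <- chans(2, 1)
  sd_of <- function(ch) {
    kind <- substr(ch, 1, 1)
    ifelse(kind == "p" | kind == "c" | kind == "t", params$pos_noise_sd,
           ifelse(kind == "v", params$vel_noise_sd, params$force_noise_sd))
  }
  structure(list(C1 = Cmat(ch1), C2 = Cmat(ch2),
                 channels1 = ch1, channels2 = ch2,
                 delay_steps = nd,
                 V = diag(sd_of(ch1)^2, length(ch1))),
            class = "observation_spec")
}
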