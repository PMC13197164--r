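#' Specify a single trial
#'
#' Resolves condition, trial type, jump direction and experiment into a
#' fully populated trial specification, including the lateral
#' displacement schedule sampled on the model time grid. Cursor jumps
#' (Experiment 1) or target jumps (Experiment 2) are a 3 cm lateral
#' shift ramped linearly over 25 ms once the center cursor has covered
#' 25% of the forward target distance; perturbation trials stay
#' displaced to the end of the trial, probe trials hold for 200 ms and
#' ramp back over 25 ms (250 ms end to end). On probe and null-probe
#' trials both hands are constrained to a force channel that blocks
#' lateral motion.
#'
#' @param condition one of [conditions()].
#' @param trial_type `"non_perturbation"`, `"perturbation"`, `"probe"` or
#'   `"null_probe"`.
#' @param direction `"left"`, `"right"` or `"none"`. Required for
#'   perturbation and probe trials; must be `"none"` otherwise.
#' @param experiment 1 (center-cursor jump) or 2 (target jump).
#' @param params a [model_params()] object.
#' @param jump_magnitude lateral jump size in m.
#' @param jump_ramp ramp duration in s.
#' @param probe_hold hold duration of the probe displacement in s.
#' @return Object of class `"trial_spec"`. Field `displacement(tau)`
#'   returns the lateral displacement at time `tau` since jump onset.
#' @export
make_trial_spec <- function(condition, trial_type,
                            direction = c("none", "left", "right"),
                            experiment = 1L,
                            params = model_params(),
                            jump_magnitude = 0.03,
                            jump_ramp = 0.025,
                            probe_hold = 0.200) {
  condition <- match.arg(condition, conditions())
  trial_type <- match.arg(trial_type,
                          c("non_perturbation", "perturbation",
                            "probe", "null_probe"))
  direction <- match.arg(direction)
  if (!experiment %in% c(1L, 2L)) stop("experiment must be 1 or 2", call. = FALSE)
  jumped <- trial_type %in% c("perturbation", "probe")
  if (jumped && direction == "none")
    stop("a ", trial_type, " trial needs direction 'left' or 'right'",
         call. = FALSE)
  if (!jumped && direction != "none")
    stop("direction must be 'none' on a ", trial_type, " trial", call. = FALSE)

  sgn <- switch(direction, left = -1, right = 1, none = 0)
  mag <- sgn * jump_magnitude
  displacement <- switch(
    trial_type,
    perturbation = function(tau) {
      mag * pmin(pmax(tau, 0) / jump_ramp, 1)
    },
    probe = function(tau) {
      out <- mag * pmin(pmax(tau, 0) / jump_ramp, 1)
      back <- tau - (jump_ramp + probe_hold)
      out - mag * pmin(pmax(back, 0) / jump_ramp, 1)
    },
    function(tau) rep(0, length(tau))
  )

  structure(list(
    condition = condition, trial_type = trial_type, direction = direction,
    experiment = as.integer(experiment),
    jump_target = if (experiment == 1L) "center_cursor" else "both_targets",
    jump_magnitude = jump_magnitude, jump_ramp = jump_ramp,
    probe_hold = probe_hold,
    onset_threshold = 0.25 * params$target_distance,
    force_channel = trial_type %in% c("probe", "null_probe"),
    geometry = list(target_distance = params$target_distance,
                    start_offset = params$start_offset,
                    narrow_width = 0.0105, wide_width = 0.20,
                    target_height = 0.0125),
    displacement = displacement
  ), class = "trial_spec")
}

#' Assemble a simulation-ready model for one condition and hypothesis
#'
#' Builds the augmented dynamics, the delayed observation model, the
#' policy gains for the requested hypothesis, and both controllers'
#' Kalman gain sequences. Kalman gains depend only on the dynamics and
#' noise configuration, so a precomputed pair can be passed in when
#' looping over conditions and hypotheses.
#'
#' @param condition one of [conditions()].
#' @param hypothesis one of [hypotheses()].
#' @param params a [model_params()] object.
#' @param kalman optional precomputed list as returned in the `kalman`
#'   field of an earlier model with identical `params`.
#' @return Object of class `"dyad_model"`.
#' @export
build_model <- function(condition, hypothesis, params = model_params(),
                        kalman = NULL) {
  dyn <- build_dynamics(params)
  obs <- build_observation(params)
  if (is.null(kalman)) {
    kalman <- list(
      k1 = compute_kalman_gains(dyn, obs$C1, obs$V, params = params),
      k2 = compute_kalman_gains(dyn, obs$C2, obs$V, params = params))
  }
  gains <- solve_policy_gains(dyn, condition, hypothesis, params)
  structure(list(condition = condition, hypothesis = hypothesis,
                 params = params, dyn = dyn, obs = obs,
                 gains = gains, kalman = kalman),
            class = "dyad_model")
}

#' Simulate one closed-loop trial of the two-controller model
#'
#' Rolls out the plant and both controllers (policy gains applied to each
#' controller's own Kalman estimate) for `params$horizon_steps` steps.
#' Cursor or target jumps are injected as additive offsets to the current
#' center-cursor (Experiment 1) or target (Experiment 2) state block once
#' the true center cursor crosses the forward onset threshold; history
#' copies are not retro-edited, so the jump reaches each controller's
#' sensory stream only after the full visual delay. On force-channel
#' trials the lateral force column of both plant input matrices is
#' zeroed (the hands cannot move laterally) while the reported applied
#' lateral force of controller i remains the lateral component of
#' `B_i u_i` under the original input matrix.
#'
#' @param model a [build_model()] object.
#' @param spec a [make_trial_spec()] object (condition should match the
#'   model's).
#' @param seed integer seed for the trial's noise draws, or `NULL` to use
#'   the current RNG state.
#' @param noise logical; `FALSE` runs the deterministic (noise-free)
#'   system.
#' @param estimator_offset optional numeric vector added to both
#'   controllers' initial state estimates (augmented coordinates), used
#'   to probe estimator convergence.
#' @return A `"trial_record"`: data frame with one row per time step
#'   (`t`, hand and center-cursor positions, lateral target position
#'   `tx`, applied lateral forces `force1`, `force2`) and attributes
#'   `spec`, `jump_onset_step`, `jump_onset_time`, `estimate_error`.
#' @export
simulate_trial <- function(model, spec, seed = NULL, noise = TRUE,
                           estimator_offset = NULL) {
  stopifnot(inherits(model, "dyad_model"), inherits(spec, "trial_spec"))
  if (!is.null(seed)) set.seed(seed)
  params <- model$params
  dyn <- model$dyn; obs <- model$obs
  F1 <- model$gains$F1; F2 <- model$gains$F2
  K1 <- model$kalman$k1$K; K2 <- model$kalman$k2$K
  rep_flag <- model$gains$partner_representation
  N <- params$horizon_steps
  dt <- params$time_step
  n <- dyn$n

  # plant input matrices (channel blocks lateral muscle force)
  B1p <- dyn$B1; B2p <- dyn$B2
  if (spec$force_channel) {
    B1p[state_index("f1x"), ] <- 0
    B2p[state_index("f2x"), ] <- 0
  }

  # noise setup
  meas_sd1 <- sqrt(diag(obs$V)); meas_sd2 <- meas_sd1
  proc_sd <- numeric(n)
  proc_sd[1:BASE_DIM] <- params$process_noise_sd
  if (spec$force_channel) {
    lat <- state_index(c("p1x", "v1x", "f1x", "p2x", "v2x", "f2x"))
    proc_sd[lat] <- 0   # the channel physically blocks lateral hand motion
  }

  x <- initial_state(params)
  xhat1 <- x; xhat2 <- x
  if (!is.null(estimator_offset)) {
    xhat1 <- xhat1 + estimator_offset
    xhat2 <- xhat2 + estimator_offset
  }
  est1 <- list(xhat = xhat1); est2 <- list(xhat = xhat2)

  jump_idx <- if (spec$experiment == 1L) state_index("ccx") else
    state_index("tx")
  onset_step <- NA_integer_
  d_prev <- 0

  rec <- matrix(NA_real_, N, 10L)
  colnames(rec) <- c("t", "p1x", "p1y", "p2x", "p2y", "ccx", "ccy", "tx",
                     "force1", "force2")
  est_err <- numeric(N); est_err_pos <- numeric(N)
  p_cols <- state_index(c("p1x", "p1y", "p2x", "p2y", "ccx", "ccy", "tx"))
  pos_cols <- state_index(c("p1x", "p1y", "p2x", "p2y", "ccx", "ccy"))

  for (k in seq_len(N)) {
    t_k <- (k - 1) * dt
    if (is.na(onset_step) && spec$trial_type != "non_perturbation" &&
        x[state_index("ccy")] >= spec$onset_threshold) {
      onset_step <- k
    }
    u1 <- -as.vector(F1[[k]] %*% est1$xhat)
    u2 <- -as.vector(F2[[k]] %*% est2$xhat)
    rec[k, ] <- c(t_k, x[p_cols],
                  (dyn$B1 %*% u1)[state_index("f1x")],
                  (dyn$B2 %*% u2)[state_index("f2x")])
    est_err[k] <- max(abs(est1$xhat[1:BASE_DIM] - x[1:BASE_DIM]))
    est_err_pos[k] <- max(abs(est1$xhat[pos_cols] - x[pos_cols]))

    # plant step
    x_next <- as.vector(dyn$A %*% x + B1p %*% u1 + B2p %*% u2)
    if (noise && params$process_noise_sd > 0)
      x_next <- x_next + stats::rnorm(n) * proc_sd  # unit draws scaled so
      # the RNG stream is identical across trial types under one seed
    if (!is.na(onset_step)) {
      tau_next <- (k + 1 - onset_step) * dt
      d_next <- spec$displacement(tau_next)
      x_next[jump_idx] <- x_next[jump_idx] + (d_next - d_prev)
      d_prev <- d_next
    }
    if (max(abs(x_next)) > 1e3)
      stop("simulation diverged (state norm guard) at step ", k, call. = FALSE)

    # measurements of the new state; estimator update
    y1 <- as.vector(obs$C1 %*% x_next)
    y2 <- as.vector(obs$C2 %*% x_next)
    if (noise) {
      y1 <- y1 + stats::rnorm(length(y1)) * meas_sd1
      y2 <- y2 + stats::rnorm(length(y2)) * meas_sd2
    }
    u2_pred <- if (rep_flag) -as.vector(F2[[k]] %*% est1$xhat) else c(0, 0)
    u1_pred <- if (rep_flag) -as.vector(F1[[k]] %*% est2$xhat) else c(0, 0)
    est1 <- kalman_step(est1, y1, u1, u2_pred, dyn, obs$C1, K1[[k]])
    est2 <- kalman_step(est2, y2, u2, u1_pred, dyn, obs$C2, K2[[k]],
                        B_self = dyn$B2, B_partner = dyn$B1)
    x <- x_next
  }

  out <- as.data.frame(rec)
  attr(out, "spec") <- spec
  attr(out, "jump_onset_step") <- onset_step
  attr(out, "jump_onset_time") <- if (is.na(onset_step)) NA_real_ else
    (onset_step - 1) * dt
  attr(out, "estimate_error") <- est_err
  attr(out, "estimate_error_pos") <- est_err_pos
  class(out) <- c("trial_record", "data.frame")
  out
}

#' Simulate a force-channel probe trial
#'
#' Thin wrapper over [simulate_trial()] that checks the spec is a probe
#' or null probe. The returned record's `force1`/`force2` columns hold
#' the applied lateral force of each controller (the lateral component of
#' `B_i u_i` under the original, unchannelled input matrix).
#'
#' @inheritParams simulate_trial
#' @export
simulate_probe <- function(model, spec, seed = NULL, noise = TRUE) {
  if (!spec$trial_type %in% c("probe", "null_probe"))
    stop("simulate_probe expects a probe or null_probe trial spec",
         call. = FALSE)
  simulate_trial(model, spec, seed = seed, noise = noise)
}

# interpolate a probe record's controller-1 force onto a time-from-onset grid
.probe_force_on_grid <- function(record, tau_grid, who = "force1") {
  onset <- attr(record, "jump_onset_time")
  if (is.na(onset)) stop("probe record has no jump onset", call. = FALSE)
  stats::approx(record$t - onset, record[[who]], xout = tau_grid,
                rule = 2)$y
}

#' Simulate a batch of probe trials and summarize model feedback responses
#'
#' For each requested condition, simulates `n_trials` left-jump and
#' `n_trials` right-jump force-channel probe trials, forms the per-trial
#' visuomotor feedback response of controller 1 (left minus right applied
#' lateral force for cursor jumps, right minus left for target jumps),
#' aligns trials at jump onset, and returns mean and SD response traces
#' together with per-trial epoch means. With `noise = FALSE` a single
#' deterministic trial pair per condition is simulated.
#'
#' @param hypothesis one of [hypotheses()].
#' @param conditions_run character vector of conditions to simulate.
#' @param params a [model_params()] object.
#' @param n_trials probe trials per direction and condition.
#' @param seed integer seed.
#' @param experiment 1 or 2.
#' @param noise logical.
#' @param kalman optional precomputed Kalman gains (see [build_model()]).
#' @param window response window (s relative to jump onset) kept in the
#'   output traces.
#' @return Object of class `"probe_batch"`: named list (one entry per
#'   condition) with fields `tau` (time from jump onset), `vfr_mean`,
#'   `vfr_sd`, `epochs` (per-trial epoch means) and `involuntary_mean`.
#' @export
run_batch <- function(hypothesis, conditions_run = conditions(),
                      params = model_params(), n_trials = 100L,
                      seed = 1L, experiment = 1L, noise = TRUE,
                      kalman = NULL, window = c(0, 0.45)) {
  stopifnot(n_trials >= 1L)
  if (!noise) n_trials <- 1L
  set.seed(seed)
  dt <- params$time_step
  tau_grid <- seq(window[1], window[2], by = dt)
  out <- list()
  for (cond in conditions_run) {
    model <- build_model(cond, hypothesis, params, kalman = kalman)
    if (is.null(kalman)) kalman <- model$kalman
    vfr <- matrix(NA_real_, n_trials, length(tau_grid))
    for (i in seq_len(n_trials)) {
      spl <- make_trial_spec(cond, "probe", "left", experiment, params)
      spr <- make_trial_spec(cond, "probe", "right", experiment, params)
      fl <- .probe_force_on_grid(simulate_trial(model, spl, noise = noise),
                                 tau_grid)
      fr <- .probe_force_on_grid(simulate_trial(model, spr, noise = noise),
                                 tau_grid)
      vfr[i, ] <- if (experiment == 1L) fl - fr else fr - fl
    }
    ep <- t(apply(vfr, 1L, function(f) {
      unlist(epoch_means(response_trace(tau_grid, f)))
    }))
    out[[cond]] <- list(
      tau = tau_grid,
      vfr_mean = colMeans(vfr),
      vfr_sd = if (n_trials > 1L) apply(vfr, 2L, stats::sd) else
        rep(0, length(tau_grid)),
      epochs = as.data.frame(ep),
      involuntary_mean = mean(ep[, "involuntary"]))
  }
  structure(out, class = "probe_batch", hypothesis = hypothesis,
            experiment = experiment, n_trials = n_trials, seed = seed)
}

#' @export
print.probe_batch <- function(x, ...) {
  cat(sprintf("Probe batch: hypothesis %s, experiment %d, %d trials/direction\n",
              attr(x, "hypothesis"), attr(x, "experiment"),
              attr(x, "n_trials")))
  for (cond in names(x))
    cat(sprintf("  %-6s involuntary VFR = %8.4f N\n", cond,
                x[[cond]]$involuntary_mean))
  invisible(x)
}
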