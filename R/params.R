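#' Model parameters for the two-player reaching game
#'
#' Bundles the physical and numerical parameters of the point-mass hand
#' model, the sensory delay line, the cost weights and the noise scales.
#' Defaults reproduce the experimental conditions: a 1.5 kg hand with viscosity
#' 0.1 N.s/m, a 20 ms first-order muscle filter, 110 ms visual delay at a
#' 10 ms time step (11 delay slots), and terminal lateral accuracy weights
#' of 40,000 (task-relevant target) vs 100 (task-irrelevant target).
#'
#' @param hand_mass hand mass in kg.
#' @param viscosity translational viscosity in N.s/m.
#' @param muscle_time_constant first-order muscle (force production) time
#'   constant in s.
#' @param time_step discretization step in s.
#' @param sensory_delay visual feedback delay in s; must be an integer
#'   multiple of `time_step`.
#' @param horizon_steps number of simulated time steps per trial.
#' @param terminal_weight_relevant terminal cost on the lateral
#'   center-cursor-to-target error for a narrow (task-relevant) target.
#' @param terminal_weight_irrelevant same weight for a wide
#'   (task-irrelevant) target.
#' @param forward_weight terminal cost on the forward
#'   center-cursor-to-target error (reaching forward is always required).
#' @param velocity_weight,force_weight small terminal regularizers on the
#'   controller's own hand velocity and muscle force, needed so the
#'   solution stabilizes at the target rather than coasting through it.
#' @param control_weight scalar r of the control cost R = r I, the
#'   energetic penalty per squared unit of motor command.
#' @param target_distance forward distance from start to targets, m.
#' @param start_offset lateral distance from each hand's start position to
#'   the center cursor, m (self hand starts to the right, +x).
#' @param pos_noise_sd,vel_noise_sd,force_noise_sd per-channel sensory
#'   (measurement) noise standard deviations (m, m/s, N).
#' @param process_noise_sd additive process noise SD applied to the
#'   current base-state block.
#' @return An object of class `"model_params"` (a validated list).
#' @examples
#' p <- model_params()
#' p$delay_steps   # 11
#' @export
model_params <- function(hand_mass = 1.5,
                         viscosity = 0.1,
                         muscle_time_constant = 0.020,
                         time_step = 0.010,
                         sensory_delay = 0.110,
                         horizon_steps = 90L,
                         terminal_weight_relevant = 40000,
                         terminal_weight_irrelevant = 100,
                         forward_weight = 40000,
                         velocity_weight = 20,
                         force_weight = 0.05,
                         control_weight = 0.05,
                         target_distance = 0.25,
                         start_offset = 0.13,
                         pos_noise_sd = 0.002,
                         vel_noise_sd = 0.02,
                         force_noise_sd = 0.02,
                         process_noise_sd = 1e-4) {
  num_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop("'", nm, "' must be a single positive number", call. = FALSE)
  }
  num_pos(hand_mass, "hand_mass")
  num_pos(viscosity, "viscosity")
  num_pos(muscle_time_constant, "muscle_time_constant")
  num_pos(time_step, "time_step")
  num_pos(terminal_weight_relevant, "terminal_weight_relevant")
  num_pos(terminal_weight_irrelevant, "terminal_weight_irrelevant")
  num_pos(control_weight, "control_weight")
  if (sensory_delay < 0) stop("'sensory_delay' must be >= 0", call. = FALSE)
  ratio <- sensory_delay / time_step
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("sensory_delay must be an integer multiple of time_step ",
         "(got ratio ", format(ratio), ")", call. = FALSE)
  horizon_steps <- as.integer(horizon_steps)
  if (horizon_steps < 1L) stop("'horizon_steps' must be >= 1", call. = FALSE)

  structure(list(
    hand_mass = hand_mass,
    viscosity = viscosity,
    muscle_time_constant = muscle_time_constant,
    time_step = time_step,
    sensory_delay = sensory_delay,
    delay_steps = as.integer(round(ratio)),
    horizon_steps = horizon_steps,
    terminal_weight_relevant = terminal_weight_relevant,
    terminal_weight_irrelevant = terminal_weight_irrelevant,
    forward_weight = forward_weight,
    velocity_weight = velocity_weight,
    force_weight = force_weight,
    control_weight = control_weight,
    target_distance = target_distance,
    start_offset = start_offset,
    pos_noise_sd = pos_noise_sd,
    vel_noise_sd = vel_noise_sd,
    force_noise_sd = force_noise_sd,
    process_noise_sd = process_noise_sd
  ), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Two-player reaching game parameters\n")
  cat(sprintf("  hand: m = %.3g kg, b = %.3g N.s/m, tau = %.3g s\n",
              x$hand_mass, x$viscosity, x$muscle_time_constant))
  cat(sprintf("  dt = %.3g s, delay = %.3g s (%d steps), horizon = %d steps\n",
              x$time_step, x$sensory_delay, x$delay_steps, x$horizon_steps))
  cat(sprintf("  terminal lateral weight: relevant %g / irrelevant %g, r = %g\n",
              x$terminal_weight_relevant, x$terminal_weight_irrelevant,
              x$control_weight))
  invisible(x)
}

# Canonical labels ----------------------------------------------------------

#' Condition and hypothesis labels
#'
#' The 2x2 target-relevance design is labelled from the perspective of
#' controller 1 (the "self"): `"pi/si"` (partner-irrelevant /
#' self-irrelevant), `"pr/si"`, `"pi/sr"`, `"pr/sr"`. Policy hypotheses
#' are `"no_rep_self"` (no partner representation, self cost, alpha = 0),
#' `"rep_self"` (representation, self cost, alpha = 0), `"rep_equal"`
#' (representation, equal joint cost, alpha = 1) and `"rep_weighted"`
#' (representation, weighted joint cost, alpha = 0.5).
#'
#' @name labels
#' @return Character vectors of valid labels.
NULL

#' @rdname labels
#' @export
conditions <- function() c("pi/si", "pr/si", "pi/sr", "pr/sr")

#' @rdname labels
#' @export
hypotheses <- function() c("no_rep_self", "rep_self", "rep_equal", "rep_weighted")

#' Decode a condition label into self/partner target relevance
#'
#' @param condition one of [conditions()].
#' @return List with logical fields `self_relevant`, `partner_relevant`.
#' @export
condition_relevance <- function(condition) {
  condition <- match.arg(condition, conditions())
  list(self_relevant = condition %in% c("pi/sr", "pr/sr"),
       partner_relevant = condition %in% c("pr/si", "pr/sr"))
}

#' Resolve a policy-hypothesis label
#'
#' Maps a hypothesis label onto its two defining properties: whether a
#' controller's policy is computed with knowledge of the partner's policy
#' (the partner representation) and the joint-cost weight alpha applied to
#' the partner's individual cost.
#'
#' @param hypothesis one of [hypotheses()].
#' @return An object of class `"policy_hypothesis"` with fields `label`,
#'   `partner_representation` (logical) and `alpha`.
#' @examples
#' policy_hypothesis("rep_weighted")$alpha  # 0.5
#' @export
policy_hypothesis <- function(hypothesis) {
  hypothesis <- match.arg(hypothesis, hypotheses())
  alpha <- switch(hypothesis,
                  no_rep_self = 0, rep_self = 0,
                  rep_equal = 1, rep_weighted = 0.5)
  structure(list(label = hypothesis,
                 partner_representation = hypothesis != "no_rep_self",
                 alpha = alpha),
            class = "policy_hypothesis")
}
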