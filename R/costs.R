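#' Build the quadratic cost structure for both controllers
#'
#' Each controller i carries a terminal state cost penalizing the
#' center-cursor-to-target error, with the lateral (x) weight set by that
#' controller's own target relevance (narrow target: 40,000; wide target:
#' 100), the forward (y) weight always at the relevant value, plus small
#' terminal regularizers on the controller's own hand velocity and muscle
#' force. The running state cost is zero (all accuracy pressure is at the
#' final step); the running control cost is `R = r I` at every step.
#' Under a joint-cost hypothesis, controller i minimizes
#' `J_i + alpha_i * J_j`.
#'
#' @param condition one of [conditions()], naming partner and self target
#'   relevance from controller 1's perspective.
#' @param hypothesis a [policy_hypothesis()] object or a label from
#'   [hypotheses()].
#' @param params a [model_params()] object.
#' @return List of two `"cost_spec"` objects (`cost1`, `cost2`), each
#'   with fields `Q` (running state cost, zero), `QN` (terminal state
#'   cost), `R` (control cost) and `alpha`.
#' @examples
#' cs <- build_costs("pr/si", "rep_weighted", model_params())
#' cs$cost1$alpha  # 0.5
#' @export
build_costs <- function(condition, hypothesis, params) {
  stopifnot(inherits(params, "model_params"))
  rel <- condition_relevance(condition)
  if (is.character(hypothesis)) hypothesis <- policy_hypothesis(hypothesis)
  stopifnot(inherits(hypothesis, "policy_hypothesis"))

  n <- BASE_DIM * (params$delay_steps + 1L)
  terminal_cost <- function(controller, relevant) {
    QN <- matrix(0, n, n)
    wx <- if (relevant) params$terminal_weight_relevant else
      params$terminal_weight_irrelevant
    # (cc - target)' W (cc - target) via difference outer products
    add_err <- function(QN, cc, tg, w) {
      QN[cc, cc] <- QN[cc, cc] + w
      QN[tg, tg] <- QN[tg, tg] + w
      QN[cc, tg] <- QN[cc, tg] - w
      QN[tg, cc] <- QN[tg, cc] - w
      QN
    }
    QN <- add_err(QN, state_index("ccx"), state_index("tx"), wx)
    QN <- add_err(QN, state_index("ccy"), state_index("ty"),
                  params$forward_weight)
    v <- state_index(paste0("v", controller, c("x", "y")))
    f <- state_index(paste0("f", controller, c("x", "y")))
    QN[cbind(v, v)] <- QN[cbind(v, v)] + params$velocity_weight
    QN[cbind(f, f)] <- QN[cbind(f, f)] + params$force_weight
    QN
  }
  mk <- function(controller, relevant) {
    structure(list(Q = matrix(0, n, n),
                   QN = terminal_cost(controller, relevant),
                   R = diag(params$control_weight, 2L),
                   alpha = hypothesis$alpha),
              class = "cost_spec")
  }
  list(cost1 = mk(1, rel$self_relevant),
       cost2 = mk(2, rel$partner_relevant))
}
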