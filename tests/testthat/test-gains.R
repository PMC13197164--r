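test_that("costs encode target relevance and the joint-cost weight", {
  p <- model_params()
  cc <- state_index("ccx"); tx <- state_index("tx")
  cs <- build_costs("pr/si", "rep_weighted", p)
  expect_equal(cs$cost1$QN[cc, cc], p$terminal_weight_irrelevant)
  expect_equal(cs$cost2$QN[cc, cc], p$terminal_weight_relevant)
  expect_equal(cs$cost1$QN[cc, tx], -p$terminal_weight_irrelevant)
  expect_equal(cs$cost1$alpha, 0.5)
  expect_equal(cs$cost2$alpha, 0.5)
  cs2 <- build_costs("pi/sr", "rep_equal", p)
  expect_equal(cs2$cost1$QN[cc, cc], p$terminal_weight_relevant)
  expect_equal(cs2$cost2$QN[cc, cc], p$terminal_weight_irrelevant)
  expect_equal(cs2$cost1$alpha, 1)
  expect_error(build_costs("pr/xx", "rep_equal", p))
  expect_error(build_costs("pr/si", "some_model", p))
  # terminal costs are symmetric PSD
  ev <- eigen(cs$cost1$QN, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-9))
})

test_that("the hypothesis map fixes representation flag and alpha", {
  h <- lapply(hypotheses(), policy_hypothesis)
  expect_equal(vapply(h, `[[`, numeric(1), "alpha"), c(0, 0, 1, 0.5))
  expect_equal(vapply(h, `[[`, logical(1), "partner_representation"),
               c(FALSE, TRUE, TRUE, TRUE))
})

test_that("a symmetric scalar game yields identical gains for both players", {
  dyn <- list(A = matrix(1), B1 = matrix(1), B2 = matrix(1))
  zero <- matrix(0)
  c1 <- structure(list(Q = zero, QN = matrix(1), R = matrix(1), alpha = 0),
                  class = "cost_spec")
  g <- solve_nash_gains(dyn, c1, c1, horizon_steps = 2)
  for (k in 1:2) expect_equal(g$F1[[k]], g$F2[[k]], tolerance = 1e-8)
})

test_that("with an inert partner the Nash gains are the single-player LQR", {
  set.seed(7)
  for (rep in 1:5) {
    gm <- random_game(n = 3, m = 2, N = 4, alpha = 0)
    gm$dyn$B2 <- gm$dyn$B2 * 0
    nash <- solve_nash_gains(gm$dyn, gm$cost1, gm$cost2, gm$N)
    # independent batch least-squares oracle for the first-step gain
    F_oracle <- -batch_lqr_first_step(
      lapply(1:gm$N, function(k) gm$dyn$A),
      lapply(1:gm$N, function(k) gm$dyn$B1),
      lapply(1:gm$N, function(k) gm$cost1$Q), gm$cost1$QN, gm$cost1$R, gm$N)
    expect_equal(nash$F1[[1]], F_oracle, tolerance = 1e-8)
    dec <- solve_decoupled_gains(gm$dyn, gm$cost1, gm$cost2, gm$N)
    for (k in 1:gm$N)
      expect_equal(nash$F1[[k]], dec$F1[[k]], tolerance = 1e-10)
  }
})

test_that("each Nash gain sequence is a best response to the frozen partner", {
  set.seed(11)
  for (rep in 1:20) {
    alpha <- sample(c(0, 0.5, 1), 1)
    gm <- random_game(n = 3, m = 2, N = 4, alpha = alpha)
    nash <- solve_nash_gains(gm$dyn, gm$cost1, gm$cost2, gm$N)
    BR1 <- best_response_first_gain(
      gm$dyn$A, gm$dyn$B1, gm$dyn$B2, nash$F2,
      Q_self = gm$cost1$Q + alpha * gm$cost2$Q,
      QN_self = gm$cost1$QN + alpha * gm$cost2$QN,
      R_self = gm$cost1$R, R_other = gm$cost2$R, alpha = alpha, N = gm$N)
    expect_equal(nash$F1[[1]], BR1, tolerance = 1e-8)
    BR2 <- best_response_first_gain(
      gm$dyn$A, gm$dyn$B2, gm$dyn$B1, nash$F1,
      Q_self = gm$cost2$Q + alpha * gm$cost1$Q,
      QN_self = gm$cost2$QN + alpha * gm$cost1$QN,
      R_self = gm$cost2$R, R_other = gm$cost1$R, alpha = alpha, N = gm$N)
    expect_equal(nash$F2[[1]], BR2, tolerance = 1e-8)
  }
})

test_that("Nash gains are the limit of alternating best-response LQR solves", {
  # fold the frozen partner policy into the plant, solve the time-varying
  # LQR by its own backward recursion, swap players, iterate
  set.seed(3)
  gm <- random_game(n = 2, m = 1, N = 3, alpha = 0)
  tv_lqr <- function(A_list, B, Q_list, QN, R, N) {
    P <- QN; Fs <- vector("list", N)
    for (k in N:1) {
      PB <- P %*% B
      Fs[[k]] <- solve(R + crossprod(B, PB), t(PB) %*% A_list[[k]])
      Acl <- A_list[[k]] - B %*% Fs[[k]]
      P <- Q_list[[k]] + crossprod(Fs[[k]], R %*% Fs[[k]]) +
        crossprod(Acl, P %*% Acl)
    }
    Fs
  }
  F1 <- lapply(1:gm$N, function(k) matrix(0, 1, 2))
  F2 <- F1
  for (it in 1:200) {
    F1 <- tv_lqr(lapply(1:gm$N, function(k) gm$dyn$A - gm$dyn$B2 %*% F2[[k]]),
                 gm$dyn$B1, lapply(1:gm$N, function(k) gm$cost1$Q),
                 gm$cost1$QN, gm$cost1$R, gm$N)
    F2 <- tv_lqr(lapply(1:gm$N, function(k) gm$dyn$A - gm$dyn$B1 %*% F1[[k]]),
                 gm$dyn$B2, lapply(1:gm$N, function(k) gm$cost2$Q),
                 gm$cost2$QN, gm$cost2$R, gm$N)
  }
  nash <- solve_nash_gains(gm$dyn, gm$cost1, gm$cost2, gm$N)
  for (k in 1:gm$N) {
    expect_equal(nash$F1[[k]], F1[[k]], tolerance = 1e-8)
    expect_equal(nash$F2[[k]], F2[[k]], tolerance = 1e-8)
  }
})

test_that("raising the lateral accuracy weight raises the lateral cc gain", {
  p0 <- model_params(sensory_delay = 0, horizon_steps = 20)
  dyn <- build_dynamics(p0)
  gain_mag <- function(w) {
    p <- model_params(sensory_delay = 0, horizon_steps = 20,
                      terminal_weight_relevant = w)
    cs <- build_costs("pr/sr", "rep_weighted", p)
    g <- solve_nash_gains(dyn, cs$cost1, cs$cost2, p$horizon_steps)
    abs(g$F1[[10]][1, state_index("ccx")])
  }
  mags <- vapply(c(1000, 10000, 40000), gain_mag, numeric(1))
  expect_true(all(diff(mags) > 0))
})

test_that("decoupled and Nash self gains differ when the partner acts", {
  p <- model_params(sensory_delay = 0, horizon_steps = 20)
  dyn <- build_dynamics(p)
  cs <- build_costs("pr/si", "rep_self", p)
  nash <- solve_nash_gains(dyn, cs$cost1, cs$cost2, p$horizon_steps)
  dec <- solve_decoupled_gains(dyn, cs$cost1, cs$cost2, p$horizon_steps)
  expect_gt(max(abs(nash$F1[[1]] - dec$F1[[1]])), 1e-6)
  expect_false(dec$partner_representation)
  expect_true(nash$partner_representation)
})

test_that("decoupled gains with two irrelevant targets barely correct laterally", {
  p <- model_params(sensory_delay = 0, horizon_steps = 20)
  dyn <- build_dynamics(p)
  cs <- build_costs("pi/si", "no_rep_self", p)
  dec <- solve_decoupled_gains(dyn, cs$cost1, cs$cost2, p$horizon_steps)
  rel <- build_costs("pi/sr", "no_rep_self", p)
  dec_rel <- solve_decoupled_gains(dyn, rel$cost1, rel$cost2, p$horizon_steps)
  g_irr <- abs(dec$F1[[10]][1, state_index("ccx")])
  g_rel <- abs(dec_rel$F1[[10]][1, state_index("ccx")])
  expect_lt(g_irr, 0.05 * g_rel)
})
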