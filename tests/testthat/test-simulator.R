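test_that("trial specs validate label combinations and schedules", {
  p <- default_params()
  expect_error(make_trial_spec("pr/sr", "non_perturbation", "left", 1, p),
               "direction")
  expect_error(make_trial_spec("pr/sr", "probe", "none", 1, p), "direction")
  expect_error(make_trial_spec("pr/sr", "probe", "left", 3, p), "experiment")
  sp <- make_trial_spec("pr/sr", "probe", "right", 1, p)
  expect_equal(sp$onset_threshold, 0.0625)
  # probe schedule: 25 ms out, 200 ms hold, 25 ms back
  expect_equal(sp$displacement(0.0125), 0.015)
  expect_equal(sp$displacement(0.025), 0.03)
  expect_equal(sp$displacement(0.150), 0.03)
  expect_equal(sp$displacement(0.225), 0.03)
  expect_equal(sp$displacement(0.2375), 0.015)
  expect_equal(sp$displacement(0.300), 0)
  # perturbation persists to trial end
  sppert <- make_trial_spec("pr/sr", "perturbation", "left", 1, p)
  expect_equal(sppert$displacement(0.8), -0.03)
  # null probe never displaces
  spn <- make_trial_spec("pr/sr", "null_probe", "none", 1, p)
  expect_equal(spn$displacement(seq(0, 0.5, 0.05)), rep(0, 11))
})

test_that("a noise-free reach lands the center cursor on the target", {
  m <- cached_model("pr/sr", "rep_weighted")
  tr <- simulate_trial(m, make_trial_spec("pr/sr", "non_perturbation",
                                          "none", 1, m$params),
                       noise = FALSE)
  last <- nrow(tr)
  expect_lt(abs(tr$ccx[last] - 0), 1e-3)   # lateral: on target to < 1 mm
  expect_lt(abs(tr$ccy[last] - 0.25), 1e-2)  # forward: inside the target box
})

test_that("left and right jumps produce mirror-image responses without noise", {
  m <- cached_model("pr/sr", "rep_weighted")
  p <- m$params
  trL <- simulate_trial(m, make_trial_spec("pr/sr", "probe", "left", 1, p),
                        noise = FALSE)
  trR <- simulate_trial(m, make_trial_spec("pr/sr", "probe", "right", 1, p),
                        noise = FALSE)
  expect_equal(trL$force1, -trR$force1, tolerance = 1e-12)
  expect_equal(trL$force2, -trR$force2, tolerance = 1e-12)
  trLp <- simulate_trial(m, make_trial_spec("pr/sr", "perturbation", "left",
                                            1, p), noise = FALSE)
  trRp <- simulate_trial(m, make_trial_spec("pr/sr", "perturbation", "right",
                                            1, p), noise = FALSE)
  expect_equal(trLp$p1x - 0.13, -(trRp$p1x - 0.13), tolerance = 1e-10)
})

test_that("the force channel freezes lateral hand motion to machine precision", {
  m <- cached_model("pr/sr", "rep_weighted")
  tr <- simulate_probe(m, make_trial_spec("pr/sr", "probe", "left", 1,
                                          m$params), seed = 21)
  expect_equal(tr$p1x, rep(0.13, nrow(tr)), tolerance = 1e-12)
  expect_equal(tr$p2x, rep(-0.13, nrow(tr)), tolerance = 1e-12)
  # the reported applied force is nonetheless nonzero after the jump
  expect_gt(max(abs(tr$force1)), 0.01)
  expect_error(simulate_probe(m, make_trial_spec("pr/sr", "perturbation",
                                                 "left", 1, m$params)),
               "probe")
})

test_that("a noise-free null probe produces no lateral force", {
  m <- cached_model("pr/sr", "rep_weighted")
  tr <- simulate_trial(m, make_trial_spec("pr/sr", "null_probe", "none", 1,
                                          m$params), noise = FALSE)
  expect_lt(max(abs(tr$force1)), 1e-9)
  expect_lt(max(abs(tr$force2)), 1e-9)
})

test_that("forward kinematics match between probe and free trials pre-jump", {
  m <- cached_model("pr/sr", "rep_weighted")
  p <- m$params
  pr <- simulate_trial(m, make_trial_spec("pr/sr", "probe", "left", 1, p),
                       seed = 77)
  np <- simulate_trial(m, make_trial_spec("pr/sr", "non_perturbation",
                                          "none", 1, p), seed = 77)
  onset <- attr(pr, "jump_onset_step")
  pre <- seq_len(onset)
  expect_equal(pr$p1y[pre], np$p1y[pre], tolerance = 1e-10)
  expect_equal(pr$ccy[pre], np$ccy[pre], tolerance = 1e-10)
})

test_that("an irrelevant-target pair does not correct a persistent jump", {
  m <- cached_model("pi/si", "rep_weighted")
  tr <- simulate_trial(m, make_trial_spec("pi/si", "perturbation", "left",
                                          1, m$params), noise = FALSE)
  last <- nrow(tr)
  expect_lt(abs(tr$p1x[last] - 0.13), 3e-3)
  expect_lt(abs(tr$p2x[last] + 0.13), 3e-3)
  # a fully relevant pair corrects by an order of magnitude more
  m2 <- cached_model("pr/sr", "rep_weighted")
  tr2 <- simulate_trial(m2, make_trial_spec("pr/sr", "perturbation", "left",
                                            1, m2$params), noise = FALSE)
  expect_gt(abs(tr2$p1x[last] - 0.13), 10 * abs(tr$p1x[last] - 0.13))
})

test_that("batches are reproducible and respect the trial count default", {
  expect_identical(formals(run_batch)$n_trials, 100L)
  p <- default_params()
  b1 <- run_batch("rep_weighted", "pr/sr", p, n_trials = 3, seed = 5,
                  kalman = default_kalman())
  b2 <- run_batch("rep_weighted", "pr/sr", p, n_trials = 3, seed = 5,
                  kalman = default_kalman())
  expect_identical(b1[["pr/sr"]]$vfr_mean, b2[["pr/sr"]]$vfr_mean)
  expect_identical(b1[["pr/sr"]]$epochs, b2[["pr/sr"]]$epochs)
})

test_that("trial-to-trial response spread scales with the noise level", {
  sds <- vapply(c(1, 0.5, 0.25), function(s) {
    p <- model_params(pos_noise_sd = 0.002 * s, vel_noise_sd = 0.02 * s,
                      force_noise_sd = 0.02 * s, process_noise_sd = 1e-4 * s)
    b <- run_batch("rep_weighted", "pr/sr", p, n_trials = 8, seed = 13)
    stats::sd(b[["pr/sr"]]$epochs$involuntary)
  }, numeric(1))
  # halving all noise scales roughly halves the spread; allow slack for
  # the small batch
  expect_lt(sds[2], 0.75 * sds[1])
  expect_lt(sds[3], 0.75 * sds[2])
  expect_gt(sds[3], 0)
})
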