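test_that("the zero-phase Butterworth filter has unit DC gain", {
  x <- rep(1, 1000)
  expect_equal(lowpass(x, 1000), x, tolerance = 1e-8)
})

test_that("filter attenuation matches the analytic magnitude response", {
  fs <- 1000; t <- seq(0, 2, by = 1 / fs)
  # dual-pass 5th-order magnitude: |H(f)|^2 with |H| evaluated from the
  # digital filter's transfer function at the sinusoid frequency
  bf <- signal::butter(5, 14 / (fs / 2), type = "low")
  mag2 <- function(f) {
    z <- exp(-2i * pi * f / fs)
    h <- sum(bf$b * z^(0:(length(bf$b) - 1))) /
      sum(bf$a * z^(0:(length(bf$a) - 1)))
    Mod(h)^2
  }
  amp_out <- function(f) {
    y <- lowpass(sin(2 * pi * f * t), fs)
    mid <- y[(length(y) %/% 4):(3 * length(y) %/% 4)]
    max(abs(mid))
  }
  expect_lt(amp_out(50), 0.01)
  expect_equal(amp_out(50), mag2(50), tolerance = 0.3)
  expect_equal(amp_out(1), mag2(1), tolerance = 0.02)
  expect_gt(amp_out(1), 0.98)
})

test_that("filter input validation rejects unusable traces", {
  expect_error(lowpass(rep(1, 500), sample_rate = 20), "cutoff")
  expect_error(lowpass(rep(1, 5), 1000), "short")
})

test_that("alignment moves time zero to presentation and is idempotent", {
  tr <- response_trace(seq(0, 1, 0.001), rnorm(1001))
  al <- align_trace(tr, jump_command_time = 0.5)
  # the sample formerly at 542 ms is now at zero
  expect_equal(al$time[which(abs(al$time) < 1e-9)],
               0)
  expect_equal(tr$force[abs(tr$time - 0.542) < 1e-9],
               al$force[abs(al$time) < 1e-9])
  al0 <- align_trace(tr, 0.5, display_delay = 0)
  expect_equal(al0$time, tr$time - 0.5)
  expect_equal(align_trace(al, 0, display_delay = 0), al)
  expect_error(align_trace(tr, 2), "outside")
})

test_that("differencing follows the per-experiment sign conventions", {
  t <- seq(0, 0.5, 0.001)
  f <- sin(2 * pi * 3 * t)
  zero <- visuomotor_response(f, f, t, experiment = 1)
  expect_equal(zero$force, rep(0, length(t)))
  v1 <- visuomotor_response(f, -f, t, experiment = 1)
  expect_equal(v1$force, 2 * f)
  v2 <- visuomotor_response(f, -f, t, experiment = 2)
  expect_equal(v2$force, -2 * f)
  # trial averaging happens within direction before differencing
  L <- rbind(f, 3 * f)
  v <- visuomotor_response(L, -f, t, experiment = 1)
  expect_equal(v$force, 3 * f)
  expect_error(visuomotor_response(f[-1], f, t), "time grid")
})

test_that("epoch means use half-open windows at the stated boundaries", {
  t <- seq(0, 0.5, 0.001)
  const <- response_trace(t, rep(1, length(t)))
  expect_equal(unlist(epoch_means(const)),
               c(involuntary = 1, semi_involuntary = 1, voluntary = 1))
  # linear ramp 0 -> 1 N over 0-400 ms: window means equal the mean of
  # the ramp over the discrete half-open windows
  ramp <- response_trace(t, pmin(t / 0.4, 1))
  em <- epoch_means(ramp)
  ramp_mean <- function(a, b) mean(pmin(t[t >= a & t < b] / 0.4, 1))
  expect_equal(em$involuntary, ramp_mean(0.18, 0.23))
  expect_equal(em$involuntary, 0.5125, tolerance = 0.005)
  expect_equal(em$semi_involuntary, ramp_mean(0.23, 0.30))
  expect_equal(em$voluntary, ramp_mean(0.30, 0.40))
  # a spike exactly at 230 ms belongs to the semi-involuntary window
  spike <- rep(0, length(t)); spike[abs(t - 0.230) < 1e-9] <- 1
  em2 <- epoch_means(response_trace(t, spike))
  expect_equal(em2$involuntary, 0)
  expect_gt(em2$semi_involuntary, 0)
  short <- response_trace(seq(0, 0.3, 0.001), rep(1, 301))
  expect_error(epoch_means(short), "cover")
})

test_that("epoch means scale linearly with the input forces", {
  t <- seq(0, 0.5, 0.001)
  set.seed(2)
  f <- cumsum(rnorm(length(t), sd = 0.01))
  e1 <- unlist(epoch_means(response_trace(t, f)))
  e3 <- unlist(epoch_means(response_trace(t, 3 * f)))
  expect_equal(e3, 3 * e1, tolerance = 1e-12)
})

test_that("final lateral deviation folds directions and ignores offsets", {
  expect_equal(final_lateral_deviation(rep(0, 5), rep(-0.02, 5)), 0.02)
  expect_equal(final_lateral_deviation(rep(0.1, 5), rep(0.1, 5)), 0)
  # folding mirrors left-jump corrections onto the right-jump side
  nonp <- rep(0.13, 10)
  pert <- c(rep(0.13 + 0.02, 5), rep(0.13 - 0.02, 5))   # left, right
  dirs <- rep(c("left", "right"), each = 5)
  expect_equal(final_lateral_deviation(nonp, pert, dirs), 0.02)
  # constant offset on every trial cancels
  expect_equal(final_lateral_deviation(nonp + 0.05, pert + 0.05, dirs), 0.02)
  expect_error(final_lateral_deviation(numeric(0), 1), "at least one")
})
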