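make_pulse <- function(n = 3000, rate = 1000, hs = 301, to = 2200,
                       peak = 700, ramp = 25) {
  y <- numeric(n)
  up <- seq(hs, hs + ramp)
  y[up] <- seq(0, peak, length.out = length(up))
  y[(hs + ramp):(to - ramp)] <- peak
  dn <- seq(to - ramp, to)
  y[dn] <- seq(peak, 0, length.out = length(dn))
  y
}

test_that("heel strike is the last zero sample before the loading ramp", {
  y <- make_pulse()
  ev <- detect_gait_events(y, 1000)
  expect_equal(ev$heel_strikes, 301L)
  expect_equal(ev$toe_offs, 2200L)
  expect_equal(ev$hs_times, 300 / 1000)
})

test_that("the 10 N hysteresis absorbs plate noise", {
  y <- make_pulse()
  set.seed(21)
  yn <- y + runif(length(y), -2, 2)
  ev0 <- detect_gait_events(y, 1000)
  ev <- detect_gait_events(yn, 1000)
  expect_length(ev$heel_strikes, 1)
  expect_length(ev$toe_offs, 1)
  expect_lte(abs(ev$heel_strikes - ev0$heel_strikes), 5)
  expect_lte(abs(ev$toe_offs - ev0$toe_offs), 5)
})

test_that("flat channels raise a no-events error", {
  expect_error(detect_gait_events(rep(0, 500), 1000), "no gait events")
  expect_error(detect_gait_events(rep(400, 500), 1000), "no gait events")
})

test_that("a 35-stride trial yields exactly 30 analysed steps", {
  tau <- 0.55
  hs_L <- (0:34) * 2 * tau
  hs_R <- hs_L + tau
  mk <- function(hs, to) structure(list(hs_times = hs, to_times = to),
                                   class = "gait_events")
  ev_L <- mk(hs_L, hs_R + 0.1)           # L toe-off shortly after R strike
  ev_R <- mk(hs_R, (hs_L + 0.1)[-1])
  steps <- build_steps(ev_L, ev_R, last_n = 30)
  expect_equal(nrow(steps), 30)
  expect_true(all(steps$t_next_hs > steps$t_hs))
  expect_true(all(steps$t_to_trailing - steps$t_hs > 0))
  all_steps <- build_steps(ev_L, ev_R, last_n = Inf)
  expect_gt(nrow(all_steps), 60)
})
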