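test_that("section and gait descriptors round-trip exactly", {
  set.seed(11)
  for (i in 1:100) {
    s <- runif(1, 0.02, 0.98); v <- runif(1, 0.02, 0.98)
    sec <- gait_to_section(s, v)
    g <- section_to_gait(sec$theta, sec$theta_dot)
    expect_equal(g$s, s, tolerance = 1e-12)
    expect_equal(g$v, v, tolerance = 1e-12)
  }
  expect_equal(gait_to_section(0.6, 0.39)$theta, -asin(0.3))
})

test_that("out-of-range gaits are rejected at the boundary", {
  expect_error(section_to_gait(0, 0.3), "step length")
  expect_error(gait_to_section(0.5, 1), "speed")
  expect_error(gait_to_section(1, 0.5), "step length")
})

test_that("margin of stability is s/2 - v with the right monotonicities", {
  expect_equal(margin_of_stability(0.6, 0.39), -0.09)
  expect_equal(margin_of_stability(0.6, 1e-9), 0.3, tolerance = 1e-6)
  b_v <- vapply(seq(0.1, 0.9, 0.1), margin_of_stability, numeric(1), s = 0.6)
  expect_true(all(diff(b_v) < 0))
  b_s <- vapply(seq(0.1, 0.9, 0.1), margin_of_stability, numeric(1), v = 0.3)
  expect_true(all(diff(b_s) > 0))
})

test_that("the CoM position cancels from the XcoM decomposition", {
  set.seed(5)
  for (i in 1:20) {
    s <- runif(1, 0.1, 0.9); v <- runif(1, 0.1, 0.9); x <- runif(1, -5, 5)
    d <- mos_decomposition(s, v, x)
    expect_equal(d$b, margin_of_stability(s, v), tolerance = 1e-12)
    expect_equal(d$u - d$x, s / 2)
    expect_equal(d$xi - d$x, v)
  }
})

test_that("the two printed forms of the propulsive force agree", {
  ## oracle: F = I_push sin(-theta*) / dt_DS
  set.seed(9)
  for (i in 1:20) {
    s <- runif(1, 0.1, 0.9); v <- runif(1, 0.1, 0.9); mu <- runif(1, 0.05, 0.3)
    ip <- optimal_push_off(s, v, mu)
    th <- -asin(s / 2); thd <- v / cos(th)
    oracle <- ip * sin(-th) / (mu / thd)
    expect_equal(propulsive_force(s, v, mu, ip), oracle, tolerance = 1e-12)
  }
  expect_lt(propulsive_force(1e-6, 0.4, 0.142, i_push = 0.2), 1e-5)
  expect_error(propulsive_force(0.5, 0.4, mu = 0), "mu")
})

test_that("maximum flexion torque is consistent with its angle", {
  g <- fig2_gait()
  tq <- max_flexion_torque(g$trajectory)
  expect_equal(tq$T, g$k_star * tq$phi_max, tolerance = 1e-12)
  expect_gte(tq$phi_max, 0)
  ## the refined maximum is at least the discrete one
  expect_gte(tq$T, max(-g$k_star * g$trajectory$states[, "phi"]) - 1e-12)
  expect_equal(max_flexion_torque(g$trajectory, k = 0), list(T = 0, phi_max = 0))
  expect_error(max_flexion_torque(list(states = NULL)), "samples")
})
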