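test_that("the worked-example gait is found and lands symmetrically", {
  g <- fig2_gait()
  expect_equal(g$k_star, FIG2_K, tolerance = 1e-6)
  expect_equal(g$s, FIG2_S, tolerance = 1e-9)
  pre <- g$trajectory$pre_collision
  expect_equal(pre[["theta"]], -g$theta_star, tolerance = 1e-6)
  expect_equal(pre[["theta_dot"]], g$theta_dot_star, tolerance = 1e-6)
  expect_lt(g$residual, 1e-8)
})

test_that("exactly one scuffing crossing is ignored for the mid-range gait", {
  g <- fig2_gait()
  expect_length(g$scuff_times, 1)
  ## the scuff happens as the legs pass each other near the vertical
  i <- which.min(abs(g$trajectory$times - g$scuff_times[1]))
  expect_lt(abs(g$trajectory$states[i, "theta"]), 0.05)
})

test_that("non-walking parameter sets raise a no-collision error", {
  expect_error(
    integrate_swing(-0.05, 0.01, walker_params(k = 0, max_step_time = 15)),
    "no collision")
})

test_that("the fixed point is a fixed point of the Poincare map", {
  g <- fig2_gait()
  m1 <- poincare_map(g$theta_star, g$theta_dot_star, g$params)
  expect_lt(max(abs(c(m1$theta - g$theta_star,
                      m1$theta_dot - g$theta_dot_star))), 1e-8)
  m2 <- poincare_map(m1$theta, m1$theta_dot, g$params)
  expect_lt(max(abs(c(m2$theta - g$theta_star,
                      m2$theta_dot - g$theta_dot_star))), 1e-8)
})

test_that("the map is continuous around the fixed point", {
  g <- fig2_gait()
  m <- poincare_map(g$theta_star + 1e-3, g$theta_dot_star, g$params)
  d1 <- max(abs(c(m$theta - g$theta_star, m$theta_dot - g$theta_dot_star)))
  m2 <- poincare_map(g$theta_star + 1e-4, g$theta_dot_star, g$params)
  d2 <- max(abs(c(m2$theta - g$theta_star, m2$theta_dot - g$theta_dot_star)))
  expect_lt(d1, 0.05)
  expect_lt(d2, d1)
})

test_that("fixed-point search by speed recovers the worked example", {
  g0 <- fig2_gait()
  g <- periodic_gait(FIG2_V, stiffness = g0$k_star)
  expect_equal(g$s, FIG2_S, tolerance = 1e-6)
  expect_lt(g$residual, 1e-10)
})

test_that("spring-free fixed point reports unit swing frequency", {
  g <- periodic_gait(0.3991, stiffness = 0)
  expect_equal(g$omega, 1)
  expect_lt(g$residual, 1e-8)
})

test_that("mechanical energy is conserved across one mapped step", {
  g <- fig2_gait()
  E_post <- mechanical_energy(g$theta_star, g$theta_dot_star, g$params)
  E_pre_full <- state_energy(g$trajectory$pre_collision, g$params)
  m <- poincare_map(g$theta_star, g$theta_dot_star, g$params)
  E_next <- mechanical_energy(m$theta, m$theta_dot, g$params)
  expect_equal(E_pre_full, E_post, tolerance = 1e-8)
  expect_equal(E_next, E_post, tolerance = 1e-8)
})

test_that("stiffness search is monotone in the target speed", {
  ks <- vapply(c(0.35, 0.39, 0.43), function(v)
    periodic_gait(v, step_length = 0.6)$k_star, numeric(1))
  expect_true(all(diff(ks) > 0))
})

test_that("degenerate step-length targets are rejected, not silently returned", {
  expect_error(periodic_gait(0.39, step_length = 0), "step length")
  expect_error(periodic_gait(0.39, step_length = 1.2), "step length")
  expect_error(periodic_gait(1.5, stiffness = 0.1), "speed")
})

test_that("hip torque is flexion-positive early and extension-negative late", {
  g <- fig2_gait()
  torque <- -g$k_star * g$trajectory$states[, "phi"]
  expect_gt(torque[1], 0)                     # 0% of the gait cycle
  expect_lt(torque[length(torque)], 0)        # 100% of the gait cycle
})

test_that("simulate() rolls converging steps and coef/residuals are consistent", {
  g <- fig2_gait()
  sim <- simulate(g, nsim = 3, perturb = c(1e-3, 0))
  expect_equal(nrow(sim), 3)
  expect_lt(abs(sim$theta[3] - g$theta_star), 1e-3)
  expect_named(residuals(g), c("theta", "theta_dot"))
  expect_equal(unname(coef(g)["b"]), g$s / 2 - g$v)
})
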