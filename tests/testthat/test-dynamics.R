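test_that("upright rest state is an equilibrium of the full dynamics", {
  d <- eom_rhs(c(0, 0, 0, 0), walker_params(k = 0.3))
  expect_equal(unname(d), c(0, 0, 0, 0))
})

test_that("accelerations match the closed-form solve of the mass-matrix system", {
  ## oracle: direct symbolic 2x2 solve, computed independently
  d <- eom_rhs(c(0.1, 0, 0, 0), walker_params(beta = 0.074, k = 0))
  expect_equal(d[["theta_ddot"]], 0.107142068280, tolerance = 1e-9)
  expect_equal(d[["phi_ddot"]], -0.106606804215, tolerance = 1e-9)
})

test_that("non-finite states are rejected", {
  expect_error(eom_rhs(c(NA, 0, 0, 0)), "finite")
  expect_error(eom_rhs(c(0, Inf, 0, 0)), "finite")
})

test_that("linearized dynamics solve the small-angle system exactly", {
  p <- walker_params(beta = 0.074, k = 0.05)
  om2 <- natural_frequency(p)^2
  phi0 <- 0.2
  d <- linearized_rhs(c(0, phi0, 0, 0), p)
  expect_equal(d[["phi_ddot"]], -(1 + p$beta) * om2 * phi0, tolerance = 1e-12)
  expect_equal(d[["theta_ddot"]], -(p$beta / (1 + p$beta)) * d[["phi_ddot"]],
               tolerance = 1e-12)
  ## spring-free stance perturbation
  p0 <- walker_params(beta = 0.074, k = 0)
  th0 <- 0.15
  d0 <- linearized_rhs(c(th0, 0, 0, 0), p0)
  expect_equal(d0[["theta_ddot"]], th0 * (1 + p0$beta), tolerance = 1e-12)
  expect_equal(unname(linearized_rhs(c(0, 0, 0, 0), p)), c(0, 0, 0, 0))
})

test_that("nonlinear accelerations converge to the linearized ones as angles shrink", {
  p <- walker_params(k = 0.1)
  scales <- 10^seq(-1, -4)
  rel_err <- vapply(scales, function(sc) {
    st <- c(0.7, -0.5, 0.3, -0.6) * sc
    a <- eom_rhs(st, p)[3:4]
    b <- linearized_rhs(st, p)[3:4]
    max(abs(a - b)) / max(abs(b))
  }, numeric(1))
  expect_true(all(diff(rel_err) < 0))          # monotone improvement
  expect_lt(rel_err[length(rel_err)], 1e-6)
})

test_that("natural frequency follows sqrt(1 + k/beta)", {
  expect_equal(natural_frequency(walker_params(k = 0)), 1)
  expect_equal(natural_frequency(walker_params(beta = 0.1, k = 0.3)), 2)
  expect_equal(natural_frequency(walker_params(beta = 0.2, k = 0.2)), sqrt(2))
  expect_error(walker_params(beta = -1), "beta")
})

test_that("section energy matches the direct kinematic energy computation", {
  p <- walker_params(k = 0.12)
  qs <- random_sections(20, seed = 42)
  for (i in seq_len(nrow(qs))) {
    E1 <- mechanical_energy(qs$theta[i], qs$theta_dot[i], p)
    E2 <- state_energy(section_to_state(qs$theta[i], qs$theta_dot[i]), p)
    expect_equal(E1, E2, tolerance = 1e-12)
  }
  expect_equal(mechanical_energy(0, 0, walker_params()), 1)
  ## strictly increasing in |theta_dot| at fixed theta
  e <- vapply(seq(0.1, 0.8, by = 0.1), mechanical_energy, numeric(1),
              theta = -0.3, params = p)
  expect_true(all(diff(e) > 0))
})

test_that("single-support trajectories conserve mechanical energy", {
  g <- fig2_gait()
  E <- apply(g$trajectory$states, 1, state_energy, params = g$params)
  expect_lt(max(abs(E - E[1])), 1e-8)
})
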