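test_that("double-support law gives the gravitational impulse", {
  expect_equal(gravity_impulse(0.142, 0.142)$i_gravity, 1)
  expect_equal(gravity_impulse(0.5, 0)$i_gravity, 0)
  expect_equal(gravity_impulse(0.4, 0.142)$dt_ds, 0.355)
  expect_error(gravity_impulse(0, 0.142), "forward")
  expect_error(gravity_impulse(-0.3, 0.142), "forward")
})

test_that("transition with no impulses at theta = 0 is the identity on theta_dot", {
  post <- collision_transition(c(0, 0, 0.5, -0.5), 0, 0, walker_params())
  expect_equal(post[["theta_dot"]], 0.5, tolerance = 1e-14)
})

test_that("massless-feet limit reduces to the classical compass-walker loss factor", {
  th <- 0.3
  post <- collision_transition(c(th, th, 0.45, -0.3), 0, 0,
                               walker_params(beta = 1e-12))
  expect_equal(post[["theta_dot"]], 0.45 * cos(2 * th), tolerance = 1e-9)
})

test_that("contact-condition contract is enforced", {
  expect_error(collision_transition(c(0.3, 0.1, 0.4, -0.3), 0, 0),
               "contact condition")
})

test_that("swing-leg velocity row is consistent with the stance row", {
  ## phi_dot_plus = -theta_dot_plus * cos(2 theta_plus) for any impulses
  p <- walker_params()
  set.seed(3)
  for (i in 1:20) {
    th <- runif(1, 0.05, 0.45)
    thd <- runif(1, 0.1, 0.8)
    ip <- runif(1, 0, 0.5); ig <- runif(1, 0, 0.5)
    post <- collision_transition(c(th, th, thd, -0.2), ip, ig, p)
    expect_equal(post[["phi_dot"]],
                 -post[["theta_dot"]] * cos(2 * post[["theta"]]),
                 tolerance = 1e-12)
  }
})

test_that("the two printed forms of the optimal push-off agree", {
  ## oracle: the theta*-form evaluated via theta* = -asin(s/2)
  set.seed(7)
  for (i in 1:25) {
    s <- runif(1, 0.1, 0.9); v <- runif(1, 0.1, 0.9)
    mu <- runif(1, 0, 0.3); beta <- 0.074
    th <- -asin(s / 2); thd <- v / cos(th)
    oracle <- -thd * tan(th) * (2 * beta * cos(th)^2 + 1) +
      mu / (2 * thd * cos(th))
    expect_equal(optimal_push_off(s, v, mu, beta), oracle, tolerance = 1e-12)
  }
})

test_that("push-off limits and signs behave as the closed form requires", {
  expect_equal(optimal_push_off(1e-9, 0.4, mu = 0.142), 0.142 / 0.8,
               tolerance = 1e-6)
  expect_gt(optimal_push_off(0.5, 0.4, mu = 0), 0)
  expect_error(optimal_push_off(1.2, 0.4), "step length")
  expect_error(optimal_push_off(0.5, 0), "speed")
})

test_that("optimal push-off restores the stance velocity across the transition", {
  g <- fig2_gait()
  pre <- g$trajectory$pre_collision
  ig <- gravity_impulse(pre[[3]], g$params$mu)
  post <- collision_transition(pre, g$i_push, ig$i_gravity, g$params)
  expect_equal(post[["theta_dot"]], pre[[3]], tolerance = 1e-10)
  ## and the trajectory-level impulse equals the closed form
  expect_equal(g$i_push, optimal_push_off(g$s, g$v, g$params$mu, g$params$beta),
               tolerance = 1e-8)
})
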