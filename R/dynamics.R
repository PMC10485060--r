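#' Equations of motion of the walking model
#'
#' Right-hand side of the nonlinear single-support dynamics. The stance leg
#' angle `theta` is measured from the vertical (positive clockwise, i.e.
#' towards the direction of travel) and the swing leg angle `phi` from the
#' trunk (positive counterclockwise). The accelerations solve the 2x2 linear
#' system given by the inertia matrix, Coriolis/centrifugal, gravity and
#' spring terms; the matrix is inverted in closed form.
#'
#' @param state named numeric vector `(theta, phi, theta_dot, phi_dot)`.
#' @param params a [walker_params] object.
#' @return Named numeric vector `(theta_dot, phi_dot, theta_ddot, phi_ddot)`.
#' @seealso [linearized_rhs] for the small-angle dynamics.
#' @export
eom_rhs <- function(state, params = walker_params()) {
  state <- as_walker_state(state[1], state[2], state[3], state[4])
  beta <- params$beta; k <- params$k
  th <- state[[1]]; ph <- state[[2]]; thd <- state[[3]]; phd <- state[[4]]
  cc <- cos(th + ph); ss <- sin(th + ph)
  det <- beta * (1 + beta) - beta^2 * cc^2
  b1 <- beta * ss * phd^2 + (1 + beta) * sin(th)
  b2 <- beta * ss * thd^2 - beta * sin(ph) - k * ph
  c(theta_dot = thd, phi_dot = phd,
    theta_ddot = unname((beta * b1 - beta * cc * b2) / det),
    phi_ddot = unname(((1 + beta) * b2 - beta * cc * b1) / det))
}

#' Linearized equations of motion
#'
#' Small-oscillation form of the dynamics: `theta_dd + beta/(1+beta) phi_dd -
#' theta = 0` and `phi_dd + theta_dd + omega^2 phi = 0`, with `omega` the
#' swing-leg natural frequency ([natural_frequency]). Used for the swing
#' tuning analysis; all trajectory work integrates the nonlinear dynamics.
#'
#' @inheritParams eom_rhs
#' @return Named numeric vector `(theta_dot, phi_dot, theta_ddot, phi_ddot)`.
#' @export
linearized_rhs <- function(state, params = walker_params()) {
  state <- as_walker_state(state[1], state[2], state[3], state[4])
  beta <- params$beta
  om2 <- natural_frequency(params)^2
  th <- state[[1]]; ph <- state[[2]]
  cc <- beta / (1 + beta)
  ## [1 cc; 1 1] [th_dd; ph_dd] = [th; -om2*ph]
  det <- 1 - cc
  th_dd <- (th + cc * om2 * ph) / det
  ph_dd <- (-om2 * ph - th) / det
  c(theta_dot = state[[3]], phi_dot = state[[4]],
    theta_ddot = th_dd, phi_ddot = ph_dd)
}

#' Mechanical energy at a Poincare-section state
#'
#' `E = (1/2)(1 + beta sin^2 2theta) theta_dot^2 + cos(theta) +
#' (1/2) k theta^2`: kinetic energy, gravitational potential and spring
#' potential of the post-collision state (where `phi = theta` and the swing
#' foot is at ground level). Under the optimal push-off hypothesis this energy
#' is conserved from one section to the next.
#'
#' @param theta,theta_dot section state.
#' @param params a [walker_params] object.
#' @return Dimensionless mechanical energy.
#' @export
mechanical_energy <- function(theta, theta_dot, params = walker_params()) {
  0.5 * (1 + params$beta * sin(2 * theta)^2) * theta_dot^2 +
    cos(theta) + 0.5 * params$k * theta^2
}

#' Mechanical energy of an arbitrary full state
#'
#' Direct kinematic evaluation: kinetic energy of the hip mass and swing-foot
#' mass, gravitational potential of both (stance foot at the origin), and the
#' spring potential `k phi^2 / 2`. Agrees with [mechanical_energy] on section
#' states and is constant along single-support trajectories.
#'
#' @param state full state `(theta, phi, theta_dot, phi_dot)`.
#' @param params a [walker_params] object.
#' @return Dimensionless mechanical energy.
#' @export
state_energy <- function(state, params = walker_params()) {
  beta <- params$beta
  th <- state[[1]]; ph <- state[[2]]; thd <- state[[3]]; phd <- state[[4]]
  ## hip at (sin th, cos th); swing foot at hip + (sin ph, -cos ph)
  v_hip2 <- thd^2
  v_foot2 <- thd^2 + phd^2 + 2 * thd * phd * cos(th + ph)
  kin <- 0.5 * v_hip2 + 0.5 * beta * v_foot2
  pot <- cos(th) + beta * (cos(th) - cos(ph))
  kin + pot + 0.5 * params$k * ph^2
}
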