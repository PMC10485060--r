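#' @keywords internal
check_gait_range <- function(s, v) {
  if (any(!is.finite(s)) || any(!is.finite(v)))
    stop("step length and speed must be finite", call. = FALSE)
  if (any(s <= 0 | s >= 1))
    stop("step length s must lie in (0, 1)", call. = FALSE)
  if (any(v <= 0 | v >= 1))
    stop("walking speed v must lie in (0, 1)", call. = FALSE)
  invisible(TRUE)
}

#' Convert between section states and gait descriptors
#'
#' A post-collision section state maps to the gait descriptors as
#' `s = -2 sin(theta)` (step length) and `v = theta_dot cos(theta)`
#' (walking speed, the forward hip velocity at heel strike); both are
#' restricted to (0, 1).
#'
#' @param theta,theta_dot section state (`theta < 0` for a forward step).
#' @return `section_to_gait`: list with `s` and `v`.
#' @export
section_to_gait <- function(theta, theta_dot) {
  s <- -2 * sin(theta)
  v <- theta_dot * cos(theta)
  check_gait_range(s, v)
  list(s = s, v = v)
}

#' @rdname section_to_gait
#' @param s step length in (0, 1).
#' @param v walking speed in (0, 1).
#' @return `gait_to_section`: list with `theta` and `theta_dot`.
#' @export
gait_to_section <- function(s, v) {
  check_gait_range(s, v)
  theta <- -asin(s / 2)
  list(theta = theta, theta_dot = v / cos(theta))
}

#' Margin of stability at heel strike
#'
#' Sagittal margin of stability `b = s/2 - v`: the distance from the
#' extrapolated centre of mass (XcoM, CoM position plus CoM velocity in
#' dimensionless units) to the anterior boundary of the base of support at
#' heel strike, where the CoM projection bisects the step.
#'
#' @inheritParams gait_to_section
#' @return The margin of stability (negative when the XcoM is ahead of the
#'   leading foot).
#' @export
margin_of_stability <- function(s, v) {
  check_gait_range(s, v)
  s / 2 - v
}

#' Margin-of-stability decomposition
#'
#' Explicit XcoM decomposition of the margin of stability: with CoM position
#' `x`, the anterior base-of-support boundary is `u = x + s/2`, the XcoM is
#' `xi = x + v`, and `b = u - xi`. The CoM position cancels, so `b` equals
#' [margin_of_stability] for any `x`.
#'
#' @inheritParams gait_to_section
#' @param x CoM position at heel strike (arbitrary origin).
#' @return List with `x`, `u`, `xi` and `b`.
#' @export
mos_decomposition <- function(s, v, x = 0) {
  check_gait_range(s, v)
  u <- x + s / 2
  xi <- x + v
  list(x = x, u = u, xi = xi, b = u - xi)
}

#' Propulsive force of the push-off
#'
#' Mean forward force exerted by the push-off impulse over the double-support
#' period: `F = I_push sin(-theta*) / dt_DS = s v / (mu sqrt(4 - s^2)) I_push`.
#'
#' @inheritParams gait_to_section
#' @param mu double-support constant, > 0.
#' @param i_push push-off impulse (defaults to the optimal push-off of the
#'   periodic gait at `(s, v)`).
#' @param beta mass ratio (used only for the default `i_push`).
#' @return The dimensionless propulsive force.
#' @export
propulsive_force <- function(s, v, mu = 0.142,
                             i_push = optimal_push_off(s, v, mu, beta),
                             beta = 0.074) {
  check_gait_range(s, v)
  if (!is.finite(mu) || mu <= 0)
    stop("'mu' must be > 0: the propulsive force is the impulse divided by the double-support period",
         call. = FALSE)
  s * v / (mu * sqrt(4 - s^2)) * i_push
}

#' Maximum hip flexion torque along a step
#'
#' The hip spring exerts torque `-k phi` on the swing leg (positive values are
#' flexion torque). The maximum over the step, `T = max(-k phi) = k phi_max`,
#' is located on the sampled trajectory and refined by a three-point quadratic
#' interpolation around the discrete argmax; `phi_max >= 0` is the hip
#' extension angle at that instant.
#'
#' @param traj a sampled [integrate_swing] trajectory (needs `states`).
#' @param k hip spring constant (defaults to the stiffness the trajectory was
#'   integrated with).
#' @return List with `T` and `phi_max` (both 0 when `k = 0`).
#' @export
max_flexion_torque <- function(traj, k = traj$k) {
  if (is.null(traj$states) || nrow(traj$states) == 0)
    stop("trajectory has no samples; rerun integrate_swing with n_samples > 0",
         call. = FALSE)
  if (k == 0) return(list(T = 0, phi_max = 0))
  mphi <- -traj$states[, "phi"]
  i <- which.max(mphi)
  phi_max <- mphi[i]
  if (i > 1 && i < length(mphi)) {
    ## quadratic refinement of the continuous-time maximum
    y1 <- mphi[i - 1]; y2 <- mphi[i]; y3 <- mphi[i + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) phi_max <- y2 - (y3 - y1)^2 / (8 * denom)
  }
  phi_max <- max(phi_max, 0)
  list(T = k * phi_max, phi_max = phi_max)
}
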