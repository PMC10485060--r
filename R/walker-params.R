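#' Walker model parameters
#'
#' Constructs the parameter set of the powered simple walking model: a point
#' mass at the hip, point feet of relative mass `beta`, a torsional hip spring
#' of stiffness `k` between trunk and swing leg, and impulsive push-off and
#' gravitational actuation at the step-to-step transition. All quantities are
#' dimensionless in the basis overall mass M = 1, leg length l = 1, time
#' sqrt(l/g) = 1.
#'
#' @param beta foot-to-hip mass ratio m/M. The default 0.074 makes the foot
#'   moment of inertia about the hip match the human lower limb.
#' @param k hip spring constant (dimensionless torque per radian), >= 0.
#' @param mu proportionality constant of the double-support law
#'   `dt_DS = mu / theta_dot_minus`; also the magnitude of the gravitational
#'   impulse. The default 0.142 is the mean value estimated from treadmill
#'   walking.
#' @param integ_rel_tol,integ_abs_tol relative and absolute tolerances of the
#'   swing-phase integrator.
#' @param event_tol tolerance to which collision events are located.
#' @param max_step_time cap on the swing duration before a no-collision error
#'   is raised (dimensionless time units).
#'
#' @return An object of class `walker_params`.
#' @examples
#' p <- walker_params(k = 0.1456)
#' natural_frequency(p)
#' @export
walker_params <- function(beta = 0.074, k = 0, mu = 0.142,
                          integ_rel_tol = 1e-10, integ_abs_tol = 1e-12,
                          event_tol = 1e-10, max_step_time = 50) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta),
            is.numeric(k), length(k) == 1L, is.finite(k),
            is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (beta <= 0) stop("'beta' must be > 0", call. = FALSE)
  if (k < 0) stop("'k' must be >= 0", call. = FALSE)
  if (mu < 0) stop("'mu' must be >= 0", call. = FALSE)
  if (integ_rel_tol <= 0 || integ_abs_tol <= 0 || event_tol <= 0)
    stop("integration tolerances must be > 0", call. = FALSE)
  if (max_step_time <= 0) stop("'max_step_time' must be > 0", call. = FALSE)
  structure(list(beta = beta, k = k, mu = mu,
                 integ_rel_tol = integ_rel_tol,
                 integ_abs_tol = integ_abs_tol,
                 event_tol = event_tol,
                 max_step_time = max_step_time),
            class = "walker_params")
}

#' @export
print.walker_params <- function(x, ...) {
  cat("Powered simple walking model parameters\n")
  cat(sprintf("  beta = %g   k = %g   mu = %g\n", x$beta, x$k, x$mu))
  cat(sprintf("  integrator rel/abs tol %g/%g, event tol %g, max step time %g\n",
              x$integ_rel_tol, x$integ_abs_tol, x$event_tol, x$max_step_time))
  invisible(x)
}

#' Natural frequency of the swing leg
#'
#' `omega = sqrt(1 + k/beta)`: the small-oscillation frequency of the
#' spring-loaded swing leg, which sets the step frequency of the gait.
#'
#' @param params a [walker_params] object (or anything with `beta` and `k`).
#' @return The dimensionless natural frequency, >= 1.
#' @export
natural_frequency <- function(params) {
  if (!is.numeric(params$beta) || params$beta <= 0)
    stop("'beta' must be > 0", call. = FALSE)
  if (params$k < 0) stop("'k' must be >= 0", call. = FALSE)
  sqrt(1 + params$k / params$beta)
}

as_walker_state <- function(theta, phi, theta_dot, phi_dot) {
  st <- c(theta = unname(theta), phi = unname(phi),
          theta_dot = unname(theta_dot), phi_dot = unname(phi_dot))
  if (!all(is.finite(st))) stop("walker state must be finite", call. = FALSE)
  st
}

#' Reconstruct the full state from a Poincare-section state
#'
#' The Poincare section is taken just after the step-to-step transition, where
#' `phi = theta` and `phi_dot = -theta_dot * cos(2 theta)`, so the 2-D section
#' state `(theta, theta_dot)` determines the full 4-D state.
#'
#' @param theta,theta_dot post-collision stance angle (rad) and angular
#'   velocity (rad per dimensionless time unit); `theta_dot` must be > 0 for
#'   forward walking.
#' @return Named numeric vector `(theta, phi, theta_dot, phi_dot)`.
#' @export
section_to_state <- function(theta, theta_dot) {
  if (!is.finite(theta) || !is.finite(theta_dot))
    stop("section state must be finite", call. = FALSE)
  if (theta_dot <= 0)
    stop("forward walking requires theta_dot > 0", call. = FALSE)
  as_walker_state(theta, theta, theta_dot, -theta_dot * cos(2 * theta))
}
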