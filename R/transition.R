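#' Gravitational impulse and double-support period
#'
#' The double-support period is modelled as inversely proportional to the
#' pre-collision stance angular velocity, `dt_DS = mu / theta_dot_minus`, and
#' the gravitational impulse (gravity integrated over the double support,
#' applied vertically to the hip mass) equals that period.
#'
#' @param theta_dot_pre pre-collision stance angular velocity, > 0.
#' @param mu proportionality constant, >= 0.
#' @return List with `i_gravity` and `dt_ds` (equal by construction).
#' @export
gravity_impulse <- function(theta_dot_pre, mu) {
  if (!is.finite(theta_dot_pre) || theta_dot_pre <= 0)
    stop("'theta_dot_pre' must be > 0 (walker moving forward)", call. = FALSE)
  if (mu < 0) stop("'mu' must be >= 0", call. = FALSE)
  list(i_gravity = mu / theta_dot_pre, dt_ds = mu / theta_dot_pre)
}

#' Step-to-step transition map
#'
#' Applies the instantaneous, perfectly inelastic collision together with the
#' push-off impulse `i_push` (along the trailing leg) and the gravitational
#' impulse `i_gravity` (vertical, on the hip mass) to a pre-collision state
#' satisfying `theta = phi`. Legs swap roles: `theta_plus = -theta_minus`.
#'
#' @param pre full pre-collision state `(theta, phi, theta_dot, phi_dot)` with
#'   `|theta - phi|` within `tol`.
#' @param i_push,i_gravity impulse magnitudes.
#' @param params a [walker_params] object.
#' @param tol collision-condition tolerance (defaults to 100x the event
#'   tolerance to accommodate event-location round-off).
#' @return Named numeric vector: the full post-collision state
#'   `(theta, phi, theta_dot, phi_dot)`.
#' @export
collision_transition <- function(pre, i_push = 0, i_gravity = 0,
                                 params = walker_params(),
                                 tol = 100 * params$event_tol) {
  th <- pre[[1]]; ph <- pre[[2]]; thd <- pre[[3]]
  if (abs(th - ph) > tol)
    stop("pre-collision state does not satisfy the contact condition theta = phi",
         call. = FALSE)
  beta <- params$beta
  D <- 1 + beta * sin(2 * th)^2
  thd_plus <- (cos(2 * th) * thd + sin(2 * th) * i_push - sin(th) * i_gravity) / D
  phd_plus <- (-cos(2 * th)^2 * thd - 0.5 * sin(4 * th) * i_push +
                 sin(th) * cos(2 * th) * i_gravity) / D
  as_walker_state(-th, -th, thd_plus, phd_plus)
}

## push-off that exactly restores theta_dot across the transition
## (optimal push-off hypothesis); linear in i_push, solved in closed form.
.push_off_restoring <- function(theta_pre, theta_dot_pre, i_gravity, beta) {
  D <- 1 + beta * sin(2 * theta_pre)^2
  (theta_dot_pre * (D - cos(2 * theta_pre)) + sin(theta_pre) * i_gravity) /
    sin(2 * theta_pre)
}

#' Optimal push-off impulse of a periodic gait
#'
#' Closed form for the push-off impulse that exactly compensates the collision
#' energy loss of a periodic gait with step length `s` and walking speed `v`:
#' `I_push = s v (s^2 beta - 4 beta - 2) / (s^2 - 4) + mu / (2 v)`.
#'
#' @param s step length, in (0, 1).
#' @param v walking speed, in (0, 1).
#' @param mu double-support constant.
#' @param beta mass ratio.
#' @return The impulse magnitude.
#' @export
optimal_push_off <- function(s, v, mu = 0.142, beta = 0.074) {
  check_gait_range(s, v)
  s * v * (s^2 * beta - 4 * beta - 2) / (s^2 - 4) + mu / (2 * v)
}
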