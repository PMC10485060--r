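#' @importFrom deSolve lsodar ode
NULL

## advance the state over [t0, t0+dt] with no event detection
.advance <- function(y, t0, dt, params) {
  o <- deSolve::lsodar(y, c(t0, t0 + dt), func = "walker_rhs",
                       dllname = "compasswalk", initfunc = "walker_initmod",
                       parms = c(params$beta, params$k),
                       rtol = params$integ_rel_tol, atol = params$integ_abs_tol)
  list(t = unname(o[2, 1]), y = unname(o[2, 2:5]))
}

## integrate from (t0, y) until the named root function fires or tmax
.to_root <- function(y, t0, tmax, params, rootfunc) {
  o <- deSolve::lsodar(y, c(t0, tmax), func = "walker_rhs",
                       dllname = "compasswalk", initfunc = "walker_initmod",
                       parms = c(params$beta, params$k),
                       rtol = params$integ_rel_tol, atol = params$integ_abs_tol,
                       rootfunc = rootfunc, nroot = 1L)
  n <- nrow(o)
  list(t = unname(o[n, 1]), y = unname(o[n, 2:5]), rooted = !is.null(attr(o, "troot")) &&
         length(attr(o, "troot")) > 0)
}

#' Integrate one swing phase to the heel-strike collision
#'
#' Reconstructs the full post-collision state from a section state and
#' integrates the nonlinear dynamics until the swing foot strikes the ground.
#' The contact condition `theta - phi = 0` is also satisfied when the swing
#' leg merely grazes the ground in mid-swing (scuffing); a crossing is
#' accepted as the heel strike only when the stance leg is past vertical
#' (`theta > 0`) and the swing foot is descending
#' (`d(theta - phi)/dt > 0`). All other crossings are recorded in
#' `scuff_times` and ignored.
#'
#' @param theta,theta_dot post-collision section state; `theta_dot > 0`.
#' @param params a [walker_params] object (its `k` is the hip stiffness used).
#' @param n_samples if > 0, the trajectory is additionally sampled on a
#'   uniform grid of this many points over `[0, tau]`.
#' @return An object of class `step_trajectory`: a list with `tau` (step
#'   period), `pre_collision` (full state at heel strike), `scuff_times`,
#'   and, when sampled, `times` and a `states` matrix with columns
#'   `theta, phi, theta_dot, phi_dot`.
#' @examples
#' \donttest{
#' g <- periodic_gait(speed = 0.39, step_length = 0.6)
#' tr <- integrate_swing(g$theta_star, g$theta_dot_star,
#'                       walker_params(k = g$k_star), n_samples = 500)
#' tr$tau
#' }
#' @export
integrate_swing <- function(theta, theta_dot, params = walker_params(),
                            n_samples = 0) {
  y0 <- section_to_state(theta, theta_dot)
  dead_band <- 10 * params$event_tol
  tmax <- params$max_step_time

  ## leave the section: theta - phi = 0 exactly at t = 0
  st <- .advance(y0, 0, 1e-3, params)
  while (abs(st$y[1] - st$y[2]) < dead_band && st$t < tmax) {
    st <- .advance(st$y, st$t, 1e-3, params)
  }

  scuffs <- numeric(0)
  repeat {
    if (st$t >= tmax)
      stop("no collision before max_step_time: not a walking parameter set",
           call. = FALSE)
    r <- .to_root(st$y, st$t, tmax, params, "walker_root_coll")
    if (!r$rooted)
      stop("no collision before max_step_time: not a walking parameter set",
           call. = FALSE)
    dy <- eom_rhs(r$y, params)
    descending <- (dy[[1]] - dy[[2]]) > 0
    if (r$y[1] > 0 && descending) break
    scuffs <- c(scuffs, r$t)
    st <- .advance(r$y, r$t, 1e-3, params)
  }

  out <- list(tau = r$t, pre_collision = as_walker_state(r$y[1], r$y[2],
                                                         r$y[3], r$y[4]),
              scuff_times = scuffs, theta = theta, theta_dot = theta_dot,
              k = params$k)
  if (n_samples > 0) {
    tt <- seq(0, r$t, length.out = n_samples)
    o <- deSolve::ode(y0, tt, func = "walker_rhs", dllname = "compasswalk",
                      initfunc = "walker_initmod",
                      parms = c(params$beta, params$k),
                      rtol = params$integ_rel_tol, atol = params$integ_abs_tol)
    st_mat <- unname(o[, 2:5, drop = FALSE])
    colnames(st_mat) <- c("theta", "phi", "theta_dot", "phi_dot")
    out$times <- tt
    out$states <- st_mat
  }
  class(out) <- "step_trajectory"
  out
}

#' @export
print.step_trajectory <- function(x, ...) {
  cat(sprintf(
    "Swing-phase trajectory: tau = %.6f, %d scuff crossing(s) ignored\n",
    x$tau, length(x$scuff_times)))
  cat(sprintf("  pre-collision state: theta = %.6f, theta_dot = %.6f\n",
              x$pre_collision[[1]], x$pre_collision[[3]]))
  invisible(x)
}

## phi at the first upward crossing of theta = 0 (mid-step symmetry section).
## A periodic gait of the optimal-push-off map is exactly a trajectory that
## passes through theta = phi = 0, so this is the solvers' residual.
.midstep_phi <- function(theta, theta_dot, params) {
  y0 <- section_to_state(theta, theta_dot)
  st <- .advance(y0, 0, 1e-3, params)
  tmax <- params$max_step_time
  repeat {
    if (st$t >= tmax) return(NULL)
    r <- .to_root(st$y, st$t, tmax, params, "walker_root_mid")
    if (!r$rooted) return(NULL)
    if (r$y[3] > 0) return(list(phi = unname(r$y[2]), t_mid = r$t))
    st <- .advance(r$y, r$t, 1e-3, params)
  }
}
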