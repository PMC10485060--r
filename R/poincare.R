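#' Stride-to-stride Poincare map under the optimal push-off hypothesis
#'
#' Maps a post-collision section state to the next one: the swing phase is
#' integrated to heel strike, the gravitational impulse follows the
#' double-support law, and the push-off impulse is chosen so that the
#' collision energy loss is exactly compensated (`theta_dot` is unchanged
#' across the transition). A negative push-off solution is non-physical and is
#' flagged with a warning but still returned.
#'
#' @param theta,theta_dot current section state.
#' @param params a [walker_params] object; `params$k` is the hip stiffness.
#' @return List with the next section state (`theta`, `theta_dot`), the
#'   impulses (`i_push`, `i_gravity`, `dt_ds`), the step period `tau`, the
#'   pre-collision state and scuff times.
#' @export
poincare_map <- function(theta, theta_dot, params = walker_params()) {
  sw <- integrate_swing(theta, theta_dot, params)
  pre <- sw$pre_collision
  gi <- gravity_impulse(pre[[3]], params$mu)
  ip <- .push_off_restoring(pre[[1]], pre[[3]], gi$i_gravity, params$beta)
  if (ip < 0)
    warning("push-off impulse is negative: non-physical push-off at this state",
            call. = FALSE)
  post <- collision_transition(pre, ip, gi$i_gravity, params)
  list(theta = post[[1]], theta_dot = post[[3]],
       i_push = ip, i_gravity = gi$i_gravity, dt_ds = gi$dt_ds,
       tau = sw$tau, pre_collision = pre, scuff_times = sw$scuff_times)
}

## Newton iteration with finite-difference derivative and step damping on the
## mid-step symmetry residual; returns theta or NULL.
.newton_theta <- function(v_target, params, theta0,
                          tol = 1e-11, max_iter = 50L, fd_step = 1e-6) {
  th <- theta0
  r <- tryCatch(.midstep_phi(th, v_target / cos(th), params),
                error = function(e) NULL)
  if (is.null(r)) return(NULL)
  for (it in seq_len(max_iter)) {
    if (abs(r$phi) < tol) return(th)
    r2 <- tryCatch(.midstep_phi(th + fd_step, v_target / cos(th + fd_step),
                                params), error = function(e) NULL)
    if (is.null(r2)) return(NULL)
    d <- (r2$phi - r$phi) / fd_step
    if (!is.finite(d) || d == 0) return(NULL)
    step <- -r$phi / d
    for (half in 0:8) {
      th_new <- max(min(th + step, -1e-4), -0.6)
      r_new <- tryCatch(.midstep_phi(th_new, v_target / cos(th_new), params),
                        error = function(e) NULL)
      if (!is.null(r_new) && abs(r_new$phi) < abs(r$phi)) break
      step <- step / 2
    }
    if (is.null(r_new)) return(NULL)
    th <- th_new; r <- r_new
  }
  if (abs(r$phi) < tol) th else NULL
}

.bracket_theta <- function(v_target, params, lo = -0.6, hi = -0.01,
                           step = 0.005) {
  grid <- seq(hi, lo, by = -step)
  vals <- vapply(grid, function(th) {
    r <- tryCatch(.midstep_phi(th, v_target / cos(th), params),
                  error = function(e) NULL)
    if (is.null(r)) NA_real_ else r$phi
  }, numeric(1))
  ok <- which(!is.na(vals))
  for (j in seq_along(ok)[-1]) {
    i1 <- ok[j - 1]; i2 <- ok[j]
    if (i2 == i1 + 1 && sign(vals[i1]) != sign(vals[i2])) {
      f <- function(th) .midstep_phi(th, v_target / cos(th), params)$phi
      return(stats::uniroot(f, c(grid[i1], grid[i2]), tol = 1e-13)$root)
    }
  }
  NULL
}

#' Fit a periodic gait of the powered walking model
#'
#' Finds a fixed point of the stride-to-stride Poincare map — a periodic gait —
#' either at a given hip-spring stiffness (`speed` + `stiffness`) or at a
#' target gait (`speed` + `step_length`, solving for the unique stiffness
#' `k*`). Periodic gaits of the optimal-push-off map are time-reversal
#' symmetric, so the solver drives the swing-leg angle at the mid-step
#' symmetry section (`theta = 0`) to zero; the Poincare-map defect of the
#' solution is reported as `residual`.
#'
#' @param speed target walking speed `v` in (0, 1) (dimensionless; a treadmill
#'   speed in m/s divided by `sqrt(g)` with `g = 9.81`).
#' @param stiffness hip spring constant `k >= 0`, fixed during the search.
#' @param step_length target step length `s` in (0, 1); when given, the spring
#'   constant is solved for instead.
#' @param params a [walker_params] object; its `k` is overridden by
#'   `stiffness` when that is given.
#' @param init_guess optional starting value for the post-collision stance
#'   angle `theta* < 0`.
#' @param n_samples trajectory samples per step used for the torque maximum.
#' @return An object of class `periodic_gait` with the fixed point
#'   (`theta_star`, `theta_dot_star`, `k_star`), the gait descriptors (`s`,
#'   `v`, `tau`, `omega`), the observables (`T`, `phi_max`, `F`, `b`, `E`,
#'   `i_push`, `i_gravity`, `dt_ds`), the solver `residual`, and the sampled
#'   step trajectory.
#' @examples
#' \donttest{
#' ## the worked example gait: s = 0.6 at v = 0.39
#' g <- periodic_gait(speed = 0.39, step_length = 0.6)
#' coef(g)
#' }
#' @export
periodic_gait <- function(speed, stiffness = NULL, step_length = NULL,
                          params = walker_params(), init_guess = NULL,
                          n_samples = 2000) {
  if (is.null(stiffness) == is.null(step_length))
    stop("give exactly one of 'stiffness' or 'step_length'", call. = FALSE)
  if (!is.finite(speed) || speed <= 0 || speed >= 1)
    stop("'speed' must lie in (0, 1)", call. = FALSE)

  if (!is.null(stiffness)) {
    if (stiffness < 0) stop("'stiffness' must be >= 0", call. = FALSE)
    params$k <- stiffness
    th <- NULL
    if (!is.null(init_guess))
      th <- .newton_theta(speed, params, init_guess)
    if (is.null(th)) {
      ## crude pendulum-style first guess, then a bracketing fallback
      guess <- -asin(min(0.45, 1.6 * speed))
      th <- .newton_theta(speed, params, guess)
    }
    if (is.null(th)) th <- .bracket_theta(speed, params)
    if (is.null(th))
      stop(sprintf("no periodic gait found at v = %g, k = %g", speed,
                   params$k), call. = FALSE)
    k_star <- params$k
  } else {
    check_gait_range(step_length, speed)
    sec <- gait_to_section(step_length, speed)
    th <- sec$theta
    r3 <- function(k) {
      params$k <- k
      r <- tryCatch(.midstep_phi(th, sec$theta_dot, params),
                    error = function(e) NULL)
      if (is.null(r)) NA_real_ else r$phi
    }
    kg <- c(0, 0.01, 0.025, 0.05, 0.1, 0.15, 0.2, 0.3, 0.5, 0.8, 1.2, 2)
    vals <- vapply(kg, r3, numeric(1))
    ok <- which(!is.na(vals))
    br <- NULL
    for (j in seq_along(ok)[-1]) {
      i1 <- ok[j - 1]; i2 <- ok[j]
      if (sign(vals[i1]) != sign(vals[i2])) { br <- c(kg[i1], kg[i2]); break }
    }
    if (is.null(br))
      stop(sprintf("no stiffness admits a periodic gait at s = %g, v = %g",
                   step_length, speed), call. = FALSE)
    k_star <- stats::uniroot(r3, br, tol = 1e-13)$root
    params$k <- k_star
  }

  .build_periodic_gait(th, speed, params, n_samples)
}

.build_periodic_gait <- function(theta_star, v_target, params, n_samples) {
  theta_dot_star <- v_target / cos(theta_star)
  traj <- integrate_swing(theta_star, theta_dot_star, params,
                          n_samples = n_samples)
  pre <- traj$pre_collision
  gi <- gravity_impulse(pre[[3]], params$mu)
  ip <- .push_off_restoring(pre[[1]], pre[[3]], gi$i_gravity, params$beta)
  g <- section_to_gait(theta_star, theta_dot_star)
  tq <- max_flexion_torque(traj, params$k)
  defect <- c(theta = pre[[1]] + theta_star,
              theta_dot = pre[[3]] - theta_dot_star)
  out <- list(theta_star = theta_star, theta_dot_star = theta_dot_star,
              k_star = params$k, s = g$s, v = g$v, tau = traj$tau,
              omega = natural_frequency(params),
              T = tq$T, phi_max = tq$phi_max,
              F = propulsive_force(g$s, g$v, params$mu, ip),
              b = margin_of_stability(g$s, g$v),
              E = mechanical_energy(theta_star, theta_dot_star, params),
              i_push = ip, i_gravity = gi$i_gravity, dt_ds = gi$dt_ds,
              residual = max(abs(defect)), defect = defect,
              scuff_times = traj$scuff_times,
              trajectory = traj, params = params)
  class(out) <- "periodic_gait"
  out
}

#' @export
print.periodic_gait <- function(x, ...) {
  cat("Periodic gait of the powered simple walking model\n")
  cat(sprintf("  s = %.4f  v = %.4f  k* = %.5f  tau = %.4f  (residual %.2e)\n",
              x$s, x$v, x$k_star, x$tau, x$residual))
  cat(sprintf("  T = %.4f  F = %.4f  b = %+.4f  omega = %.4f\n",
              x$T, x$F, x$b, x$omega))
  invisible(x)
}

#' @export
summary.periodic_gait <- function(object, ...) {
  structure(list(gait = object), class = "summary.periodic_gait")
}

#' @export
print.summary.periodic_gait <- function(x, ...) {
  g <- x$gait
  print(g)
  cat(sprintf("  fixed point: theta* = %.6f rad, theta_dot* = %.6f\n",
              g$theta_star, g$theta_dot_star))
  cat(sprintf("  impulses: I_push = %.5f, I_gravity = dt_DS = %.5f\n",
              g$i_push, g$i_gravity))
  cat(sprintf("  energy E = %.6f, max flexion torque at phi_max = %.4f rad\n",
              g$E, g$phi_max))
  cat(sprintf("  %d scuff crossing(s) ignored during the swing\n",
              length(g$scuff_times)))
  invisible(x)
}

#' @export
coef.periodic_gait <- function(object, ...) {
  with(object, c(s = s, v = v, k_star = k_star, tau = tau, omega = omega,
                 T = T, F = F, b = b, E = E, i_push = i_push,
                 i_gravity = i_gravity, theta_star = theta_star,
                 theta_dot_star = theta_dot_star))
}

#' @export
residuals.periodic_gait <- function(object, ...) object$defect

#' @export
as.data.frame.periodic_gait <- function(x, ...) {
  as.data.frame(as.list(coef(x)))
}

#' Re-check a periodic gait through the Poincare map
#'
#' Applies the stride-to-stride map once to the gait's fixed point and returns
#' the defect `f(q*) - q*`, a direct verification of periodicity.
#'
#' @param gait a [periodic_gait] object.
#' @return Named numeric vector with the `theta` and `theta_dot` defects.
#' @export
gait_defect <- function(gait) {
  m <- poincare_map(gait$theta_star, gait$theta_dot_star, gait$params)
  c(theta = m$theta - gait$theta_star,
    theta_dot = m$theta_dot - gait$theta_dot_star)
}

#' @export
#' @importFrom stats simulate
#' @method simulate periodic_gait
#' @param object a [periodic_gait] object.
#' @param nsim number of steps to roll out.
#' @param seed ignored (the map is deterministic); present for the generic.
#' @param perturb optional numeric of length 2 added to the initial section
#'   state `(theta, theta_dot)`.
#' @param ... unused.
#' @rdname periodic_gait
simulate.periodic_gait <- function(object, nsim = 5, seed = NULL,
                                   perturb = c(0, 0), ...) {
  th <- object$theta_star + perturb[1]
  thd <- object$theta_dot_star + perturb[2]
  rows <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    m <- poincare_map(th, thd, object$params)
    rows[[i]] <- data.frame(step = i, theta = th, theta_dot = thd,
                            tau = m$tau, i_push = m$i_push,
                            i_gravity = m$i_gravity)
    th <- m$theta; thd <- m$theta_dot
  }
  do.call(rbind, rows)
}

#' @export
#' @importFrom graphics plot lines abline par mtext
#' @method plot periodic_gait
#' @rdname periodic_gait
#' @param x a [periodic_gait] object.
plot.periodic_gait <- function(x, ...) {
  tr <- x$trajectory
  if (is.null(tr$states)) stop("gait has no sampled trajectory", call. = FALSE)
  phi <- tr$states[, "phi"]; k <- x$k_star
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(-phi, -k * phi, type = "l", xlab = "hip extension angle -phi (rad)",
       ylab = "hip torque -k phi", main = "torque vs angle")
  abline(h = 0, col = "grey70")
  pct <- 100 * tr$times / x$tau
  plot(pct, -k * phi, type = "l", xlab = "gait cycle (%)",
       ylab = "hip torque -k phi", main = "torque over the step")
  abline(h = 0, col = "grey70")
  invisible(x)
}
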