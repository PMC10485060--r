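#' The six nominal treadmill belt speeds, nondimensionalized
#'
#' Belt speeds 0.50 to 1.75 m/s in 0.25 m/s steps, divided by `sqrt(g)` with
#' `g = 9.81` (the convention implies a 1 m length scale).
#'
#' @param speeds_ms belt speeds in m/s.
#' @return Dimensionless walking speeds.
#' @export
nominal_speeds <- function(speeds_ms = seq(0.5, 1.75, by = 0.25)) {
  speeds_ms / sqrt(9.81)
}

#' Stiffness sweep at constant walking speed
#'
#' Fits a periodic gait at each spring constant of `k_grid` while holding the
#' walking speed fixed, using each converged fixed point to seed the next grid
#' point (continuation). Grid points with no converged gait are recorded in
#' `failures`.
#'
#' @param v_target walking speed in (0, 1).
#' @param k_grid increasing vector of spring constants (default 0 to 0.30 in
#'   steps of 0.005, covering the experimentally observed quasi-stiffness
#'   range).
#' @param params a [walker_params] object.
#' @param n_samples trajectory samples per gait for the torque maximum.
#' @return An object of class `stiffness_sweep`: list with `v_target`,
#'   `gaits` (list of [periodic_gait]), `failures` (k values), and a tidy
#'   `data.frame` of all gait observables under `$table`.
#' @export
sweep_stiffness <- function(v_target, k_grid = seq(0, 0.30, by = 0.005),
                            params = walker_params(), n_samples = 2000) {
  if (is.unsorted(k_grid, strictly = TRUE))
    stop("'k_grid' must be strictly increasing", call. = FALSE)
  gaits <- list(); failures <- numeric(0)
  guess <- NULL
  for (k in k_grid) {
    g <- tryCatch(
      periodic_gait(v_target, stiffness = k, params = params,
                    init_guess = guess, n_samples = n_samples),
      error = function(e) NULL)
    if (is.null(g)) {
      failures <- c(failures, k)
    } else {
      gaits[[length(gaits) + 1L]] <- g
      guess <- g$theta_star
    }
  }
  if (length(gaits) == 0)
    stop(sprintf("stiffness sweep failed at every grid point (v = %g)",
                 v_target), call. = FALSE)
  tab <- do.call(rbind, lapply(gaits, as.data.frame))
  out <- list(v_target = v_target, k_grid = k_grid, gaits = gaits,
              failures = failures, table = tab)
  class(out) <- "stiffness_sweep"
  out
}

#' @export
print.stiffness_sweep <- function(x, ...) {
  cat(sprintf("Stiffness sweep at v = %.4f: %d/%d gaits converged\n",
              x$v_target, length(x$gaits), length(x$k_grid)))
  rng <- range(x$table$k_star)
  cat(sprintf("  k in [%.3f, %.3f]; s %.3f -> %.3f; T %.4f -> %.4f\n",
              rng[1], rng[2], x$table$s[1], x$table$s[nrow(x$table)],
              x$table$T[1], x$table$T[nrow(x$table)]))
  invisible(x)
}

#' @export
as.data.frame.stiffness_sweep <- function(x, ...) x$table

#' @export
#' @importFrom graphics matplot
#' @method plot stiffness_sweep
plot.stiffness_sweep <- function(x, ...) {
  tab <- x$table
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 1.5, 1))
  on.exit(par(op))
  for (var in c("T", "F", "b", "s"))
    plot(tab$k_star, tab[[var]], type = "l", xlab = "k", ylab = var)
  invisible(x)
}

#' Swing-tuning relations over a collection of gaits
#'
#' Verifies the two tuning relations of the spring-loaded swing leg: the
#' natural frequency is proportional to the step frequency
#' (`omega` regressed on `1/tau` through the origin), and the step period is
#' approximated by step length over walking speed (`tau ~ s/v`). The fit uses
#' the uncentered coefficient of determination appropriate for a
#' through-origin regression.
#'
#' @param gaits a list of [periodic_gait] objects (or a [sweep_stiffness]
#'   result, whose gaits are used), at least 3, spanning distinct stiffness.
#' @return List with `slope` and `r_squared` of the origin-constrained
#'   `omega` vs `1/tau` fit, and `tau_rel_dev`, the per-gait relative
#'   deviations `|tau - s/v| / tau` (with `median_tau_rel_dev`).
#' @export
tuning_relations <- function(gaits) {
  if (inherits(gaits, "stiffness_sweep")) gaits <- gaits$gaits
  if (length(gaits) < 3)
    stop("need at least 3 converged gaits", call. = FALSE)
  tab <- do.call(rbind, lapply(gaits, as.data.frame))
  x <- 1 / tab$tau; y <- tab$omega
  slope <- sum(x * y) / sum(x^2)
  r2 <- 1 - sum((y - slope * x)^2) / sum(y^2)
  dev <- abs(tab$tau - tab$s / tab$v) / tab$tau
  list(slope = slope, r_squared = r2, tau_rel_dev = dev,
       median_tau_rel_dev = stats::median(dev))
}
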