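G_ACC <- 9.81

#' Construct a motion-capture trial
#'
#' Container for one treadmill walking trial: kinematic channels (heel/toe
#' marker X positions per side, CoM X/Y position, hip angle and torque per
#' side) and two-plate ground-reaction-force channels, with subject metadata.
#' Hip angles are extension-positive (rad); hip torques flexion-positive
#' (N m); GRF in N with Y vertical and X anterior.
#'
#' @param kin data.frame with columns `time`, `heel_x_L`, `heel_x_R`,
#'   `toe_x_L`, `toe_x_R`, `com_x`, `com_y`, `hip_angle_L`, `hip_angle_R`,
#'   `hip_torque_L`, `hip_torque_R`.
#' @param grf data.frame with columns `time`, `grf_x_L`, `grf_y_L`,
#'   `grf_x_R`, `grf_y_R`.
#' @param meta list with at least `subject_mass` (kg), `kinematic_rate` and
#'   `grf_rate` (Hz), `belt_speed_nominal` (m/s); optionally `belt_scale`,
#'   `subject_id`, `speed_label`.
#' @param truth optional ground-truth list (synthetic trials).
#' @return An object of class `mocap_trial`.
#' @export
mocap_trial <- function(kin, grf, meta, truth = NULL) {
  kin_cols <- c("time", "heel_x_L", "heel_x_R", "toe_x_L", "toe_x_R",
                "com_x", "com_y", "hip_angle_L", "hip_angle_R",
                "hip_torque_L", "hip_torque_R")
  grf_cols <- c("time", "grf_x_L", "grf_y_L", "grf_x_R", "grf_y_R")
  miss <- setdiff(kin_cols, names(kin))
  if (length(miss))
    stop("kinematic table is missing channels: ", paste(miss, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(grf_cols, names(grf))
  if (length(miss))
    stop("GRF table is missing channels: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (f in c("subject_mass", "kinematic_rate", "grf_rate"))
    if (is.null(meta[[f]])) stop("metadata field missing: ", f, call. = FALSE)
  structure(list(kin = kin[kin_cols], grf = grf[grf_cols], meta = meta,
                 truth = truth), class = "mocap_trial")
}

#' @export
print.mocap_trial <- function(x, ...) {
  cat(sprintf(
    "Motion-capture trial: %.1f s at %g/%g Hz, subject %.1f kg, belt %s m/s%s\n",
    max(x$kin$time), x$meta$kinematic_rate, x$meta$grf_rate,
    x$meta$subject_mass,
    if (is.null(x$meta$belt_speed_nominal)) "?" else
      format(x$meta$belt_speed_nominal),
    if (is.null(x$truth)) "" else " (synthetic, ground truth attached)"))
  invisible(x)
}

## linear interpolation of a channel at arbitrary times
.ch_at <- function(time, x, t) stats::approx(time, x, xout = t, rule = 2)$y

#' Per-step analysis of a treadmill trial
#'
#' Runs the full measurement chain: zero-lag filtering (6 Hz kinematics,
#' 18 Hz GRF), gait-event detection on the vertical GRF, and per-step
#' computation of the experimental gait quantities. Velocities are centred
#' finite differences of the filtered positions; the treadmill belt motion is
#' removed by subtracting the trailing-foot toe-marker velocity at heel
#' strike. Step length and CoM height give the reconstructed leg length by
#' Pythagoras (the CoM projection is assumed to bisect the step), and all
#' quantities are nondimensionalized with the stated denominators.
#'
#' @param trial a [mocap_trial].
#' @param last_n number of final steps to keep (the preceding steps are
#'   treated as acclimatization).
#' @param kin_cutoff,grf_cutoff filter cut-offs, Hz.
#' @param floor zero-force floor passed to [detect_gait_events].
#' @return A data.frame of class `step_metrics`, one row per step:
#'   `side`, `t_hs`, `tau_expt`, `l_expt`, `l_c_h`, `s_expt`, `v_expt`, `v_y`,
#'   `theta_minus_expt`, `theta_dot_minus_expt`, `dt_ds_expt`, `x_expt`,
#'   `xi_expt`, `u_expt`, `b_expt`, `k_expt`, `r2_k`, `T_expt`, `F_expt`,
#'   plus `speed_label` and `subject_id` copied from the metadata.
#' @export
analyze_trial <- function(trial, last_n = 30, kin_cutoff = 6,
                          grf_cutoff = 18, floor = 0) {
  stopifnot(inherits(trial, "mocap_trial"))
  kr <- trial$meta$kinematic_rate; gr <- trial$meta$grf_rate
  M <- trial$meta$subject_mass

  kin <- trial$kin
  kinf <- kin
  for (nm in setdiff(names(kin), "time"))
    kinf[[nm]] <- zero_lag_lowpass(kin[[nm]], kr, kin_cutoff)
  grf <- trial$grf
  grff <- grf
  for (nm in setdiff(names(grf), "time"))
    grff[[nm]] <- zero_lag_lowpass(grf[[nm]], gr, grf_cutoff)

  ev_L <- detect_gait_events(grff$grf_y_L, gr, floor = floor)
  ev_R <- detect_gait_events(grff$grf_y_R, gr, floor = floor)
  ## event indices are relative to the grf time axis
  t0g <- grf$time[1]
  ev_L$hs_times <- ev_L$hs_times + t0g; ev_L$to_times <- ev_L$to_times + t0g
  ev_R$hs_times <- ev_R$hs_times + t0g; ev_R$to_times <- ev_R$to_times + t0g
  steps <- build_steps(ev_L, ev_R, last_n = last_n)

  tt <- kinf$time
  vel <- lapply(kinf[setdiff(names(kinf), "time")], finite_diff, rate = kr)

  rows <- lapply(seq_len(nrow(steps)), function(i) {
    st <- steps[i, ]
    lead <- st$side; trail <- if (lead == "L") "R" else "L"
    t_hs <- st$t_hs

    heel_lead <- .ch_at(tt, kinf[[paste0("heel_x_", lead)]], t_hs)
    heel_trail <- .ch_at(tt, kinf[[paste0("heel_x_", trail)]], t_hs)
    L_step <- heel_lead - heel_trail
    h_com <- .ch_at(tt, kinf$com_y, t_hs)
    com_x <- .ch_at(tt, kinf$com_x, t_hs)
    if (L_step <= 0) return(NULL)
    l_expt <- sqrt(h_com^2 + (L_step / 2)^2)
    s_expt <- L_step / l_expt
    if (s_expt / 2 > 1) stop("step geometry error: s/2 > 1", call. = FALSE)

    v_com <- .ch_at(tt, vel$com_x, t_hs)
    v_toe <- .ch_at(tt, vel[[paste0("toe_x_", trail)]], t_hs)
    v_rel <- v_com - v_toe                      # belt-corrected, m/s
    v_expt <- v_rel / sqrt(G_ACC * l_expt)
    v_y <- .ch_at(tt, vel$com_y, t_hs) / sqrt(G_ACC * l_expt)
    th_m <- asin(s_expt / 2)
    thd_m <- v_expt * cos(th_m) - v_y * sin(th_m)
    dt_ds <- (st$t_to_trailing - t_hs) / sqrt(l_expt / G_ACC)
    tau_expt <- (t_hs - st$t_prev_hs) / sqrt(l_expt / G_ACC)

    ## margin of stability, nondimensionalized by the CoM-to-heel distance
    l_c_h <- sqrt((heel_lead - com_x)^2 + h_com^2)
    if (l_c_h <= 0) stop("step geometry error: zero CoM-to-heel distance",
                         call. = FALSE)
    u_expt <- heel_lead / l_c_h
    x_expt <- com_x / l_c_h
    xd_expt <- v_rel / sqrt(G_ACC * l_c_h)
    xi_expt <- x_expt + xd_expt
    b_expt <- u_expt - xi_expt

    ## hip quasi-stiffness of the swinging (trailing) leg
    qs <- fit_quasi_stiffness(
      angle = kinf[[paste0("hip_angle_", trail)]],
      torque = kinf[[paste0("hip_torque_", trail)]] / (M * G_ACC * l_expt),
      time = tt, t_preswing = c(t_hs, st$t_to_trailing),
      t_swing_end = st$t_next_hs)

    ## peak outcomes over the step window
    in_step_k <- tt >= t_hs & tt < st$t_next_hs
    T_expt <- max(kinf[[paste0("hip_torque_", trail)]][in_step_k]) /
      (M * G_ACC * l_expt)
    in_step_g <- grf$time >= t_hs & grf$time < st$t_next_hs
    F_expt <- max(grff[[paste0("grf_x_", trail)]][in_step_g]) / (M * G_ACC)

    data.frame(side = lead, t_hs = t_hs, tau_expt = tau_expt,
               l_expt = l_expt, l_c_h = l_c_h, s_expt = s_expt,
               v_expt = v_expt, v_y = v_y, theta_minus_expt = th_m,
               theta_dot_minus_expt = thd_m, dt_ds_expt = dt_ds,
               x_expt = x_expt, xi_expt = xi_expt, u_expt = u_expt,
               b_expt = b_expt, k_expt = qs$k_expt, r2_k = qs$r2_k,
               T_expt = T_expt, F_expt = F_expt)
  })
  out <- do.call(rbind, rows)
  out$speed_label <- trial$meta$speed_label %||% trial$meta$belt_speed_nominal
  out$subject_id <- trial$meta$subject_id %||% NA_character_
  class(out) <- c("step_metrics", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hip quasi-stiffness of one swing
#'
#' Slope of the linear fit of hip torque against hip angle over the window
#' from the maximum hip extension during pre-swing (contralateral heel strike
#' to ipsilateral toe-off) to the end of the swing phase. The angle channel is
#' extension-positive and the torque channel flexion-positive, so a restoring
#' hip spring appears as a positive slope; the magnitude is reported.
#'
#' @param angle hip angle channel (rad, extension-positive), filtered.
#' @param torque hip torque channel, nondimensionalized by `M g l`, filtered.
#' @param time kinematic time axis (s).
#' @param t_preswing length-2 numeric: the pre-swing window (contralateral
#'   heel strike, ipsilateral toe-off).
#' @param t_swing_end time of the next ipsilateral heel strike.
#' @param min_frames minimum window length.
#' @return List with `k_expt` and `r2_k`.
#' @export
fit_quasi_stiffness <- function(angle, torque, time, t_preswing, t_swing_end,
                                min_frames = 10) {
  pre <- which(time >= t_preswing[1] & time <= t_preswing[2])
  if (length(pre) < 2) stop("empty pre-swing window", call. = FALSE)
  i_start <- pre[which.max(angle[pre])]
  i_end <- max(which(time < t_swing_end))
  idx <- i_start:i_end
  if (length(idx) < min_frames)
    stop("quasi-stiffness window shorter than ", min_frames, " frames",
         call. = FALSE)
  fit <- stats::lm(torque[idx] ~ angle[idx])
  y <- torque[idx]
  r2 <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
  list(k_expt = abs(unname(coef(fit)[2])), r2_k = r2)
}

#' Double-support regression
#'
#' Tests the inverse-proportionality law of the double-support period: fits
#' `theta_dot_minus = mu / dt_DS` by least squares without intercept
#' (explanatory variable `1/dt_DS`) and reports the proportionality constant
#' and the coefficient of determination `1 - SS_res/SS_tot`.
#'
#' @param records a `step_metrics` data.frame (needs `theta_dot_minus_expt`
#'   and `dt_ds_expt`), or any data.frame with those columns.
#' @param min_steps minimum number of steps required.
#' @return An object of class `ds_fit`: list with `mu_expt`, `r2`, `n`.
#' @export
fit_double_support <- function(records, min_steps = 10) {
  y <- records$theta_dot_minus_expt
  x <- 1 / records$dt_ds_expt
  ok <- is.finite(x) & is.finite(y) & records$dt_ds_expt > 0
  x <- x[ok]; y <- y[ok]
  if (length(y) < min_steps)
    stop("need at least ", min_steps, " steps for the double-support regression",
         call. = FALSE)
  if (stats::sd(y) == 0 || stats::sd(x) == 0)
    stop("degenerate variance in the double-support regression", call. = FALSE)
  mu <- sum(x * y) / sum(x^2)
  r2 <- 1 - sum((y - mu * x)^2) / sum((y - mean(y))^2)
  structure(list(mu_expt = mu, r2 = r2, n = length(y)), class = "ds_fit")
}

#' @export
print.ds_fit <- function(x, ...) {
  cat(sprintf("Double-support law fit: mu_expt = %.4f, R^2 = %.4f (n = %d steps)\n",
              x$mu_expt, x$r2, x$n))
  invisible(x)
}
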