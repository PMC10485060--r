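#' Configuration of the synthetic-trial generator
#'
#' Defines one synthetic treadmill trial driven by a periodic gait of the
#' walking model. The defaults emulate the measurement protocol of the
#' treadmill study: nominal belt speeds 0.50-1.75 m/s scaled by the square
#' root of the leg length, 200/1000 Hz kinematic/GRF rates, 35 strides per
#' side, and a hip quasi-stiffness that rises with speed.
#'
#' @param nominal_speed nominal belt speed, m/s.
#' @param k_true hip spring stiffness used for the torque-angle coupling; the
#'   default interpolates the speed-dependent values observed in treadmill
#'   walking (0.08 at 0.50 m/s up to 0.16 at 1.75 m/s).
#' @param mu_true double-support law constant.
#' @param leg_length leg length, m.
#' @param subject_mass subject mass, kg.
#' @param belt_scale multiplier on the nominal speed (defaults to
#'   `sqrt(leg_length)`, the leg-length scaling of the protocol).
#' @param n_strides strides per side (>= 32 so that 30 steps remain after
#'   acclimatization).
#' @param noise list of additive measurement-noise scales: `marker` (m),
#'   `angle` (rad), `grf` (N), `torque_frac` (hip-torque AR(1) noise as a
#'   fraction of the swing torque scale) and `torque_rho` (AR(1) coefficient
#'   at the kinematic rate). Set the scales to 0 for a noiseless trial.
#' @param jitter list of stride-to-stride coefficient-of-variation values for
#'   step length (`s_cv`) and heel-strike speed (`v_cv`).
#' @param kinematic_rate,grf_rate sampling rates, Hz.
#' @param seed RNG seed; the same seed reproduces the trial exactly.
#' @param subject_id,speed_label optional labels carried into the metadata.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(nominal_speed = 1.25, k_true = NULL,
                             mu_true = 0.142, leg_length = 0.96,
                             subject_mass = 58.8,
                             belt_scale = sqrt(leg_length),
                             n_strides = 35,
                             noise = list(marker = 0.001, angle = 0.002,
                                          grf = 2, torque_frac = 0.9,
                                          torque_rho = 0.85),
                             jitter = list(s_cv = 0.02, v_cv = 0.015),
                             kinematic_rate = 200, grf_rate = 1000,
                             seed = 1, subject_id = "S01",
                             speed_label = nominal_speed) {
  if (is.null(k_true))
    k_true <- stats::approx(seq(0.5, 1.75, by = 0.25),
                            c(0.08, 0.10, 0.12, 0.14, 0.15, 0.16),
                            xout = nominal_speed, rule = 2)$y
  if (n_strides < 32)
    stop("'n_strides' must be >= 32 to leave 30 analysable steps", call. = FALSE)
  noise <- utils::modifyList(list(marker = 0.001, angle = 0.002, grf = 2,
                                  torque_frac = 0.9, torque_rho = 0.85), noise)
  jitter <- utils::modifyList(list(s_cv = 0.02, v_cv = 0.015), jitter)
  structure(list(nominal_speed = nominal_speed, k_true = k_true,
                 mu_true = mu_true, leg_length = leg_length,
                 subject_mass = subject_mass, belt_scale = belt_scale,
                 n_strides = n_strides, noise = noise, jitter = jitter,
                 kinematic_rate = kinematic_rate, grf_rate = grf_rate,
                 seed = seed, subject_id = subject_id,
                 speed_label = speed_label), class = "synthetic_config")
}

## cubic Hermite segment evaluated at times t in [a, b]
.hermite <- function(t, a, b, ya, yb, da, db) {
  h <- b - a
  u <- (t - a) / h
  u2 <- u * u; u3 <- u2 * u
  ya * (2 * u3 - 3 * u2 + 1) + yb * (-2 * u3 + 3 * u2) +
    da * h * (u3 - 2 * u2 + u) + db * h * (u3 - u2)
}

## Piecewise single-harmonic track through (t_nodes, x_nodes) with prescribed
## node velocities: on each interval the velocity is
## m + (A (1-u) + A' u) cos(2 pi u), integrated in closed form, so the
## waveform's energy sits at the stride fundamental.
.harmonic_track <- function(tt, t_nodes, x_nodes, v_nodes) {
  n <- length(t_nodes)
  out <- rep(NA_real_, length(tt))
  for (i in 1:(n - 1)) {
    a <- t_nodes[i]; b <- t_nodes[i + 1]; Tl <- b - a
    inb <- which(tt >= a & tt < b)
    if (!length(inb)) next
    u <- (tt[inb] - a) / Tl
    m <- (x_nodes[i + 1] - x_nodes[i]) / Tl
    A <- v_nodes[i] - m; A2 <- v_nodes[i + 1] - m
    I1 <- sin(2 * pi * u) / (2 * pi)
    I2 <- u * sin(2 * pi * u) / (2 * pi) + (cos(2 * pi * u) - 1) / (4 * pi^2)
    out[inb] <- x_nodes[i] + m * Tl * u + Tl * (A * (I1 - I2) + A2 * I2)
  }
  pre <- tt < t_nodes[1]
  out[pre] <- x_nodes[1] + v_nodes[1] * (tt[pre] - t_nodes[1])
  post <- tt >= t_nodes[n]
  out[post] <- x_nodes[n] + v_nodes[n] * (tt[post] - t_nodes[n])
  out
}

## double-hump vertical GRF stance shape on u in [0, 1]
.grf_y_shape <- function(u) {
  ramp <- function(z) { z <- pmin(pmax(z, 0), 1); z * z * (3 - 2 * z) }
  base <- exp(-((u - 0.28) / 0.16)^2) + exp(-((u - 0.72) / 0.16)^2) +
    0.55 * exp(-((u - 0.5) / 0.22)^2)
  base * ramp(u / 0.05) * ramp((1 - u) / 0.05)
}

## detection offsets of the filtered event chain for a stance pulse of the
## given duration: the generator shifts its force onsets so that the
## documented detection chain recovers the intended contact times.
.calibrate_grf_offsets <- function(stance_dur, amp, grf_rate, grf_cutoff = 18) {
  pad <- 0.6
  tt <- seq(0, stance_dur + 2 * pad, by = 1 / grf_rate)
  off <- c(on = 0, off = 0)
  for (it in 1:3) {
    a <- pad + off["on"]; b <- pad + stance_dur - off["off"]
    y <- numeric(length(tt))
    inb <- tt >= a & tt <= b
    y[inb] <- amp * .grf_y_shape((tt[inb] - a) / (b - a))
    yf <- zero_lag_lowpass(y, grf_rate, grf_cutoff)
    ev <- detect_gait_events(yf, grf_rate)
    if (length(ev$hs_times) < 1 || length(ev$to_times) < 1) break
    off <- off + c(on = pad - ev$hs_times[1],
                   off = ev$to_times[1] - (pad + stance_dur))
  }
  off
}

#' Generate a synthetic motion-capture trial from the walking model
#'
#' Solves the periodic gait at the configured dimensionless speed and
#' stiffness, rolls its limit cycle into continuous treadmill-frame marker,
#' CoM, hip and ground-reaction-force channels with stride-to-stride jitter,
#' and adds measurement noise. The double-support overlap of the two vertical
#' GRF channels follows the inverse law `dt_DS = mu_true / theta_dot_minus`
#' stride by stride, the hip torque equals `-k_true * phi` over each swing
#' (plus a stance-phase deviation outside the quasi-stiffness window), and
#' the anterior GRF carries a push-off peak scaled to the model's propulsive
#' force. Per-stride ground truth is stored alongside the channels.
#'
#' @param config a [synthetic_config].
#' @return A [mocap_trial] whose `truth` field holds the per-step truth table
#'   and the generating gait.
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  l <- config$leg_length; M <- config$subject_mass
  tu <- sqrt(l / G_ACC)                      # time unit, s
  vu <- sqrt(G_ACC * l)                      # speed unit, m/s
  v_belt_ms <- config$nominal_speed * config$belt_scale
  v_dim <- v_belt_ms / vu
  params <- walker_params(k = config$k_true, mu = config$mu_true)
  gait <- periodic_gait(v_dim, stiffness = config$k_true, params = params)

  ## base limit-cycle trajectories on normalized step time u in [0, 1]
  base_u <- gait$trajectory$times / gait$tau
  th_fun <- stats::approxfun(base_u, gait$trajectory$states[, "theta"])
  ph_fun <- stats::approxfun(base_u, gait$trajectory$states[, "phi"])

  ## per-step truth with stride-to-stride jitter (L strikes first)
  n_steps <- 2L * config$n_strides
  s_i <- gait$s * exp(rnorm(n_steps, 0, config$jitter$s_cv))
  v_i <- v_dim * exp(rnorm(n_steps, 0, config$jitter$v_cv))
  s_i <- pmin(pmax(s_i, 0.05), 0.995)
  v_i <- pmin(v_i, 0.995)
  th_m <- asin(s_i / 2)                      # theta_minus per step, > 0
  thd_m <- v_i / cos(th_m)
  dt_ds <- config$mu_true / thd_m            # dimensionless double support
  tau_i <- gait$tau * (s_i / gait$s) / (v_i / v_dim)
  F_i <- vapply(seq_len(n_steps), function(i)
    propulsive_force(s_i[i], v_i[i], config$mu_true,
                     optimal_push_off(s_i[i], v_i[i], config$mu_true,
                                      params$beta)), numeric(1))

  pad <- 1.5
  t_hs <- pad + c(0, cumsum(tau_i[-n_steps] * tu))
  sides <- rep(c("L", "R"), length.out = n_steps)
  dt_s <- dt_ds * tu                         # dimensional double support
  total <- t_hs[n_steps] + 1.2 + pad

  ## heel placements in the treadmill frame
  L_i <- s_i * l
  vb <- sum(L_i[-1]) / (t_hs[n_steps] - t_hs[1])
  p <- numeric(n_steps)
  p[1] <- 0.3
  for (i in 2:n_steps)
    p[i] <- p[i - 1] - vb * (t_hs[i] - t_hs[i - 1]) + L_i[i]

  tk <- seq(0, total, by = 1 / config$kinematic_rate)
  tg <- seq(0, total, by = 1 / config$grf_rate)
  nk <- length(tk)

  ## ---- heel and toe markers ------------------------------------------------
  heel <- list(L = numeric(nk), R = numeric(nk))
  stance_end <- c(t_hs[-1] + dt_s[-1], t_hs[n_steps] + 0.75 * tau_i[n_steps] * tu)
  for (side in c("L", "R")) {
    idx <- which(sides == side)
    x <- rep(NA_real_, nk)
    for (j in seq_along(idx)) {
      i <- idx[j]
      ## stance: linear backward motion at belt speed
      in_st <- tk >= t_hs[i] & tk <= stance_end[i]
      x[in_st] <- p[i] - vb * (tk[in_st] - t_hs[i])
      ## swing to the next ipsilateral strike; the marker dwells briefly
      ## after toe-off so the fast swing motion stays clear of the filter
      ## window around the contralateral heel strike
      if (j < length(idx)) {
        i2 <- idx[j + 1]
        a <- stance_end[i]; b <- t_hs[i2]
        a2 <- a + 0.18 * (b - a)
        in_dw <- tk > a & tk < a2
        x[in_dw] <- p[i] - vb * (tk[in_dw] - t_hs[i])
        in_sw <- tk >= a2 & tk < b
        x[in_sw] <- .hermite(tk[in_sw], a2, b, p[i] - vb * (a2 - t_hs[i]),
                             p[i2], -vb, -vb)
      }
    }
    i1 <- idx[1]; iN <- idx[length(idx)]
    pre <- tk < t_hs[i1]
    x[pre] <- p[i1] - vb * (tk[pre] - t_hs[i1])
    x[is.na(x)] <- p[iN] - vb * (stance_end[iN] - t_hs[iN])
    heel[[side]] <- x
  }

  ## ---- CoM ------------------------------------------------------------------
  ## Both CoM channels are built as single-harmonic waveforms per step: the
  ## velocity is mean + (blended amplitude) * cos(2 pi u), which meets the
  ## per-stride position and velocity constraints at every heel strike while
  ## keeping the spectrum at the step frequency, well below the 6 Hz
  ## kinematic filter cut-off.
  cx <- p - L_i / 2
  cv <- v_i * vu - vb
  com_x <- .harmonic_track(tk, t_hs, cx, cv)
  h_i <- l * cos(th_m)
  vy_pre <- -thd_m * sin(th_m) * vu
  com_y <- .harmonic_track(tk, t_hs, h_i, vy_pre)

  ## ---- hip angle and torque -------------------------------------------------
  ang <- list(L = rep(NA_real_, nk), R = rep(NA_real_, nk))
  scale_i <- th_m / (-gait$theta_star)
  for (i in 1:(n_steps - 1)) {
    inb <- tk >= t_hs[i] & tk < t_hs[i + 1]
    u <- (tk[inb] - t_hs[i]) / (t_hs[i + 1] - t_hs[i])
    sc <- (1 - u) * scale_i[i] + u * scale_i[i + 1]
    lead <- sides[i]; trail <- if (lead == "L") "R" else "L"
    ang[[lead]][inb] <- th_fun(u) * sc
    ang[[trail]][inb] <- -ph_fun(u) * sc
  }
  for (side in c("L", "R")) {
    x <- ang[[side]]
    first <- which(!is.na(x))[1]
    if (first > 1) x[seq_len(first - 1)] <- x[first]
    last <- max(which(!is.na(x)))
    x[is.na(x)] <- x[last]
    ang[[side]] <- x
  }

  trq <- list(L = ang$L * config$k_true * M * G_ACC * l,
              R = ang$R * config$k_true * M * G_ACC * l)
  ## stance-phase torque deviation (outside the quasi-stiffness window)
  ramp <- function(z) { z <- pmin(pmax(z, 0), 1); z * z * (3 - 2 * z) }
  A_dev <- 0.45 * config$k_true * (-gait$theta_star) * M * G_ACC * l
  for (i in 1:(n_steps - 1)) {
    inb <- which(tk >= t_hs[i] & tk < t_hs[i + 1])
    u <- (tk[inb] - t_hs[i]) / (t_hs[i + 1] - t_hs[i])
    dev <- -A_dev * exp(-((u - 0.3) / 0.15)^2) *
      ramp(u / 0.08) * ramp((0.92 - u) / 0.08)
    lead <- sides[i]
    trq[[lead]][inb] <- trq[[lead]][inb] + dev
  }

  ## per-step torque truth: peak flexion torque of the swinging leg
  T_i <- vapply(1:(n_steps - 1), function(i) {
    inb <- tk >= t_hs[i] & tk < t_hs[i + 1]
    trail <- if (sides[i] == "L") "R" else "L"
    max(ang[[trail]][inb]) * config$k_true
  }, numeric(1))
  T_i <- c(T_i, NA_real_)

  ## ---- ground reaction forces ----------------------------------------------
  grf_y <- list(L = numeric(length(tg)), R = numeric(length(tg)))
  grf_x <- list(L = numeric(length(tg)), R = numeric(length(tg)))
  amp_y <- 1.12 * M * G_ACC
  mean_stance <- mean(stance_end[1:(n_steps - 1)] - t_hs[1:(n_steps - 1)])
  off <- .calibrate_grf_offsets(mean_stance, amp_y, config$grf_rate)
  for (i in seq_len(n_steps)) {
    side <- sides[i]
    a <- t_hs[i] + off["on"]; b <- stance_end[i] - off["off"]
    inb <- which(tg >= a & tg <= b)
    u <- (tg[inb] - a) / (b - a)
    grf_y[[side]][inb] <- grf_y[[side]][inb] + amp_y * .grf_y_shape(u)
    ## anterior GRF: braking lobe early, propulsion peak in late stance,
    ## scaled to the model's propulsive force of the *next* step
    F_amp <- if (i < n_steps) F_i[i + 1] * M * G_ACC else 0
    if (F_amp > 0) {
      d_next <- dt_s[i + 1]
      t_peak <- t_hs[i + 1] + 0.45 * d_next
      u_peak <- (t_peak - a) / (b - a)
      sig_p <- 0.45 * d_next / (b - a)
      shape <- -0.7 * exp(-((u - 0.16) / 0.10)^2) +
        exp(-((u - u_peak) / sig_p)^2)
      grf_x[[side]][inb] <- grf_x[[side]][inb] + F_amp * shape *
        ramp(u / 0.05) * ramp((1 - u) / 0.05)
    }
  }

  ## ---- measurement noise ----------------------------------------------------
  nz <- config$noise
  addn <- function(x, sd) if (sd > 0) x + rnorm(length(x), 0, sd) else x
  ar1 <- function(n, sd, rho = nz$torque_rho) {
    if (sd <= 0) return(numeric(n))
    e <- rnorm(n, 0, sd * sqrt(1 - rho^2))
    stats::filter(e, rho, method = "recursive")
  }
  torque_scale <- config$k_true * (-gait$theta_star) * M * G_ACC * l
  kin <- data.frame(
    time = tk,
    heel_x_L = addn(heel$L, nz$marker), heel_x_R = addn(heel$R, nz$marker),
    toe_x_L = addn(heel$L + 0.18, nz$marker),
    toe_x_R = addn(heel$R + 0.18, nz$marker),
    com_x = addn(com_x, nz$marker), com_y = addn(com_y, nz$marker),
    hip_angle_L = addn(ang$L, nz$angle), hip_angle_R = addn(ang$R, nz$angle),
    hip_torque_L = trq$L + as.numeric(ar1(nk, nz$torque_frac * torque_scale)),
    hip_torque_R = trq$R + as.numeric(ar1(nk, nz$torque_frac * torque_scale)))
  grf <- data.frame(
    time = tg,
    grf_x_L = addn(grf_x$L, nz$grf), grf_y_L = addn(grf_y$L, nz$grf),
    grf_x_R = addn(grf_x$R, nz$grf), grf_y_R = addn(grf_y$R, nz$grf))

  truth <- list(
    steps = data.frame(step = seq_len(n_steps), side = sides, t_hs = t_hs,
                       s = s_i, v = v_i, b = s_i / 2 - v_i,
                       theta_dot_minus = thd_m, dt_ds = dt_ds, tau = tau_i,
                       F = F_i, T = T_i),
    k_true = config$k_true, mu_true = config$mu_true,
    leg_length = l, subject_mass = M, v_dim = v_dim,
    belt_speed = v_belt_ms, gait = coef(gait))
  meta <- list(subject_mass = M, kinematic_rate = config$kinematic_rate,
               grf_rate = config$grf_rate,
               belt_speed_nominal = config$nominal_speed,
               belt_scale = config$belt_scale,
               subject_id = config$subject_id,
               speed_label = config$speed_label)
  mocap_trial(kin, grf, meta, truth = truth)
}

#' Generate a synthetic cohort across subjects and belt speeds
#'
#' Emulates the study design: `n_subjects` subjects each walking at the six
#' nominal belt speeds, with per-subject anthropometrics (mass, leg length)
#' and a per-subject hip-stiffness offset around the speed-dependent mean, so
#' that within every speed the stiffness varies across subjects with the
#' designed effect signs.
#'
#' @param n_subjects number of subjects.
#' @param speeds nominal belt speeds, m/s.
#' @param k_by_speed mean stiffness per speed.
#' @param k_sd between-subject stiffness standard deviation.
#' @param n_strides strides per side and trial.
#' @param noise noise list passed to [synthetic_config].
#' @param seed cohort seed; trial seeds are derived from it.
#' @return List of [mocap_trial] objects.
#' @export
generate_cohort <- function(n_subjects = 11,
                            speeds = seq(0.5, 1.75, by = 0.25),
                            k_by_speed = c(0.08, 0.10, 0.12, 0.14, 0.15, 0.16),
                            k_sd = 0.03, n_strides = 35,
                            noise = list(marker = 0.001, angle = 0.002,
                                         grf = 2, torque_frac = 0.9),
                            seed = 1) {
  stopifnot(length(k_by_speed) == length(speeds))
  set.seed(seed)
  mass <- rnorm(n_subjects, 58.8, 9.1)
  leg <- rnorm(n_subjects, 0.96, 0.05)
  k_off <- rnorm(n_subjects, 0, k_sd)
  trials <- list()
  for (i in seq_len(n_subjects)) {
    for (j in seq_along(speeds)) {
      cfg <- synthetic_config(
        nominal_speed = speeds[j],
        k_true = max(0.02, k_by_speed[j] + k_off[i]),
        leg_length = leg[i], subject_mass = mass[i],
        n_strides = n_strides, noise = noise,
        seed = (seed * 1000L + i * 10L + j) %% .Machine$integer.max,
        subject_id = sprintf("S%02d", i), speed_label = speeds[j])
      trials[[length(trials) + 1L]] <- generate_trial(cfg)
    }
  }
  trials
}
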