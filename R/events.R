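#' Detect gait events from a vertical ground-reaction-force channel
#'
#' Heel strike: for each up-crossing of the 10 N threshold, scan backward to
#' the last sample at or below the zero floor. Toe-off: for each down-crossing
#' of the threshold, scan forward to the first sample at or below the floor.
#' The 10 N hysteresis makes the detection robust to plate noise of a few
#' newtons; duplicate events from repeated threshold crossings are merged.
#'
#' @param grf_y vertical GRF samples (N) of one plate/side.
#' @param rate sampling rate, Hz.
#' @param threshold detection threshold, N.
#' @param floor zero-force floor, N (real plates never read exactly 0; for
#'   synthetic data the default exact 0 applies).
#' @return An object of class `gait_events`: list with integer sample indices
#'   `heel_strikes` and `toe_offs` and the corresponding `hs_times`,
#'   `to_times` (s, first sample = time 0).
#' @export
detect_gait_events <- function(grf_y, rate, threshold = 10, floor = 0) {
  n <- length(grf_y)
  up <- which(grf_y[-1] > threshold & grf_y[-n] <= threshold) + 1L
  down <- which(grf_y[-1] <= threshold & grf_y[-n] > threshold)
  if (length(up) == 0 && length(down) == 0)
    stop("no crossings of the detection threshold: no gait events", call. = FALSE)

  hs <- integer(0)
  for (i in up) {
    j <- i
    while (j > 1L && grf_y[j] > floor) j <- j - 1L
    if (grf_y[j] <= floor) hs <- c(hs, j)
  }
  to <- integer(0)
  for (i in down) {
    j <- i
    while (j < n && grf_y[j] > floor) j <- j + 1L
    if (grf_y[j] <= floor) to <- c(to, j)
  }
  hs <- sort(unique(hs)); to <- sort(unique(to))
  ev <- structure(list(heel_strikes = hs, toe_offs = to,
                       hs_times = (hs - 1L) / rate,
                       to_times = (to - 1L) / rate, rate = rate),
                  class = "gait_events")
  ## sanity: within a side heel strikes and toe-offs must alternate
  if (length(hs) > 1 && length(to) > 0) {
    lab <- rbind(data.frame(t = ev$hs_times, e = "hs"),
                 data.frame(t = ev$to_times, e = "to"))
    lab <- lab[order(lab$t), ]
    if (any(lab$e[-1] == lab$e[-nrow(lab)]))
      warning("non-alternating heel-strike/toe-off pattern: malformed trial?",
              call. = FALSE)
  }
  ev
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("Gait events: %d heel strikes, %d toe-offs (rate %g Hz)\n",
              length(x$heel_strikes), length(x$toe_offs), x$rate))
  invisible(x)
}

#' Build step windows from two-sided gait events
#'
#' A step runs from one heel strike to the next contralateral heel strike.
#' Steps are returned in time order with their leading side, the trailing
#' side's toe-off (end of double support), and the previous ipsilateral
#' step's heel strike (for the step period).
#'
#' @param events_left,events_right [detect_gait_events] results per side.
#' @param last_n keep only the last `last_n` complete steps (`Inf` for all).
#' @return data.frame with columns `side` (leading side), `t_hs`, `t_next_hs`,
#'   `t_prev_hs` (previous contralateral heel strike), `t_to_trailing`.
#' @export
build_steps <- function(events_left, events_right, last_n = 30) {
  hs <- rbind(data.frame(t = events_left$hs_times, side = "L"),
              data.frame(t = events_right$hs_times, side = "R"))
  hs <- hs[order(hs$t), ]
  if (nrow(hs) < 3) stop("not enough heel strikes to form steps", call. = FALSE)
  keep <- c(TRUE, hs$side[-1] != hs$side[-nrow(hs)])
  if (!all(keep)) {
    warning("dropping heel strikes that do not alternate between sides",
            call. = FALSE)
    hs <- hs[keep, ]
  }
  n <- nrow(hs)
  steps <- data.frame(side = hs$side[2:(n - 1)],
                      t_prev_hs = hs$t[1:(n - 2)],
                      t_hs = hs$t[2:(n - 1)],
                      t_next_hs = hs$t[3:n])
  ## trailing side's toe-off just after each heel strike
  steps$t_to_trailing <- vapply(seq_len(nrow(steps)), function(i) {
    tos <- if (steps$side[i] == "L") events_right$to_times else
      events_left$to_times
    cand <- tos[tos > steps$t_hs[i] & tos < steps$t_next_hs[i]]
    if (length(cand)) cand[1] else NA_real_
  }, numeric(1))
  steps <- steps[!is.na(steps$t_to_trailing), ]
  if (is.finite(last_n) && nrow(steps) > last_n)
    steps <- steps[(nrow(steps) - last_n + 1L):nrow(steps), ]
  rownames(steps) <- NULL
  steps
}
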