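#' Zero-lag Butterworth low-pass filter
#'
#' Fourth-order (net), zero-lag low-pass filter: a second-order Butterworth
#' filter applied forward and backward. Edge transients are suppressed by
#' odd-reflection padding at both ends before the forward-backward pass, so
#' constant signals pass through unchanged.
#'
#' @param x numeric signal.
#' @param rate sampling rate, Hz.
#' @param cutoff cut-off frequency, Hz; must be below the Nyquist frequency.
#' @return Filtered signal, same length as `x`.
#' @export
zero_lag_lowpass <- function(x, rate, cutoff) {
  if (!is.numeric(x) || length(x) < 8)
    stop("'x' must be a numeric signal with at least 8 samples", call. = FALSE)
  if (cutoff <= 0 || cutoff >= rate / 2)
    stop("'cutoff' must lie in (0, rate/2)", call. = FALSE)
  bf <- signal::butter(2, cutoff / (rate / 2), type = "low")
  n <- length(x)
  npad <- min(n - 1L, as.integer(ceiling(3 * rate / cutoff)))
  head_pad <- 2 * x[1] - x[seq(npad + 1L, 2L)]
  tail_pad <- 2 * x[n] - x[seq(n - 1L, n - npad)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  y[(npad + 1L):(npad + n)]
}

## centred finite differences (one-sided at the boundaries)
finite_diff <- function(x, rate) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * rate / 2
  d[1] <- (x[2] - x[1]) * rate
  d[n] <- (x[n] - x[n - 1]) * rate
  d
}
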