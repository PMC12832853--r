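#' Total pressure per foot
#'
#' Sums the eight sensor channels of each foot into one time series per
#' foot, the signal the gait-period detector operates on.
#'
#' @param rec a \code{pressure_recording}.
#' @return A list with numeric vectors \code{left} and \code{right}.
#' @export
foot_sum <- function(rec) {
  stopifnot(inherits(rec, "pressure_recording"))
  list(left  = rowSums(rec$pressure[, 1:8,  drop = FALSE]),
       right = rowSums(rec$pressure[, 9:16, drop = FALSE]))
}

#' Detect the dominant gait period of a 1-D pressure signal
#'
#' Two-stage estimate: the magnitude spectrum (after mean subtraction)
#' yields a candidate frequency as the largest peak in the physiological
#' gait band, and the unbiased autocorrelation refines the corresponding
#' lag in the time domain. Because the within-stride loading pattern of a
#' foot is double-bumped (heel strike, then push-off), the spectral argmax
#' can land on the second harmonic of the stride rate; the refinement
#' therefore searches +/-50\% windows around integer multiples of the
#' spectral candidate lag and keeps the smallest lag whose autocorrelation
#' comes within \code{harmonic_tol} of the best, resolving octave errors
#' while preferring the spectral estimate. The spectral peak must rise
#' above \code{prominence} times the median in-band magnitude, otherwise
#' the signal is treated as aperiodic.
#'
#' @param x numeric vector (summed foot pressure).
#' @param fs sampling frequency in Hz.
#' @param band frequency band (Hz) searched for the gait fundamental.
#' @param prominence required ratio of the spectral peak to the median
#'   in-band magnitude.
#' @param harmonic_tol fraction of the best autocorrelation value within
#'   which a smaller candidate lag is preferred.
#' @param max_harmonic largest multiple of the spectral candidate lag
#'   examined.
#' @return Integer period in samples, with attributes \code{fft_peak_freq}
#'   (Hz) and \code{autocorr_lag} (= the returned period).
#' @examples
#' t <- seq(0, 30, by = 1 / 20)
#' detect_period_1d(sin(2 * pi * 1.0 * t), fs = 20)  # 20 samples
#' @export
detect_period_1d <- function(x, fs, band = c(0.3, 3.0), prominence = 3,
                             harmonic_tol = 0.05, max_harmonic = 3) {
  n <- length(x)
  if (n < 4 * fs)
    stop_plantar("need at least 4 s of signal for period detection",
                 "detection_error")
  if (any(!is.finite(x)))
    stop_plantar("signal contains non-finite values", "detection_error")
  xc <- x - mean(x)
  if (stats::var(xc) == 0)
    stop_plantar("flat signal: no periodic structure", "detection_error")

  mag <- Mod(stats::fft(xc))
  freq <- (seq_len(n) - 1) * fs / n
  in_band <- which(freq >= band[1] & freq <= band[2])
  if (length(in_band) == 0)
    stop_plantar("no spectral bins inside the gait band", "detection_error")
  peak <- in_band[which.max(mag[in_band])]
  if (mag[peak] < prominence * stats::median(mag[in_band]))
    stop_plantar("no prominent spectral peak in the gait band",
                 "detection_error")
  f_star <- freq[peak]
  p0 <- round_half_up(fs / f_star)

  # unbiased autocorrelation, refined around multiples of the candidate lag
  acf_u <- function(l) sum(xc[seq_len(n - l)] * xc[(l + 1):n]) / (n - l)
  best <- lapply(seq_len(max_harmonic), function(k) {
    lo <- max(2, ceiling(0.5 * k * p0))
    hi <- min(n - 1, floor(1.5 * k * p0))
    if (lo > hi || k * p0 > n / 2) return(NULL)
    lags <- lo:hi
    ac <- vapply(lags, acf_u, numeric(1))
    i <- which.max(ac)  # first (smallest) lag on ties
    list(lag = lags[i], value = ac[i])
  })
  best <- best[!vapply(best, is.null, logical(1))]
  vals <- vapply(best, `[[`, numeric(1), "value")
  lags <- vapply(best, `[[`, numeric(1), "lag")
  ok <- vals >= (1 - harmonic_tol) * max(vals)
  p <- min(lags[ok])  # smallest near-best lag resolves octave errors

  structure(as.integer(p), fft_peak_freq = f_star, autocorr_lag = as.integer(p))
}

#' Unify left and right gait periods
#'
#' Equal periods are adopted directly; unequal periods are averaged and
#' rounded half-up to a whole number of samples.
#'
#' @param p_left,p_right periods in samples.
#' @return Integer unified period.
#' @export
unify_periods <- function(p_left, p_right) {
  stopifnot(p_left > 0, p_right > 0)
  if (p_left == p_right) return(as.integer(p_left))
  as.integer(round_half_up((p_left + p_right) / 2))
}

#' Detect the unified gait period of a recording
#'
#' @param rec a \code{pressure_recording}.
#' @param ... passed to \code{\link{detect_period_1d}}.
#' @return A list of class \code{gait_period}: \code{period_left},
#'   \code{period_right}, \code{period_unified} (samples),
#'   \code{fft_peak_freq} (Hz, per foot).
#' @export
detect_gait_period <- function(rec, ...) {
  s <- foot_sum(rec)
  pl <- detect_period_1d(s$left,  rec$sample_rate, ...)
  pr <- detect_period_1d(s$right, rec$sample_rate, ...)
  structure(list(period_left = as.integer(pl),
                 period_right = as.integer(pr),
                 period_unified = unify_periods(pl, pr),
                 fft_peak_freq = c(left = attr(pl, "fft_peak_freq"),
                                   right = attr(pr, "fft_peak_freq"))),
            class = "gait_period")
}

#' @export
print.gait_period <- function(x, ...) {
  cat(sprintf("<gait_period> left %d, right %d -> unified %d samples\n",
              x$period_left, x$period_right, x$period_unified))
  invisible(x)
}
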