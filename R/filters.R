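#' Individual filter primitives
#'
#' Zero-phase (forward-backward) Butterworth filters and the non-IIR
#' smoothing steps used by the modality chains. All IIR filters are
#' applied with [signal::filtfilt()], so the effective magnitude response
#' is the squared magnitude of the designed filter and no group delay is
#' introduced (heartbeat morphology measurements would otherwise be
#' biased).
#'
#' @param x numeric signal vector.
#' @param fs sampling rate (Hz).
#' @param cutoff,lo,hi cutoff frequencies (Hz); must be below `fs / 2`.
#' @param order Butterworth order of the designed (single-pass) filter.
#' @name filter-primitives
NULL

checkCutoff <- function(f, fs) {
  if (any(f >= fs / 2) || any(f <= 0))
    stop("cutoff frequencies must lie in (0, fs/2)", call. = FALSE)
}

#' @rdname filter-primitives
#' @export
butterLowpass <- function(x, cutoff, fs, order = 4) {
  checkCutoff(cutoff, fs)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' @rdname filter-primitives
#' @export
butterHighpass <- function(x, cutoff, fs, order = 4) {
  checkCutoff(cutoff, fs)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  as.numeric(signal::filtfilt(bf, x))
}

#' @rdname filter-primitives
#' @export
butterBandpass <- function(x, lo, hi, fs, order = 4) {
  checkCutoff(c(lo, hi), fs)
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' @rdname filter-primitives
#' @param center notch center frequency (Hz).
#' @param halfWidth half-bandwidth of the stop band (Hz); the chains use
#'   narrow +/- 1 Hz notches.
#' @export
butterNotch <- function(x, center, fs, halfWidth = 1, order = 2) {
  checkCutoff(c(center - halfWidth, center + halfWidth), fs)
  bf <- signal::butter(order, c(center - halfWidth, center + halfWidth) / (fs / 2),
                       type = "stop")
  as.numeric(signal::filtfilt(bf, x))
}

#' @rdname filter-primitives
#' @param window lookback window (s) of the trailing moving average.
#' @details `baselineMovingAverage` subtracts a trailing ("lookback")
#'   moving average from the signal; during the first window the average
#'   runs over the samples seen so far (warm-up region).
#' @export
baselineMovingAverage <- function(x, fs, window = 1) {
  stopifnotScalar(window, "window")
  w <- max(1L, round(window * fs))
  cs <- cumsum(x)
  n <- length(x)
  ma <- numeric(n)
  idx <- seq_len(n)
  ma[idx <= w] <- cs[idx[idx <= w]] / idx[idx <= w]
  if (n > w) ma[(w + 1):n] <- (cs[(w + 1):n] - cs[1:(n - w)]) / w
  x - ma
}

#' @rdname filter-primitives
#' @param width median filter width (s); rounded to samples, forced odd.
#' @export
medianSmooth <- function(x, fs, width = 0.05) {
  k <- max(1L, round(width * fs))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L) return(x)
  as.numeric(stats::runmed(x, k, endrule = "median"))
}

#' @rdname filter-primitives
#' @details `linearDetrend` removes the least-squares straight line.
#' @export
linearDetrend <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, t), x)
  as.numeric(fit$residuals)
}

#' @rdname filter-primitives
#' @export
meanSubtract <- function(x) x - mean(x)
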