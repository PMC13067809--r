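#' Peak-to-peak heartbeat amplitude
#'
#' `A_pp = max(beat) - min(beat)`.
#'
#' @param beat numeric beat vector (mV).
#' @return peak-to-peak amplitude (mV).
#' @export
peakToPeak <- function(beat) {
  if (!length(beat)) stop("empty beat", call. = FALSE)
  max(beat) - min(beat)
}

#' Locate Q and S troughs around the aligned R peak
#'
#' On centroid beats (which carry no detector annotations) Q is taken as
#' the minimum in the 60 ms before the R sample and S as the minimum in
#' the 60 ms after it.
#'
#' @param beat numeric beat vector.
#' @param rIdx 1-based R sample within the window.
#' @param fs sampling rate (Hz).
#' @return list with `qIdx` and `sIdx`.
#' @export
locateQS <- function(beat, rIdx, fs) {
  w <- round(0.06 * fs)
  qr <- max(1L, rIdx - w):(rIdx - 1L)
  sr <- (rIdx + 1L):min(length(beat), rIdx + w)
  list(qIdx = qr[which.min(beat[qr])], sIdx = sr[which.min(beat[sr])])
}

#' P- and T-wave amplitudes relative to the Q point
#'
#' The P amplitude is the absolute deviation from the Q-point value of
#' the extremum located before the Q wave; the T amplitude likewise for
#' the extremum after the S wave. Magnitudes are reported, so inverted
#' waves yield positive amplitudes. Empty search segments yield `NA`
#' with a warning rather than a silent zero.
#'
#' @param beat numeric beat vector.
#' @param qIdx,sIdx Q and S sample indices (1-based, `qIdx < sIdx`),
#'   e.g. from QRS detector annotations or [locateQS()].
#' @return list with `pAmp` and `tAmp` (mV, `NA` if undefined).
#' @export
landmarkAmplitudes <- function(beat, qIdx, sIdx) {
  n <- length(beat)
  if (qIdx < 1L || sIdx > n || qIdx >= sIdx)
    stop("invalid Q/S indices", call. = FALSE)
  qv <- beat[qIdx]
  amp <- function(seg, what) {
    if (!length(seg)) {
      warning(what, "-wave segment empty; amplitude undefined")
      return(NA_real_)
    }
    dev <- seg - qv
    abs(dev[which.max(abs(dev))])
  }
  list(pAmp = amp(beat[seq_len(qIdx - 1L)], "P"),
       tAmp = amp(if (sIdx < n) beat[(sIdx + 1L):n] else numeric(0), "T"))
}

#' Maximum normalized cross-correlation between aligned heartbeats
#'
#' Cross-correlates the two beats at all integer lags `m` in
#' `(-N, N)` with zero padding outside the overlap, normalizes each lag
#' by the square root of the product of the two beats' energies, and
#' returns the maximum. Scale-invariant: multiplying either beat by a
#' positive constant does not change the result.
#'
#' @param beat1,beat2 equal-length numeric vectors with nonzero energy.
#' @return list with `rho` (maximum normalized cross-correlation, in
#'   `[-1, 1]`) and `lag` (the maximizing lag, samples).
#' @export
xcorrMax <- function(beat1, beat2) {
  N <- length(beat1)
  if (length(beat2) != N) stop("beats must have equal length", call. = FALSE)
  e1 <- sum(beat1^2); e2 <- sum(beat2^2)
  if (e1 == 0 || e2 == 0)
    stop("zero-energy beat: cross-correlation undefined", call. = FALSE)
  lags <- seq(-(N - 1L), N - 1L)
  r <- vapply(lags, function(m) {
    if (m >= 0) sum(beat1[(m + 1L):N] * beat2[seq_len(N - m)])
    else sum(beat1[seq_len(N + m)] * beat2[(1L - m):N])
  }, numeric(1))
  rho <- r / sqrt(e1 * e2)
  i <- which.max(rho)
  list(rho = rho[i], lag = lags[i])
}

#' Normalized root-mean-square error between aligned heartbeats
#'
#' RMSE divided by the value range over the union of both beats. Two
#' identical constant beats have zero range; that 0/0 case is guarded
#' and returns 0 with a warning.
#'
#' @param beat1,beat2 equal-length numeric vectors.
#' @return dimensionless NRMSE (>= 0).
#' @export
nrmse <- function(beat1, beat2) {
  N <- length(beat1)
  if (length(beat2) != N || N == 0L)
    stop("beats must be non-empty and of equal length", call. = FALSE)
  rng <- max(beat1, beat2) - min(beat1, beat2)
  rmse <- sqrt(mean((beat1 - beat2)^2))
  if (rng == 0) {
    warning("zero combined range; returning 0")
    return(0)
  }
  rmse / rng
}

#' Per-cluster morphology table
#'
#' Convenience wrapper computing peak-to-peak, P and T amplitudes for
#' each row of a centroid-waveform matrix.
#'
#' @param waveforms K x p matrix of beats (e.g. [centroidHeartbeats()]).
#' @param rIdx R sample within the window.
#' @param fs sampling rate (Hz).
#' @return data.frame with `a_pp`, `p_amp`, `t_amp` per waveform.
#' @export
morphologyTable <- function(waveforms, rIdx, fs) {
  waveforms <- as.matrix(waveforms)
  out <- t(apply(waveforms, 1, function(b) {
    qs <- locateQS(b, rIdx, fs)
    la <- landmarkAmplitudes(b, qs$qIdx, qs$sIdx)
    c(a_pp = peakToPeak(b), p_amp = la$pAmp, t_amp = la$tAmp)
  }))
  as.data.frame(out)
}
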