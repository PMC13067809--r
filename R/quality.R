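#' Variance-based SNR in decibels
#'
#' `SNR_dB = 10 log10(var(signal) / var(noise))` between an activity
#' segment and a baseline noise segment.
#'
#' @param signalSeg,noiseSeg numeric segments.
#' @return SNR in dB.
#' @export
snrVariance <- function(signalSeg, noiseSeg) {
  if (!length(signalSeg) || !length(noiseSeg))
    stop("segments must be nonempty", call. = FALSE)
  vn <- var(noiseSeg)
  if (is.na(vn) || vn == 0)
    stop("noise segment has zero variance", call. = FALSE)
  10 * log10(var(signalSeg) / vn)
}

#' QRS-anchored noise windows for ECG SNR
#'
#' One 100 ms window per pair of successive R peaks, centered at the
#' midpoint between them; windows crossing the record bounds are
#' dropped.
#'
#' @param rTimes R-peak times (s).
#' @param width window width (s).
#' @param duration record length (s) used for the bounds check.
#' @return data.frame with `start`, `end`, `mid` (s); zero rows (with a
#'   warning) when fewer than 2 peaks are supplied.
#' @export
ecgNoiseWindows <- function(rTimes, width = 0.1, duration = Inf) {
  if (length(rTimes) < 2L) {
    warning("fewer than 2 R peaks: no noise windows")
    return(data.frame(start = numeric(0), end = numeric(0), mid = numeric(0)))
  }
  mid <- (head(rTimes, -1) + tail(rTimes, -1)) / 2
  out <- data.frame(start = mid - width / 2, end = mid + width / 2, mid = mid)
  out[out$start >= 0 & out$end <= duration, , drop = FALSE]
}

#' ECG SNR report from QRS-anchored noise windows
#'
#' Computes, per lead, the variance-based SNR with the signal variance
#' taken over the whole (preprocessed) lead and the noise variance over
#' the concatenated inter-QRS noise windows.
#'
#' @param rec preprocessed [Recording-class].
#' @param rTimes detected R-peak times (s).
#' @param width noise-window width (s).
#' @return data.frame with per-lead `var_signal`, `var_noise`, `snr_db`.
#' @export
ecgSnrReport <- function(rec, rTimes, width = 0.1) {
  stopifnot(is(rec, "Recording"))
  fs <- rec@fs
  wins <- ecgNoiseWindows(rTimes, width, duration = ncol(rec@samples) / fs)
  if (!nrow(wins)) stop("no usable noise windows", call. = FALSE)
  idx <- unlist(lapply(seq_len(nrow(wins)), function(i)
    (round(wins$start[i] * fs) + 1L):(round(wins$end[i] * fs))))
  idx <- idx[idx >= 1 & idx <= ncol(rec@samples)]
  out <- lapply(seq_len(nrow(rec@samples)), function(ld) {
    x <- as.numeric(rec@samples[ld, ])
    data.frame(lead = rec@leadLabels[ld], var_signal = var(x),
               var_noise = var(x[idx]),
               snr_db = snrVariance(x, x[idx]))
  })
  do.call(rbind, out)
}

#' Welch power spectral density
#'
#' Averaged modified periodograms over Hamming-windowed segments
#' (protocol default 2 s with 50% overlap), one-sided density scaling so
#' that the integral of the density equals the signal's mean square
#' (Parseval).
#'
#' @param x numeric signal (or [Recording-class], first lead).
#' @param fs sampling rate (Hz); taken from the recording if given.
#' @param win segment length (s).
#' @param overlap fractional overlap in `[0, 1)`.
#' @return list with `freq` (Hz) and `psd` (density, unit^2/Hz).
#' @export
welchPsd <- function(x, fs = NULL, win = 2, overlap = 0.5) {
  if (is(x, "Recording")) {
    fs <- x@fs
    x <- leadVector(x, 1L)
  }
  if (is.null(fs)) stop("fs required", call. = FALSE)
  n <- length(x)
  L <- round(win * fs)
  if (n < L) stop("record shorter than one window", call. = FALSE)
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- hammingWindow(L)
  scale <- fs * sum(w^2)
  nf <- floor(L / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)] * w
    pxx <- Mod(fft(seg))^2 / scale
    acc <- acc + pxx[seq_len(nf)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even L)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (L %% 2L == 0L) dbl[nf] <- 1
  list(freq = (seq_len(nf) - 1) * fs / L, psd = psd * dbl)
}

#' Integrated band power from a PSD
#'
#' @param freq,psd PSD grid as returned by [welchPsd()].
#' @param lo,hi band edges (Hz).
#' @return band power (rectangle rule over bins with `lo <= f < hi`).
#' @export
bandPower <- function(freq, psd, lo, hi) {
  if (hi <= lo) stop("empty band", call. = FALSE)
  df <- freq[2] - freq[1]
  sum(psd[freq >= lo & freq < hi]) * df
}

#' Default frequency bands for processed-to-raw power ratios
#'
#' Named band edges for the noise/content ratio analysis; the edges are
#' configuration defaults.
#'
#' @return data.frame with `name`, `lo`, `hi` (Hz).
#' @export
defaultBands <- function() {
  data.frame(name = c("motion", "LF", "MF", "HF", "UHF1", "UHF2"),
             lo = c(0.05, 0.5, 4, 15, 40, 60),
             hi = c(0.5, 4, 15, 40, 60, 90))
}

#' Processed-to-raw band-power ratios
#'
#' Welch PSD of the raw and processed signals, band power by
#' integration, and the per-band ratio `processed / raw`. Bands with
#' zero raw power yield `NaN` with a warning.
#'
#' @param raw,processed [Recording-class] objects (or numeric vectors)
#'   with identical sampling rate and length.
#' @param bands data.frame like [defaultBands()].
#' @param fs sampling rate (Hz) for vector input.
#' @param lead channel used when recordings are given.
#' @param win Welch segment length (s); 20 s by default so the lowest
#'   (sub-0.5 Hz) bands are resolved by several frequency bins.
#' @return data.frame `name`, `lo`, `hi`, `power_raw`, `power_processed`,
#'   `ratio`.
#' @export
bandPowerRatio <- function(raw, processed, bands = defaultBands(),
                           fs = NULL, lead = 1L, win = 20) {
  if (is(raw, "Recording")) {
    stopifnot(is(processed, "Recording"), raw@fs == processed@fs,
              ncol(raw@samples) == ncol(processed@samples))
    fs <- raw@fs
    raw <- leadVector(raw, lead)
    processed <- leadVector(processed, lead)
  }
  stopifnot(length(raw) == length(processed))
  pr <- welchPsd(raw, fs, win = win)
  pp <- welchPsd(processed, fs, win = win)
  out <- bands
  out$power_raw <- mapply(function(lo, hi) bandPower(pr$freq, pr$psd, lo, hi),
                          bands$lo, bands$hi)
  out$power_processed <- mapply(function(lo, hi)
    bandPower(pp$freq, pp$psd, lo, hi), bands$lo, bands$hi)
  out$ratio <- out$power_processed / out$power_raw
  if (any(out$power_raw == 0)) {
    warning("zero raw power in at least one band; ratio set to NaN")
    out$ratio[out$power_raw == 0] <- NaN
  }
  out
}

#' Time-resolved delta-band power
#'
#' Sliding-window band power (default delta, 0.5-4 Hz) with 2 s windows
#' and 0.5 s steps, each window timestamped at its center.
#'
#' @param x numeric signal or [Recording-class] (first lead).
#' @param fs sampling rate (Hz).
#' @param win,step window and step (s).
#' @param band band edges (Hz).
#' @return data.frame with `time` (s, window centers) and `power`.
#' @export
deltaPowerTimeseries <- function(x, fs = NULL, win = 2, step = 0.5,
                                 band = c(0.5, 4)) {
  if (is(x, "Recording")) {
    fs <- x@fs
    x <- leadVector(x, 1L)
  }
  n <- length(x)
  L <- round(win * fs)
  if (n < L) stop("record shorter than one window", call. = FALSE)
  stepn <- max(1L, round(step * fs))
  starts <- seq(1L, n - L + 1L, by = stepn)
  w <- hammingWindow(L)
  scale <- fs * sum(w^2)
  nf <- floor(L / 2) + 1L
  freq <- (seq_len(nf) - 1) * fs / L
  sel <- freq >= band[1] & freq < band[2]
  df <- fs / L
  power <- vapply(starts, function(s) {
    pxx <- Mod(fft(x[s:(s + L - 1L)] * w))^2 / scale
    pxx <- pxx[seq_len(nf)]
    dbl <- rep(2, nf); dbl[1] <- 1
    if (L %% 2L == 0L) dbl[nf] <- 1
    sum((pxx * dbl)[sel]) * df
  }, numeric(1))
  data.frame(time = (starts - 1) / fs + win / 2, power = power)
}
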