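# Modality-specific preprocessing chains. Each chain maps a Recording to
# a Recording of the same length; every constituent filter is exported on
# its own (filters.R) and the ECG chain can apply any single step in
# isolation for band-power ratio analyses.

applyPerLead <- function(rec, fun) {
  out <- rec
  for (ld in seq_len(nrow(rec@samples)))
    out@samples[ld, ] <- fun(as.numeric(rec@samples[ld, ]))
  out
}

#' ECG preprocessing chain
#'
#' The full chain applies, in order: an order-4 Butterworth low-pass at
#' 90 Hz, two narrow-band order-2 Butterworth notches at 50 and 80 Hz
#' (+/- 1 Hz), baseline removal by subtracting a trailing 1 s moving
#' average, and variance-based bad-segment rejection. `mode` may instead
#' name a single step (`"lowpass"`, `"notch"`, `"notch50"`, `"notch80"`,
#' `"baseline_ma"`) to apply that filter in isolation, as needed for
#' processed-to-raw band-power comparisons.
#'
#' @param rec a [Recording-class]; `fs` must exceed 180 Hz so the 90 Hz
#'   cutoff is below Nyquist.
#' @param mode `"full"` or a single step name.
#' @param lowpassCutoff,lowpassOrder,notchFreqs,notchHalfWidth,notchOrder,
#'   baselineWindow filter parameters (protocol defaults).
#' @param varianceWin,varianceZ segment-rejection parameters, see
#'   [rejectBadSegments()].
#' @return list with `recording` (filtered [Recording-class]) and `mask`
#'   (a [SegmentMask-class]; all-keep in single-step modes).
#' @export
ecgChain <- function(rec, mode = "full", lowpassCutoff = 90, lowpassOrder = 4,
                     notchFreqs = c(50, 80), notchHalfWidth = 1,
                     notchOrder = 2, baselineWindow = 1,
                     varianceWin = 2, varianceZ = 5) {
  stopifnot(is(rec, "Recording"))
  fs <- rec@fs
  if (fs <= 2 * lowpassCutoff)
    stop("fs must exceed twice the low-pass cutoff", call. = FALSE)
  steps <- list(
    lowpass = function(x) butterLowpass(x, lowpassCutoff, fs, lowpassOrder),
    notch50 = function(x) butterNotch(x, notchFreqs[1], fs, notchHalfWidth, notchOrder),
    notch80 = function(x) butterNotch(x, notchFreqs[2], fs, notchHalfWidth, notchOrder),
    baseline_ma = function(x) baselineMovingAverage(x, fs, baselineWindow))
  steps$notch <- function(x) steps$notch80(steps$notch50(x))
  n <- ncol(rec@samples)
  if (mode == "full") {
    out <- applyPerLead(rec, function(x)
      steps$baseline_ma(steps$notch80(steps$notch50(steps$lowpass(x)))))
    mask <- rejectBadSegments(out, varianceWin = varianceWin,
                              varianceZ = varianceZ)
    list(recording = out, mask = mask)
  } else {
    if (!mode %in% names(steps))
      stop("unknown step '", mode, "'", call. = FALSE)
    list(recording = applyPerLead(rec, steps[[mode]]),
         mask = new("SegmentMask", keep = rep(TRUE, n),
                    reason = rep("", n)))
  }
}

#' Variance (and optional impedance) based bad-segment rejection
#'
#' Splits the record into non-overlapping windows and rejects windows
#' whose log-variance is an outlier: the z-score uses the median and MAD
#' across windows (a robust scale, so a single large burst cannot mask
#' itself by inflating the spread). If any channel's window exceeds the
#' threshold the window is rejected for all channels. When an impedance
#' series is supplied, samples whose impedance exceeds
#' `impedanceThreshold` are additionally rejected; otherwise the
#' impedance rule is skipped (with a message).
#'
#' @param rec a [Recording-class].
#' @param varianceWin window length (s).
#' @param varianceZ robust z-score threshold on window log-variance.
#' @param impedanceSeries optional numeric vector (one value per sample).
#' @param impedanceThreshold rejection threshold for the impedance rule.
#' @return a [SegmentMask-class].
#' @export
rejectBadSegments <- function(rec, varianceWin = 2, varianceZ = 5,
                              impedanceSeries = NULL,
                              impedanceThreshold = NULL) {
  stopifnot(is(rec, "Recording"))
  n <- ncol(rec@samples)
  keep <- rep(TRUE, n)
  reason <- rep("", n)
  if (n == 0L)
    return(new("SegmentMask", keep = keep, reason = reason))
  w <- max(1L, round(varianceWin * rec@fs))
  starts <- seq(1L, n, by = w)
  for (ld in seq_len(nrow(rec@samples))) {
    x <- as.numeric(rec@samples[ld, ])
    v <- vapply(starts, function(s) {
      seg <- x[s:min(n, s + w - 1L)]
      if (length(seg) < 2L) 0 else var(seg)
    }, numeric(1))
    lv <- log(v + .Machine$double.eps)
    scale <- stats::mad(lv)
    if (scale == 0) next
    z <- (lv - stats::median(lv)) / scale
    bad <- which(z > varianceZ)
    for (b in bad) {
      idx <- starts[b]:min(n, starts[b] + w - 1L)
      keep[idx] <- FALSE
      reason[idx] <- "variance"
    }
  }
  if (!is.null(impedanceSeries)) {
    if (is.null(impedanceThreshold))
      stop("impedanceThreshold required with impedanceSeries", call. = FALSE)
    bad <- which(impedanceSeries > impedanceThreshold)
    keep[bad] <- FALSE
    reason[bad] <- "impedance"
  } else {
    message("impedance series absent; impedance rule skipped")
  }
  new("SegmentMask", keep = keep, reason = reason)
}

#' EOG preprocessing chain
#'
#' Order-4 Butterworth band-pass 0.1-15 Hz, mean subtraction, linear
#' detrending, db4 wavelet denoising at level 3, and a 50 ms median
#' filter, in that order.
#'
#' @param rec a [Recording-class].
#' @param lo,hi band-pass edges (Hz).
#' @param order Butterworth order.
#' @param waveletLevel db4 decomposition depth.
#' @param medianWidth median filter width (s).
#' @return filtered [Recording-class].
#' @export
eogChain <- function(rec, lo = 0.1, hi = 15, order = 4, waveletLevel = 3,
                     medianWidth = 0.05) {
  stopifnot(is(rec, "Recording"))
  fs <- rec@fs
  if (ncol(rec@samples) < 2L^waveletLevel * 8L)
    stop("record too short for wavelet level ", waveletLevel, call. = FALSE)
  applyPerLead(rec, function(x) {
    x <- butterBandpass(x, lo, hi, fs, order)
    x <- meanSubtract(x)
    x <- linearDetrend(x)
    x <- waveletDenoise(x, waveletLevel)
    medianSmooth(x, fs, medianWidth)
  })
}

#' EMG preprocessing chain with cardiac template subtraction
#'
#' Band-pass 20-90 Hz (order-4 Butterworth) and a 50 Hz notch, followed by
#' removal of cardiac interference: a template is formed as the mean of
#' windows centered on the supplied R-peak times, scaled per beat by a
#' least-squares fit and subtracted; finally db4 wavelet thresholding.
#' With fewer than 3 R times the template step is skipped with a warning.
#'
#' @param rec a [Recording-class].
#' @param rTimes sorted R-peak times (s) inside the record.
#' @param lo,hi band-pass edges (Hz).
#' @param order Butterworth order.
#' @param notch notch center frequency (Hz).
#' @param waveletLevel db4 decomposition depth.
#' @param templateHalfWidth half-width of the cardiac window (s).
#' @return filtered [Recording-class].
#' @export
emgChain <- function(rec, rTimes = numeric(0), lo = 20, hi = 90, order = 4,
                     notch = 50, waveletLevel = 3, templateHalfWidth = 0.3) {
  stopifnot(is(rec, "Recording"))
  fs <- rec@fs
  if (is.unsorted(rTimes)) stop("rTimes must be sorted", call. = FALSE)
  n <- ncol(rec@samples)
  if (length(rTimes) && (min(rTimes) < 0 || max(rTimes) > n / fs))
    stop("rTimes outside record", call. = FALSE)
  doTemplate <- length(rTimes) >= 3L
  if (length(rTimes) && !doTemplate)
    warning("fewer than 3 R times; cardiac template step skipped")
  hw <- round(templateHalfWidth * fs)
  applyPerLead(rec, function(x) {
    x <- butterBandpass(x, lo, hi, fs, order)
    x <- butterNotch(x, notch, fs)
    if (doTemplate) {
      centers <- round(rTimes * fs) + 1L
      ok <- centers - hw >= 1L & centers + hw <= n
      centers <- centers[ok]
      if (length(centers) >= 3L) {
        wins <- vapply(centers, function(cc) x[(cc - hw):(cc + hw)],
                       numeric(2L * hw + 1L))
        templ <- rowMeans(wins)
        tt <- sum(templ^2)
        if (tt > 0) {
          for (j in seq_along(centers)) {
            idx <- (centers[j] - hw):(centers[j] + hw)
            a <- sum(x[idx] * templ) / tt
            x[idx] <- x[idx] - a * templ
          }
        }
      }
    }
    waveletDenoise(x, waveletLevel)
  })
}

#' EEG preprocessing chain
#'
#' Linear detrending followed by an order-4 Butterworth low-pass at 49 Hz.
#'
#' @param rec a [Recording-class].
#' @param cutoff low-pass cutoff (Hz).
#' @param order Butterworth order.
#' @return filtered [Recording-class].
#' @export
eegChain <- function(rec, cutoff = 49, order = 4) {
  stopifnot(is(rec, "Recording"))
  fs <- rec@fs
  applyPerLead(rec, function(x) butterLowpass(linearDetrend(x), cutoff, fs, order))
}
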