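#' Pan-Tompkins R-peak detection
#'
#' Classic Pan-Tompkins stages: band-pass 5-15 Hz, five-point derivative,
#' squaring, 150 ms moving-window integration, then adaptive signal/noise
#' thresholds with a 200 ms refractory period and a search-back pass for
#' long gaps. Accepted detections are refined by snapping to the
#' largest-magnitude extremum of the input signal within +/- 40 ms.
#'
#' @param rec a [Recording-class] (preprocessed ECG) or numeric vector.
#' @param lead channel index or label used for detection.
#' @param fs sampling rate (Hz), required when `rec` is a vector.
#' @param refractory minimum inter-peak distance (s).
#' @param snapWindow half-width (s) of the extremum-refinement window.
#' @return strictly increasing R-peak times (s); empty for flat signals.
#' @export
detectRPeaks <- function(rec, lead = 1L, fs = NULL, refractory = 0.2,
                         snapWindow = 0.04) {
  if (is(rec, "Recording")) {
    x <- leadVector(rec, lead)
    fs <- rec@fs
  } else {
    x <- as.numeric(rec)
    if (is.null(fs)) stop("fs required for vector input", call. = FALSE)
  }
  n <- length(x)
  if (n < 2 * fs) stop("record must be at least 2 s long", call. = FALSE)
  if (all(x == x[1])) return(numeric(0))

  bp <- butterBandpass(x, 5, 15, fs, order = 3)
  dk <- c(-1, -2, 0, 2, 1) * fs / 8
  der <- as.numeric(stats::filter(bp, rev(dk), sides = 2))
  der[is.na(der)] <- 0
  sq <- der^2
  wlen <- round(0.150 * fs)
  if (wlen %% 2L == 0L) wlen <- wlen + 1L
  mwi <- as.numeric(stats::filter(sq, rep(1 / wlen, wlen), sides = 2))
  mwi[is.na(mwi)] <- 0

  # candidate peaks: local maxima of the integrated signal
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  cand <- cand[mwi[cand] > 0]
  if (!length(cand)) return(numeric(0))

  initSeg <- mwi[seq_len(min(n, round(2 * fs)))]
  spki <- 0.25 * max(initSeg)
  npki <- 0.5 * mean(initSeg)
  refr <- refractory * fs
  accepted <- integer(0)
  rrAvg <- NA_real_
  lastIdx <- -Inf
  for (i in seq_along(cand)) {
    pk <- cand[i]; amp <- mwi[pk]
    thr1 <- npki + 0.25 * (spki - npki)
    if (amp > thr1 && (pk - lastIdx) >= refr) {
      # consolidate: noisy ripples on the QRS lobe must not pre-empt the
      # true apex, so take the largest candidate within the refractory
      # span ahead before committing
      ahead <- cand[cand >= pk & cand < pk + refr]
      pk <- ahead[which.max(mwi[ahead])]
      amp <- mwi[pk]
      if (length(accepted)) {
        rr <- pk - lastIdx
        rrAvg <- if (is.na(rrAvg)) rr else 0.875 * rrAvg + 0.125 * rr
      }
      accepted <- c(accepted, pk)
      lastIdx <- pk
      spki <- 0.125 * amp + 0.875 * spki
    } else if ((pk - lastIdx) >= refr) {
      npki <- 0.125 * amp + 0.875 * npki
      # search-back: a long silent gap suggests a missed beat
      if (!is.na(rrAvg) && (pk - lastIdx) > 1.66 * rrAvg) {
        gap <- cand[cand > lastIdx + refr & cand < pk]
        gap <- gap[mwi[gap] > 0.5 * thr1]
        if (length(gap)) {
          best <- gap[which.max(mwi[gap])]
          accepted <- c(accepted, best)
          lastIdx <- best
          spki <- 0.25 * mwi[best] + 0.75 * spki
        }
      }
    }
  }
  if (!length(accepted)) return(numeric(0))

  # snap to the largest-magnitude extremum of the input signal
  half <- round(snapWindow * fs)
  snapped <- vapply(accepted, function(pk) {
    i0 <- max(1L, pk - half); i1 <- min(n, pk + half)
    as.integer(i0 + which.max(abs(x[i0:i1])) - 1L)
  }, integer(1))
  snapped <- sort(unique(snapped))
  # enforce refractory after snapping (keep the earlier of close pairs)
  keep <- logical(length(snapped))
  last <- -Inf
  for (i in seq_along(snapped)) {
    if (snapped[i] - last >= refr) {
      keep[i] <- TRUE
      last <- snapped[i]
    }
  }
  (snapped[keep] - 1) / fs
}

#' Batch force-aligned heartbeats
#'
#' Cuts one fixed-length window per R peak and per lead, with the R peak
#' forced to the window center (samples `R - 60 .. R + 60` for the
#' default 121-sample window, i.e. 0.605 s at 200 Hz). Windows that cross
#' the record edges, or that overlap rejected samples when a mask is
#' given, are dropped and counted.
#'
#' @param rec a [Recording-class].
#' @param rTimes R-peak times (s) within the record.
#' @param window window length in samples (odd; default 121).
#' @param mask optional [SegmentMask-class]; beats touching rejected
#'   samples are excluded before batching.
#' @return a [BeatMatrix-class]; `metadata()$dropped` counts the excluded
#'   beats.
#' @export
batchBeats <- function(rec, rTimes, window = 121L, mask = NULL) {
  stopifnot(is(rec, "Recording"))
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  fs <- rec@fs
  n <- ncol(rec@samples)
  if (length(rTimes) && (min(rTimes) < 0 || max(rTimes) > n / fs))
    stop("rTimes outside record", call. = FALSE)
  half <- (window - 1L) %/% 2L
  centers <- round(rTimes * fs) + 1L
  ok <- centers - half >= 1L & centers + half <= n
  if (!is.null(mask)) {
    stopifnot(is(mask, "SegmentMask"), length(mask@keep) == n)
    ok <- ok & vapply(centers, function(cc) {
      i0 <- max(1L, cc - half); i1 <- min(n, cc + half)
      all(mask@keep[i0:i1])
    }, logical(1))
  }
  dropped <- sum(!ok)
  centers <- centers[ok]
  nLeads <- nrow(rec@samples)
  nBeats <- length(centers) * nLeads
  beats <- matrix(0, nrow = window, ncol = nBeats)
  pid <- character(nBeats); lid <- character(nBeats); rt <- numeric(nBeats)
  j <- 0L
  for (ld in seq_len(nLeads)) {
    for (k in seq_along(centers)) {
      j <- j + 1L
      beats[, j] <- rec@samples[ld, (centers[k] - half):(centers[k] + half)]
      pid[j] <- rec@participantId
      lid[j] <- rec@leadLabels[ld]
      rt[j] <- (centers[k] - 1) / fs
    }
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(beats = beats),
    colData = S4Vectors::DataFrame(participant_id = pid, lead_id = lid,
                                   electrode = rep(rec@electrode, nBeats),
                                   r_time = rt),
    metadata = list(fs = fs, rIndex = half + 1L, dropped = dropped))
  as(se, "BeatMatrix")
}

#' Combine beat batches
#'
#' Column-binds beat matrices from several recordings (participants with
#' several recordings are pooled at the beat level).
#'
#' @param ... [BeatMatrix-class] objects with identical window length,
#'   sampling rate and R index.
#' @return a single [BeatMatrix-class].
#' @export
combineBeats <- function(...) {
  lst <- list(...)
  if (length(lst) == 1L && is.list(lst[[1]]) && !is(lst[[1]], "BeatMatrix"))
    lst <- lst[[1]]
  stopifnot(length(lst) >= 1L, all(vapply(lst, is, logical(1), "BeatMatrix")))
  fs0 <- S4Vectors::metadata(lst[[1]])$fs
  r0 <- S4Vectors::metadata(lst[[1]])$rIndex
  for (b in lst) {
    md <- S4Vectors::metadata(b)
    stopifnot(md$fs == fs0, md$rIndex == r0,
              nrow(b) == nrow(lst[[1]]))
  }
  beats <- do.call(cbind, lapply(lst, beatValues))
  cd <- do.call(rbind, lapply(lst, SummarizedExperiment::colData))
  dropped <- sum(vapply(lst, function(b) S4Vectors::metadata(b)$dropped,
                        numeric(1)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(beats = beats), colData = cd,
    metadata = list(fs = fs0, rIndex = r0, dropped = dropped))
  as(se, "BeatMatrix")
}
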