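#' @import methods
#' @importFrom stats var sd median mad rnorm runif rpois fft prcomp kmeans
#'   dist setNames
#' @importFrom utils head tail read.csv write.csv
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors metadata DataFrame
NULL

WAVE_NAMES <- c("P", "Q", "R", "S", "T")

#' Five-wave heartbeat morphology template
#'
#' Parameterizes a single heartbeat as a sum of five Gaussian deflections
#' (P, Q, R, S, T), each with an amplitude (mV), a center (s, measured within
#' the beat so that centers are strictly ordered P < Q < R < S < T) and a
#' width (s, the Gaussian standard deviation), together with the mean and
#' standard deviation of the RR interval used to place successive beats.
#'
#' @slot waveParams numeric 5 x 3 matrix, rows P,Q,R,S,T, columns
#'   amplitude (mV), center (s), width (s).
#' @slot rrMean mean RR interval (s).
#' @slot rrSd standard deviation of the RR interval (s).
#' @export
setClass("BeatTemplate",
  representation(waveParams = "matrix", rrMean = "numeric", rrSd = "numeric"),
  validity = function(object) {
    wp <- object@waveParams
    msg <- character()
    if (!is.numeric(wp) || nrow(wp) != 5L || ncol(wp) != 3L)
      msg <- c(msg, "waveParams must be a numeric 5 x 3 matrix")
    else {
      if (any(wp[, 3L] <= 0)) msg <- c(msg, "wave widths must be > 0")
      if (any(diff(wp[, 2L]) <= 0))
        msg <- c(msg, "wave centers must be strictly ordered P < Q < R < S < T")
      span <- wp[5L, 2L] - wp[1L, 2L]
      if (length(object@rrMean) != 1L || object@rrMean <= 2 * span)
        msg <- c(msg, "rrMean must exceed twice the P-to-T center span")
    }
    if (length(object@rrSd) != 1L || object@rrSd < 0)
      msg <- c(msg, "rrSd must be a single non-negative number")
    if (length(msg)) msg else TRUE
  })

#' Additive noise model for synthetic biosignals
#'
#' @slot baselineAmp baseline-wander amplitude (mV).
#' @slot baselineFreq baseline-wander frequency (Hz, below 1 Hz).
#' @slot powerline50 50 Hz interference amplitude (mV).
#' @slot powerline80 80 Hz interference amplitude (mV).
#' @slot broadbandSd white-noise standard deviation (mV).
#' @slot artifactRate motion-artifact event rate (events/min).
#' @slot artifactAmp motion-artifact amplitude (mV).
#' @slot artifactDur motion-artifact duration (s).
#' @export
setClass("NoiseSpec",
  representation(baselineAmp = "numeric", baselineFreq = "numeric",
                 powerline50 = "numeric", powerline80 = "numeric",
                 broadbandSd = "numeric", artifactRate = "numeric",
                 artifactAmp = "numeric", artifactDur = "numeric"),
  validity = function(object) {
    amps <- c(object@baselineAmp, object@powerline50, object@powerline80,
              object@broadbandSd, object@artifactRate, object@artifactAmp)
    msg <- character()
    if (any(amps < 0)) msg <- c(msg, "all amplitudes and rates must be >= 0")
    if (object@artifactDur <= 0) msg <- c(msg, "artifactDur must be > 0")
    if (object@baselineFreq <= 0 || object@baselineFreq >= 1)
      msg <- c(msg, "baselineFreq must lie in (0, 1) Hz")
    if (length(msg)) msg else TRUE
  })

#' First-order electrode transfer model
#'
#' Abstracts the electrode-dependent filtering of the skin-electrode
#' interface as a single-pole low-pass filter at `lpCutoff` plus
#' multiplicative gains on the additive broadband noise and on the
#' drift/artifact components. The `ideal` kind is the identity transfer
#' with zero noise and drift gains.
#'
#' @slot kind one of `"PPHG"`, `"AgCl"`, `"ideal"`.
#' @slot lpCutoff low-pass pole frequency (Hz).
#' @slot noiseGain multiplier on broadband noise (dimensionless, >= 0).
#' @slot driftGain multiplier on baseline wander and motion artifacts.
#' @export
setClass("ElectrodeModel",
  representation(kind = "character", lpCutoff = "numeric",
                 noiseGain = "numeric", driftGain = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("PPHG", "AgCl", "ideal"))
      msg <- c(msg, "kind must be one of 'PPHG', 'AgCl', 'ideal'")
    if (object@lpCutoff <= 0) msg <- c(msg, "lpCutoff must be > 0")
    if (object@noiseGain < 0 || object@driftGain < 0)
      msg <- c(msg, "gains must be >= 0")
    if (object@kind == "ideal" && (object@noiseGain != 0 || object@driftGain != 0))
      msg <- c(msg, "ideal electrode requires noiseGain = driftGain = 0")
    if (length(msg)) msg else TRUE
  })

#' Multichannel biosignal recording
#'
#' A uniformly sampled multichannel time series (channels x samples, mV)
#' with sampling rate, lead labels and provenance metadata. Synthetic
#' recordings additionally carry ground truth (true R-peak times and the
#' clean, noise-free signal) in the `truth` list.
#'
#' @slot samples numeric channels x time matrix (mV).
#' @slot fs sampling rate (Hz).
#' @slot leadLabels character vector, one unique label per channel.
#' @slot participantId participant identifier.
#' @slot electrode electrode kind string.
#' @slot truth list; optionally `rTimes` (s) and `clean` (matrix like
#'   `samples`).
#' @export
setClass("Recording",
  representation(samples = "matrix", fs = "numeric", leadLabels = "character",
                 participantId = "character", electrode = "character",
                 truth = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@fs) != 1L || object@fs <= 0)
      msg <- c(msg, "fs must be a single positive number")
    if (nrow(object@samples) != length(object@leadLabels))
      msg <- c(msg, "one lead label per channel required")
    if (anyDuplicated(object@leadLabels))
      msg <- c(msg, "lead labels must be unique")
    if (length(msg)) msg else TRUE
  })

#' R-aligned heartbeat batch
#'
#' A `SummarizedExperiment` whose `"beats"` assay holds force-aligned
#' heartbeats column-wise: each column is one 121-sample beat window (mV)
#' with the R peak at a fixed row (`rIndex` in the metadata), and `colData`
#' carries the per-beat participant, lead and electrode labels. At the
#' default 200 Hz, 121 samples span 0.605 s.
#'
#' @export
setClass("BeatMatrix", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character()
    if (!"beats" %in% SummarizedExperiment::assayNames(object))
      msg <- c(msg, "a 'beats' assay is required")
    md <- S4Vectors::metadata(object)
    if (is.null(md$fs) || is.null(md$rIndex))
      msg <- c(msg, "metadata fields 'fs' and 'rIndex' are required")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("participant_id", "lead_id") %in% colnames(cd)))
      msg <- c(msg, "colData must have 'participant_id' and 'lead_id'")
    if (length(msg)) msg else TRUE
  })

#' Electrochemical impedance spectrum
#'
#' Complex impedance versus frequency from a small-signal AC sweep, with
#' the parallel-plate cell geometry (electrode area and sample thickness)
#' needed to convert impedance into dielectric quantities.
#'
#' @slot freq frequencies (Hz), strictly ascending.
#' @slot zReal real part of impedance (ohm).
#' @slot zImag imaginary part of impedance (ohm).
#' @slot area electrode area (m^2).
#' @slot thickness sample thickness (m).
#' @export
setClass("ImpedanceSpectrum",
  representation(freq = "numeric", zReal = "numeric", zImag = "numeric",
                 area = "numeric", thickness = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@freq)
    if (length(object@zReal) != n || length(object@zImag) != n)
      msg <- c(msg, "freq, zReal, zImag must have equal length")
    if (n && (any(object@freq <= 0) || any(diff(object@freq) <= 0)))
      msg <- c(msg, "freq must be positive and strictly ascending")
    if (length(msg)) msg else TRUE
  })

#' Dielectric spectrum derived from impedance
#'
#' Relative permittivity (eps' storage, eps'' loss), loss tangent
#' tan(delta) = eps''/eps', electric modulus M* = 1/eps*, and the
#' interfacial relaxation time tau = 1/(2 pi f_max) located at the -Z''
#' peak.
#'
#' @export
setClass("DielectricSpectrum",
  representation(freq = "numeric", epsReal = "numeric", epsImag = "numeric",
                 tanDelta = "numeric", modReal = "numeric", modImag = "numeric",
                 tau = "numeric", fMax = "numeric"))

#' Per-sample keep/reject mask from quality control
#'
#' @slot keep logical, one element per sample; `TRUE` = retained.
#' @slot reason character, reason code (`"variance"`, `"impedance"`,
#'   `"manual"`) on rejected samples, `""` on kept samples.
#' @export
setClass("SegmentMask",
  representation(keep = "logical", reason = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@keep) != length(object@reason))
      msg <- c(msg, "keep and reason must have equal length")
    if (any(nzchar(object@reason[object@keep])))
      msg <- c(msg, "reason codes allowed only on rejected samples")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "SegmentMask", function(object) {
  cat(sprintf("SegmentMask: %d/%d samples kept\n", sum(object@keep),
              length(object@keep)))
})

setMethod("show", "BeatTemplate", function(object) {
  cat("BeatTemplate: rrMean =", object@rrMean, "s, rrSd =", object@rrSd, "s\n")
  print(round(object@waveParams, 4))
})

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording '%s' (%s): %d lead(s) x %d samples @ %g Hz (%.1f s)\n",
              object@participantId, object@electrode, nrow(object@samples),
              ncol(object@samples), object@fs, ncol(object@samples) / object@fs))
  cat("  leads:", paste(object@leadLabels, collapse = ", "))
  if (!is.null(object@truth$rTimes))
    cat(sprintf(" | truth: %d R peaks", length(object@truth$rTimes)))
  cat("\n")
})

setMethod("show", "ImpedanceSpectrum", function(object) {
  cat(sprintf("ImpedanceSpectrum: %d points, %g-%g Hz\n", length(object@freq),
              min(object@freq), max(object@freq)))
})

setMethod("show", "DielectricSpectrum", function(object) {
  cat(sprintf("DielectricSpectrum: %d points; tau = %.4g s (f_max = %.4g Hz)\n",
              length(object@freq), object@tau, object@fMax))
})
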