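#' Construct a heartbeat morphology template
#'
#' @param waveParams 5 x 3 numeric matrix (rows P,Q,R,S,T; columns amplitude
#'   mV, center s relative to the R peak, width s).
#' @param rrMean,rrSd mean and SD of the RR interval (s).
#' @return a [BeatTemplate-class].
#' @export
beatTemplate <- function(waveParams = defaultWaveParams(), rrMean = 0.95,
                         rrSd = 0.02) {
  dimnames(waveParams) <- list(WAVE_NAMES, c("amplitude", "center", "width"))
  new("BeatTemplate", waveParams = waveParams, rrMean = rrMean, rrSd = rrSd)
}

#' @rdname beatTemplate
#' @export
defaultWaveParams <- function() {
  matrix(c( 0.12, -0.150, 0.025,   # P
           -0.12, -0.030, 0.010,   # Q
            1.00,  0.000, 0.012,   # R
           -0.25,  0.030, 0.010,   # S
            0.30,  0.270, 0.045),  # T
         nrow = 5, ncol = 3, byrow = TRUE,
         dimnames = list(WAVE_NAMES, c("amplitude", "center", "width")))
}

#' Construct an additive noise specification
#'
#' All amplitudes in mV. `none = TRUE` gives the all-zero specification
#' used for clean-signal identities.
#'
#' @param baselineAmp,baselineFreq baseline wander amplitude and frequency
#'   (sub-1 Hz).
#' @param powerline50,powerline80 mains interference amplitudes at 50 Hz and
#'   at the 80 Hz component observed alongside it.
#' @param broadbandSd white-noise SD.
#' @param artifactRate,artifactAmp,artifactDur Poisson motion-artifact bursts:
#'   rate (events/min), amplitude (mV) and duration (s).
#' @param none logical; if `TRUE` all amplitudes are zero.
#' @return a [NoiseSpec-class].
#' @export
noiseSpec <- function(baselineAmp = 0.15, baselineFreq = 0.25,
                      powerline50 = 0.05, powerline80 = 0.02,
                      broadbandSd = 0.04, artifactRate = 2,
                      artifactAmp = 0.5, artifactDur = 1.5, none = FALSE) {
  if (none)
    return(new("NoiseSpec", baselineAmp = 0, baselineFreq = 0.25,
               powerline50 = 0, powerline80 = 0, broadbandSd = 0,
               artifactRate = 0, artifactAmp = 0, artifactDur = 1))
  new("NoiseSpec", baselineAmp = baselineAmp, baselineFreq = baselineFreq,
      powerline50 = powerline50, powerline80 = powerline80,
      broadbandSd = broadbandSd, artifactRate = artifactRate,
      artifactAmp = artifactAmp, artifactDur = artifactDur)
}

#' Construct an electrode transfer model
#'
#' Presets encode the contrast the benchmark exercises: the hydrogel
#' (`"PPHG"`) electrode behaves as an interfacial low-pass filter with a
#' lower pole and attenuated noise/drift coupling, the clinical `"AgCl"`
#' electrode passes more high-frequency noise, and `"ideal"` is the
#' identity transfer. The preset numbers are configuration, not measured
#' claims.
#'
#' @param kind `"PPHG"`, `"AgCl"` or `"ideal"`.
#' @param lpCutoff,noiseGain,driftGain override the preset values.
#' @return an [ElectrodeModel-class].
#' @export
electrodeModel <- function(kind = c("PPHG", "AgCl", "ideal"),
                           lpCutoff = NULL, noiseGain = NULL,
                           driftGain = NULL) {
  kind <- match.arg(kind)
  preset <- switch(kind,
    PPHG  = list(lp = 40,  ng = 0.7, dg = 0.6),
    AgCl  = list(lp = 95,  ng = 1.0, dg = 1.0),
    ideal = list(lp = 1e6, ng = 0,   dg = 0))
  new("ElectrodeModel", kind = kind,
      lpCutoff = if (is.null(lpCutoff)) preset$lp else lpCutoff,
      noiseGain = if (is.null(noiseGain)) preset$ng else noiseGain,
      driftGain = if (is.null(driftGain)) preset$dg else driftGain)
}

#' Cohort priors for template sampling
#'
#' The distributions from which [sampleCohortTemplates()] draws
#' per-participant morphology. Amplitudes in mV, times in s; normal
#' components are truncated at about two SD to keep templates
#' physiological and the sampling unbiased.
#'
#' @return named list of `c(mean, sd)` pairs (or ranges for uniforms).
#' @export
cohortPriors <- function() {
  list(
    p_amp = c(0.12, 0.03), q_amp = c(-0.12, 0.03), r_amp = c(1.00, 0.20),
    s_amp = c(-0.25, 0.08), t_amp = c(0.30, 0.10),
    p_center = c(-0.150, 0.020), q_center = c(-0.030, 0.005),
    s_center = c(0.030, 0.005), t_center = c(0.270, 0.030),
    p_width = c(0.025, 0.006), q_width = c(0.010, 0.002),
    r_width = c(0.012, 0.003), s_width = c(0.010, 0.002),
    t_width = c(0.045, 0.010),
    rr_mean = c(0.95, 0.04),          # truncated to +/- 2 SD
    rr_sd = c(0.010, 0.040)           # uniform range
  )
}

#' Sample per-participant heartbeat templates
#'
#' Draws `n` morphology templates from the cohort priors
#' ([cohortPriors()]), emulating inter-personal variability of the P-QRS-T
#' landmarks and RR statistics. Deterministic for a fixed seed.
#'
#' @param n number of participants (>= 1).
#' @param seed integer RNG seed.
#' @return list of [BeatTemplate-class], named `p1..pn`.
#' @export
sampleCohortTemplates <- function(n, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a count >= 1", call. = FALSE)
  n <- as.integer(n)
  pr <- cohortPriors()
  tn <- function(k, par, lo = -Inf, hi = Inf)
    rnormTrunc(k, par[1], par[2], max(lo, par[1] - 2 * par[2]),
               min(hi, par[1] + 2 * par[2]))
  withSeed(seed, {
    lapply(setNames(seq_len(n), paste0("p", seq_len(n))), function(i) {
      amp <- c(tn(1, pr$p_amp, lo = 0.04), tn(1, pr$q_amp, hi = -0.02),
               tn(1, pr$r_amp, lo = 0.5), tn(1, pr$s_amp, hi = -0.05),
               tn(1, pr$t_amp, lo = 0.10))
      ctr <- c(tn(1, pr$p_center), tn(1, pr$q_center), 0,
               tn(1, pr$s_center), tn(1, pr$t_center))
      wid <- c(tn(1, pr$p_width, lo = 0.005), tn(1, pr$q_width, lo = 0.004),
               tn(1, pr$r_width, lo = 0.005), tn(1, pr$s_width, lo = 0.004),
               tn(1, pr$t_width, lo = 0.01))
      span <- ctr[5] - ctr[1]
      repeat {
        rrm <- tn(1, pr$rr_mean)
        if (rrm > 2 * span + 0.01) break
      }
      beatTemplate(matrix(c(amp, ctr, wid), ncol = 3), rrMean = rrm,
                   rrSd = runif(1, pr$rr_sd[1], pr$rr_sd[2]))
    })
  })
}

# default per-lead gains on the five wave amplitudes (rows = leads).
# Each wave has its own electrical axis, so its projection onto a lead is
# wave-specific rather than a global scalar: lead II carries the largest
# R, lead I relatively prominent P/T with a smaller R, lead III a small R
# with deep Q/S and an inverted T.
defaultLeadGains <- function(leads) {
  base <- matrix(c(0.85, 0.50, 0.50, 0.30, 0.90,    # lead I
                   1.00, 1.00, 1.00, 1.00, 1.00,    # lead II
                   0.45, 1.60, 0.30, 1.80, -0.60),  # lead III
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("I", "II", "III"), WAVE_NAMES))
  if (leads <= 3) return(base[seq_len(leads), , drop = FALSE])
  extra <- base[rep_len(seq_len(3), leads - 3), , drop = FALSE] * 0.8
  rownames(extra) <- paste0("X", seq_len(leads - 3))
  rbind(base, extra)
}

onePoleLowpass <- function(x, fc, fs) {
  a <- exp(-2 * pi * fc / fs)
  as.numeric(stats::filter((1 - a) * x, filter = a, method = "recursive"))
}

#' Synthesize a multi-lead ECG recording with known ground truth
#'
#' Generates a Gaussian-wave (P,Q,R,S,T) beat train at RR intervals
#' `rrMean +/- rrSd` (i.i.d. normal, truncated at 3 SD), scales wave
#' amplitudes per lead, removes the clean train's mean per lead (the
#' recorder is AC-coupled), then adds baseline wander, 50 and 80 Hz mains
#' components, white noise and Hann-windowed motion-artifact bursts at
#' Poisson times, and finally applies the electrode's single-pole low-pass
#' transfer (identity for the ideal electrode). True R-peak times and the
#' clean signal are stored in the `truth` slot.
#'
#' @param template a [BeatTemplate-class].
#' @param leads number of leads (per-lead gains from an internal 3-lead
#'   default, see Details).
#' @param duration record length (s); must be at least `5 * rrMean`.
#' @param fs sampling rate (Hz, >= 100; default 200).
#' @param noise a [NoiseSpec-class].
#' @param electrode an [ElectrodeModel-class].
#' @param seed integer RNG seed.
#' @param participantId label stored in the recording.
#' @param leadGains optional leads x 5 gain matrix overriding the default.
#' @return a [Recording-class] with `truth$rTimes` and `truth$clean`.
#' @export
synthesizeECG <- function(template, leads = 3L, duration = 420, fs = 200,
                          noise = noiseSpec(), electrode = electrodeModel("ideal"),
                          seed = 1L, participantId = "p1", leadGains = NULL) {
  stopifnot(is(template, "BeatTemplate"), is(noise, "NoiseSpec"),
            is(electrode, "ElectrodeModel"))
  if (fs < 100) stop("fs must be >= 100 Hz", call. = FALSE)
  if (duration < 5 * template@rrMean)
    stop("duration must be at least 5 * rrMean", call. = FALSE)
  if (is.null(leadGains)) leadGains <- defaultLeadGains(leads)
  stopifnot(nrow(leadGains) == leads, ncol(leadGains) == 5L)

  n <- round(duration * fs)
  tgrid <- (seq_len(n) - 1) / fs
  wp <- template@waveParams

  withSeed(seed, {
    # R-peak schedule
    rTimes <- numeric(0)
    tcur <- 0.4
    while (tcur <= duration - 0.05) {
      rTimes <- c(rTimes, tcur)
      rr <- template@rrMean +
        rnormTrunc(1, 0, template@rrSd, -3 * template@rrSd, 3 * template@rrSd)
      tcur <- tcur + rr
    }

    clean <- matrix(0, nrow = leads, ncol = n)
    for (w in seq_len(5)) {
      ctr <- wp[w, 2]; wid <- wp[w, 3]
      for (r in rTimes) {
        mu <- r + ctr
        i0 <- max(1L, floor((mu - 5 * wid) * fs) + 1L)
        i1 <- min(n, ceiling((mu + 5 * wid) * fs) + 1L)
        if (i0 > i1) next
        g <- exp(-((tgrid[i0:i1] - mu)^2) / (2 * wid^2))
        for (ld in seq_len(leads))
          clean[ld, i0:i1] <- clean[ld, i0:i1] + wp[w, 1] * leadGains[ld, w] * g
      }
    }
    clean <- clean - rowMeans(clean)   # AC coupling

    out <- clean
    for (ld in seq_len(leads)) {
      drift <- noise@baselineAmp *
        sin(2 * pi * noise@baselineFreq * tgrid + runif(1, 0, 2 * pi))
      nArt <- rpois(1, noise@artifactRate * duration / 60)
      if (nArt > 0) {
        wlen <- max(3L, round(noise@artifactDur * fs))
        for (k in seq_len(nArt)) {
          st <- sample.int(max(1L, n - wlen), 1L)
          drift[st:(st + wlen - 1L)] <- drift[st:(st + wlen - 1L)] +
            sample(c(-1, 1), 1) * noise@artifactAmp * hannWindow(wlen)
        }
      }
      mains <- noise@powerline50 * sin(2 * pi * 50 * tgrid + runif(1, 0, 2 * pi)) +
        noise@powerline80 * sin(2 * pi * 80 * tgrid + runif(1, 0, 2 * pi))
      white <- if (noise@broadbandSd > 0) rnorm(n, 0, noise@broadbandSd) else 0
      x <- clean[ld, ] + electrode@driftGain * drift +
        electrode@noiseGain * white + mains
      if (electrode@kind != "ideal") x <- onePoleLowpass(x, electrode@lpCutoff, fs)
      out[ld, ] <- x
    }

    new("Recording", samples = out, fs = fs,
        leadLabels = rownames(leadGains), participantId = participantId,
        electrode = electrode@kind,
        truth = list(rTimes = rTimes, clean = clean, seed = seed,
                     template = template))
  })
}

#' Synthesize a single-relaxation impedance spectrum
#'
#' Equivalent-circuit oracle: a series resistance `rs` in series with the
#' parallel combination of a charge-transfer resistance `rct` and a
#' double-layer capacitance `cdl`, i.e. `Z(w) = rs + rct / (1 + i w rct cdl)`.
#' The -Im(Z) semicircle peaks at exactly `f = 1 / (2 pi rct cdl)`.
#'
#' @param rs series resistance (ohm, >= 0).
#' @param rct charge-transfer resistance (ohm, > 0).
#' @param cdl double-layer capacitance (F, > 0).
#' @param freqs frequency grid (Hz), positive ascending; default log grid
#'   0.01-1e5 Hz.
#' @param area,thickness cell geometry (m^2, m) stored for dielectric
#'   conversion.
#' @return an [ImpedanceSpectrum-class].
#' @export
synthesizeEIS <- function(rs, rct, cdl,
                          freqs = 10^seq(-2, 5, length.out = 141),
                          area = pi * 0.0085^2, thickness = 1.5e-3) {
  if (!is.numeric(rs) || rs < 0) stop("rs must be >= 0", call. = FALSE)
  stopifnotScalar(rct, "rct"); stopifnotScalar(cdl, "cdl")
  if (any(freqs <= 0) || is.unsorted(freqs, strictly = TRUE))
    stop("freqs must be positive and strictly ascending", call. = FALSE)
  w <- 2 * pi * freqs
  z <- rs + rct / (1 + 1i * w * rct * cdl)
  new("ImpedanceSpectrum", freq = freqs, zReal = Re(z), zImag = Im(z),
      area = area, thickness = thickness)
}
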