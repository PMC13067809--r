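# Daubechies-4 discrete wavelet transform (periodic boundary) and
# soft-threshold denoising; analytic Morlet CWT for scalograms.
# Implemented here because no wavelet library ships with the package's
# dependency set; the transform is orthonormal, so soft thresholding can
# only shrink signal energy.

# db4 scaling (low-pass) filter, 8 taps, orthonormal (sums to sqrt(2))
DB4_H <- c( 0.230377813308855230, 0.714846570552541500,
            0.630880767929590400, -0.027983769416983850,
           -0.187034811718881140, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278)

# quadrature mirror high-pass filter g[k] = (-1)^k h[L-1-k]
db4G <- function() {
  L <- length(DB4_H)
  rev(DB4_H) * (-1)^(seq_len(L) - 1)
}

# one analysis level with periodic extension; n must be even
dwtStep <- function(x, h, g) {
  n <- length(x)
  half <- n %/% 2L
  a <- numeric(half); d <- numeric(half)
  for (m in seq_along(h)) {
    idx <- ((2L * (seq_len(half) - 1L) + (m - 1L)) %% n) + 1L
    a <- a + h[m] * x[idx]
    d <- d + g[m] * x[idx]
  }
  list(a = a, d = d)
}

# adjoint (= inverse, orthonormal transform) of dwtStep; for fixed tap m
# the target indices (2k + m) mod n are pairwise distinct, so plain
# indexed accumulation is safe
idwtStep <- function(a, d, h, g) {
  half <- length(a)
  n <- 2L * half
  x <- numeric(n)
  for (m in seq_along(h)) {
    idx <- ((2L * (seq_len(half) - 1L) + (m - 1L)) %% n) + 1L
    x[idx] <- x[idx] + h[m] * a + g[m] * d
  }
  x
}

dwtPeriodic <- function(x, level) {
  h <- DB4_H; g <- db4G()
  details <- vector("list", level)
  a <- x
  for (l in seq_len(level)) {
    st <- dwtStep(a, h, g)
    a <- st$a
    details[[l]] <- st$d
  }
  list(approx = a, details = details)
}

idwtPeriodic <- function(dec) {
  h <- DB4_H; g <- db4G()
  a <- dec$approx
  for (l in rev(seq_along(dec$details)))
    a <- idwtStep(a, dec$details[[l]], h, g)
  a
}

#' Wavelet denoising (Daubechies-4, soft universal threshold)
#'
#' Decomposes the signal with an orthonormal db4 DWT (periodic boundary)
#' to the requested level, soft-thresholds each detail level at the
#' universal threshold `sqrt(2 log n_j) * sigma_j` with the level's noise
#' scale `sigma_j` estimated by the median absolute deviation of its
#' coefficients, and reconstructs. Signals whose length is not a multiple
#' of `2^level` are edge-padded for the transform and truncated after
#' reconstruction.
#'
#' @param x numeric signal.
#' @param level decomposition depth (default 3, the protocol value).
#' @return denoised signal, same length as `x`.
#' @export
waveletDenoise <- function(x, level = 3L) {
  n <- length(x)
  if (n < 2L^level * 8L)
    stop("signal too short for the requested decomposition level",
         call. = FALSE)
  blk <- 2L^level
  npad <- ceiling(n / blk) * blk
  xp <- if (npad > n) c(x, rep(x[n], npad - n)) else x
  dec <- dwtPeriodic(xp, level)
  dec$details <- lapply(dec$details, function(d) {
    sigma <- stats::mad(d)
    if (sigma == 0) return(d)
    thr <- sigma * sqrt(2 * log(length(d)))
    sign(d) * pmax(abs(d) - thr, 0)
  })
  idwtPeriodic(dec)[seq_len(n)]
}

#' Continuous wavelet scalogram (analytic Morlet)
#'
#' Magnitude of the continuous wavelet transform on a logarithmic
#' frequency grid, computed in the Fourier domain with an analytic Morlet
#' wavelet (center frequency `omega0 = 6`). Visualization output.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param fmin,fmax frequency range (Hz).
#' @param voicesPerOctave frequency resolution (>= 10 by default).
#' @return list with `time` (s), `freq` (Hz) and `mag`
#'   (`length(freq)` x `length(x)` magnitude matrix).
#' @export
scalogram <- function(x, fs, fmin = 0.5, fmax = 49, voicesPerOctave = 10) {
  n <- length(x)
  if (n == 0L) stop("empty signal", call. = FALSE)
  omega0 <- 6
  nOct <- log2(fmax / fmin)
  freq <- fmin * 2^(seq(0, nOct, by = 1 / voicesPerOctave))
  scales <- omega0 / (2 * pi * freq)        # in units of samples / fs
  xf <- fft(x)
  w <- 2 * pi * c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / n
  mag <- matrix(0, nrow = length(freq), ncol = n)
  for (i in seq_along(freq)) {
    s <- scales[i] * fs                      # scale in samples
    psi <- ifelse(w > 0, pi^(-0.25) * exp(-((s * w - omega0)^2) / 2), 0)
    wt <- fft(xf * psi * sqrt(s), inverse = TRUE) / n
    mag[i, ] <- Mod(wt)
  }
  list(time = (seq_len(n) - 1) / fs, freq = freq, mag = mag)
}
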