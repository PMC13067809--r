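EPS0 <- 8.8541878128e-12  # vacuum permittivity, F/m

#' Interfacial relaxation time from an impedance spectrum
#'
#' Locates `f_max`, the frequency of the -Im(Z) peak (the apex of the
#' Nyquist semicircle), on the raw frequency grid and returns the
#' relaxation time `tau = 1 / (2 pi f_max)`. An optional quadratic
#' refinement interpolates the apex between grid points; it is off by
#' default so the reported `f_max` is an actual grid frequency.
#'
#' @param spectrum an [ImpedanceSpectrum-class].
#' @param refine logical; quadratic peak interpolation in log-frequency.
#' @return list with `tau` (s), `fMax` (Hz) and `index`; all `NA` (with
#'   a warning) when -Im(Z) has no interior maximum.
#' @export
relaxationTime <- function(spectrum, refine = FALSE) {
  stopifnot(is(spectrum, "ImpedanceSpectrum"))
  y <- -spectrum@zImag
  i <- which.max(y)
  if (i == 1L || i == length(y)) {
    warning("-Im(Z) has no interior maximum; relaxation time undefined")
    return(list(tau = NA_real_, fMax = NA_real_, index = NA_integer_))
  }
  fMax <- spectrum@freq[i]
  if (refine) {
    lf <- log10(spectrum@freq[(i - 1):(i + 1)])
    yy <- y[(i - 1):(i + 1)]
    denom <- (yy[1] - 2 * yy[2] + yy[3])
    if (denom < 0) {
      delta <- 0.5 * (yy[1] - yy[3]) / denom
      fMax <- 10^(lf[2] + delta * (lf[3] - lf[1]) / 2)
    }
  }
  list(tau = 1 / (2 * pi * fMax), fMax = fMax, index = i)
}

#' Convert an impedance spectrum to dielectric quantities
#'
#' Parallel-plate conversion with empty-cell capacitance
#' `C0 = eps0 * area / thickness`: complex relative permittivity
#' `eps* = eps' - i eps'' = 1 / (i w C0 Z*)`, loss tangent
#' `tan(delta) = eps'' / eps'`, and electric modulus
#' `M* = M' + i M'' = 1 / eps* = i w C0 Z*`. The relaxation time and
#' `f_max` from [relaxationTime()] are carried along.
#'
#' @param spectrum an [ImpedanceSpectrum-class].
#' @param area,thickness override the spectrum's cell geometry (m^2, m).
#' @return a [DielectricSpectrum-class].
#' @export
toDielectric <- function(spectrum, area = NULL, thickness = NULL) {
  stopifnot(is(spectrum, "ImpedanceSpectrum"))
  A <- if (is.null(area)) spectrum@area else area
  d <- if (is.null(thickness)) spectrum@thickness else thickness
  if (!length(A) || !length(d) || is.na(A) || is.na(d) || A <= 0 || d <= 0)
    stop("cell geometry (area, thickness) must be set and positive",
         call. = FALSE)
  w <- 2 * pi * spectrum@freq
  C0 <- EPS0 * A / d
  Z <- complex(real = spectrum@zReal, imaginary = spectrum@zImag)
  epsStar <- 1 / (1i * w * C0 * Z)          # = eps' - i eps''
  epsReal <- Re(epsStar)
  epsImag <- -Im(epsStar)
  tanDelta <- ifelse(epsReal > 0, epsImag / epsReal, NA_real_)
  modStar <- 1i * w * C0 * Z                # = M' + i M''
  rt <- suppressWarnings(relaxationTime(spectrum))
  new("DielectricSpectrum", freq = spectrum@freq, epsReal = epsReal,
      epsImag = epsImag, tanDelta = tanDelta, modReal = Re(modStar),
      modImag = Im(modStar), tau = rt$tau, fMax = rt$fMax)
}

#' Mean Nyquist curve with smoothing across replicate spectra
#'
#' Pointwise mean and SD of (Z', -Z'') over replicate spectra sharing a
#' frequency grid (triplicate measurements are the typical use), then
#' moving-average smoothing of the mean curves with the stated window
#' (centered, partial at the edges). `smoothWindow = 1` is the identity.
#'
#' @param spectra list of [ImpedanceSpectrum-class] on one grid.
#' @param smoothWindow moving-average window (points).
#' @return data.frame with `freq`, `zr_mean`, `zr_sd`, `znim_mean`,
#'   `znim_sd`, `zr_smooth`, `znim_smooth`.
#' @export
nyquistCurve <- function(spectra, smoothWindow = 1L) {
  if (is(spectra, "ImpedanceSpectrum")) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1L,
            all(vapply(spectra, is, logical(1), "ImpedanceSpectrum")))
  f0 <- spectra[[1]]@freq
  for (sp in spectra)
    if (length(sp@freq) != length(f0) || any(sp@freq != f0))
      stop("spectra do not share a frequency grid", call. = FALSE)
  zr <- sapply(spectra, function(s) s@zReal)
  zn <- sapply(spectra, function(s) -s@zImag)
  zr <- matrix(zr, nrow = length(f0))
  zn <- matrix(zn, nrow = length(f0))
  sd0 <- function(m) if (ncol(m) > 1L) apply(m, 1, sd) else rep(0, nrow(m))
  sm <- function(x) {
    if (smoothWindow <= 1L) return(x)
    as.numeric(zoo::rollapply(zoo::zoo(x), smoothWindow, mean,
                              partial = TRUE, align = "center"))
  }
  data.frame(freq = f0,
             zr_mean = rowMeans(zr), zr_sd = sd0(zr),
             znim_mean = rowMeans(zn), znim_sd = sd0(zn),
             zr_smooth = sm(rowMeans(zr)), znim_smooth = sm(rowMeans(zn)))
}
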