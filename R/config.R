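#' Default pipeline configuration
#'
#' Aggregates every protocol parameter in one serializable structure:
#' the modality filter chains (ordered step lists with their cutoffs and
#' orders), band definitions, beat-window and clustering parameters
#' (99% PCA variance target, 5 k-means restarts, 1000 iterations,
#' perplexity 30, K = 3 for lead identification and K = 39 for
#' participant identification) and the 200 Hz sampling rate.
#'
#' @return nested named list.
#' @export
defaultConfig <- function() {
  list(
    fs = 200,
    beat_window = 121,
    chains = list(
      ecg = list(
        list(name = "lowpass", cutoff = 90, order = 4),
        list(name = "notch", center = 50, half_width = 1, order = 2),
        list(name = "notch", center = 80, half_width = 1, order = 2),
        list(name = "baseline_ma", window = 1),
        list(name = "reject", variance_win = 2, variance_z = 5)),
      eog = list(
        list(name = "bandpass", lo = 0.1, hi = 15, order = 4),
        list(name = "mean_subtract"),
        list(name = "detrend"),
        list(name = "wavelet_denoise", wavelet = "db4", level = 3),
        list(name = "median", width = 0.05)),
      emg = list(
        list(name = "bandpass", lo = 20, hi = 90, order = 4),
        list(name = "notch", center = 50, half_width = 1, order = 2),
        list(name = "template_subtract", half_width = 0.3),
        list(name = "wavelet_denoise", wavelet = "db4", level = 3)),
      eeg = list(
        list(name = "detrend"),
        list(name = "lowpass", cutoff = 49, order = 4))),
    bands = as.list(setNames(
      mapply(function(lo, hi) c(lo, hi), defaultBands()$lo, defaultBands()$hi,
             SIMPLIFY = FALSE), defaultBands()$name)),
    clustering = list(variance_target = 0.99, restarts = 5, iters = 1000,
                      perplexity = 30, K_lead = 3, K_participant = 39),
    welch = list(win = 2, overlap = 0.5),
    delta = list(win = 2, step = 0.5, band = c(0.5, 4)),
    geometry = list(diameter_m = 0.017, thickness_m = 0.0015)
  )
}

#' Read / write a pipeline configuration (YAML)
#'
#' Configurations round-trip unchanged through serialization.
#'
#' @param config nested list as from [defaultConfig()].
#' @param path YAML file path.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  yaml::read_yaml(path)
}
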