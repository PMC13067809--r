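#' Read and write recordings as CSV plus JSON sidecar
#'
#' A recording is serialized as `<path>.csv` (column 1 = time in s, then
#' one column per lead, mV) and `<path>.json` (sampling rate, lead
#' labels, participant, electrode kind, seed and ground-truth R times
#' when present).
#'
#' @param rec a [Recording-class].
#' @param path file stem (without extension).
#' @return `writeRecording` returns `path` invisibly; `readRecording`
#'   returns a [Recording-class].
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "Recording"))
  n <- ncol(rec@samples)
  df <- data.frame(time_s = (seq_len(n) - 1) / rec@fs)
  for (ld in seq_len(nrow(rec@samples)))
    df[[rec@leadLabels[ld]]] <- as.numeric(rec@samples[ld, ])
  write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  meta <- list(fs = rec@fs, lead_labels = rec@leadLabels,
               participant_id = rec@participantId, electrode = rec@electrode,
               seed = rec@truth$seed, truth_r_times = rec@truth$rTimes)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeRecording
#' @export
readRecording <- function(path) {
  csv <- paste0(path, ".csv")
  df <- read.csv(csv, check.names = FALSE)
  if (ncol(df) < 2L) stop("recording CSV needs time plus >= 1 lead column",
                          call. = FALSE)
  dt <- diff(df[[1]])
  if (any(dt <= 0)) {
    row <- which(dt <= 0)[1] + 1L
    stop(sprintf("non-monotone time column at row %d of %s", row, csv),
         call. = FALSE)
  }
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  truth <- list()
  if (!is.null(meta$truth_r_times)) truth$rTimes <- as.numeric(meta$truth_r_times)
  if (!is.null(meta$seed)) truth$seed <- meta$seed
  new("Recording",
      samples = t(as.matrix(df[, -1, drop = FALSE])),
      fs = as.numeric(meta$fs),
      leadLabels = as.character(meta$lead_labels),
      participantId = as.character(meta$participant_id),
      electrode = as.character(meta$electrode),
      truth = truth)
}

#' Read and write beat batches as CSV
#'
#' One row per beat: the window's value columns `v1..vP` followed by
#' `participant_id`, `lead_id`, `electrode`, `r_time`.
#'
#' @param beats a [BeatMatrix-class].
#' @param path CSV file path.
#' @export
writeBeatMatrix <- function(beats, path) {
  stopifnot(is(beats, "BeatMatrix"))
  vals <- t(beatValues(beats))
  colnames(vals) <- paste0("v", seq_len(ncol(vals)))
  cd <- as.data.frame(SummarizedExperiment::colData(beats))
  df <- cbind(as.data.frame(vals), cd)
  attr(df, "fs") <- samplingRate(beats)
  write.csv(df, path, row.names = FALSE)
  # sidecar keeps fs and R index
  jsonlite::write_json(list(fs = samplingRate(beats), r_index = rIndex(beats)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeBeatMatrix
#' @export
readBeatMatrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vcols <- grep("^v[0-9]+$", colnames(df), value = TRUE)
  beats <- t(as.matrix(df[, vcols, drop = FALSE]))
  rownames(beats) <- NULL
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(beats = beats),
    colData = S4Vectors::DataFrame(df[, setdiff(colnames(df), vcols),
                                      drop = FALSE]),
    metadata = list(fs = as.numeric(meta$fs), rIndex = as.integer(meta$r_index),
                    dropped = 0))
  as(se, "BeatMatrix")
}

#' Read and write impedance spectra as CSV
#'
#' Columns `freq_hz`, `z_real_ohm`, `z_imag_ohm`. Descending frequency
#' grids are auto-sorted on read with a warning.
#'
#' @param spectrum an [ImpedanceSpectrum-class].
#' @param path CSV file path.
#' @param area,thickness cell geometry (m^2, m) attached on read; the
#'   package defaults (1.7 cm diameter disc, 1.5 mm thick) are used with
#'   a warning when omitted.
#' @export
writeImpedance <- function(spectrum, path) {
  stopifnot(is(spectrum, "ImpedanceSpectrum"))
  write.csv(data.frame(freq_hz = spectrum@freq, z_real_ohm = spectrum@zReal,
                       z_imag_ohm = spectrum@zImag), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeImpedance
#' @export
readImpedance <- function(path, area = NULL, thickness = NULL) {
  df <- read.csv(path)
  need <- c("freq_hz", "z_real_ohm", "z_imag_ohm")
  if (!all(need %in% colnames(df)))
    stop("impedance CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.unsorted(df$freq_hz)) {
    warning("frequency grid not ascending; sorting")
    df <- df[order(df$freq_hz), ]
  }
  if (is.null(area)) {
    warning("using default cell geometry (1.7 cm diameter, 1.5 mm thickness)")
    area <- pi * 0.0085^2
  }
  if (is.null(thickness)) thickness <- 1.5e-3
  new("ImpedanceSpectrum", freq = df$freq_hz, zReal = df$z_real_ohm,
      zImag = df$z_imag_ohm, area = area, thickness = thickness)
}

#' Write an experiment report as JSON
#'
#' @param report named list (e.g. from [runLeadIdExperiment()]).
#' @param path output JSON path.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
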