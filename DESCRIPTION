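Package: ElectrodeBench
Title: Benchmarking Skin-Electrode Recordings by Signal Processing, Heartbeat
    Clustering and Dielectric Relaxation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to benchmark wearable electrophysiology electrodes (e.g.
    conducting-hydrogel vs clinical Ag/AgCl) across ECG, EOG, EMG and EEG
    modalities. Provides a synthetic multi-participant cohort generator with
    known ground truth (Gaussian-wave ECG morphology, RR variability, baseline
    wander, powerline interference, motion artifacts and a first-order
    electrode transfer model), modality-specific preprocessing chains
    (Butterworth low-pass/notch/band-pass, moving-average baseline removal,
    Daubechies-4 wavelet denoising, median filtering, variance-based segment
    rejection), Pan-Tompkins R-peak detection with forced R-aligned heartbeat
    batching, unsupervised lead and participant identification (PCA, restarted
    k-means, Hungarian cluster-to-class assignment, accuracy and micro/macro
    F1), waveform morphology and similarity statistics (peak-to-peak and
    landmark amplitudes, maximum normalized cross-correlation, NRMSE),
    variance-based SNR estimation, Welch spectral analysis and band-power
    ratios, and conversion of electrochemical impedance spectra to dielectric
    quantities including the interfacial relaxation time 1/(2*pi*f_max).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    zoo,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
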