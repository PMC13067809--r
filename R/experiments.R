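# End-to-end experiment drivers on simulated cohorts: synthesize ->
# preprocess -> detect R peaks -> batch beats -> PCA -> restarted k-means
# -> Munkres mapping -> metrics and centroid waveforms.

simulateCohortBeats <- function(nParticipants, duration, fs, electrode,
                                noise, seed, leads = 3L) {
  templates <- sampleCohortTemplates(nParticipants, seed = seed)
  em <- if (is(electrode, "ElectrodeModel")) electrode else electrodeModel(electrode)
  batches <- vector("list", nParticipants)
  counts <- data.frame(participant = names(templates), beats = 0L,
                       dropped = 0L)
  for (i in seq_len(nParticipants)) {
    rec <- synthesizeECG(templates[[i]], leads = leads, duration = duration,
                         fs = fs, noise = noise, electrode = em,
                         seed = deriveSeed(seed, i),
                         participantId = names(templates)[i])
    pp <- suppressMessages(ecgChain(rec, mode = "full"))
    rt <- detectRPeaks(pp$recording, lead = min(2L, leads))
    bm <- batchBeats(pp$recording, rt, mask = pp$mask)
    batches[[i]] <- bm
    counts$beats[i] <- ncol(bm)
    counts$dropped[i] <- S4Vectors::metadata(bm)$dropped
  }
  list(beats = combineBeats(batches), counts = counts,
       templates = templates)
}

#' Lead-identification experiment on a simulated cohort
#'
#' Synthesizes a cohort, runs the full ECG chain, detects R peaks,
#' batches 121-sample R-aligned beats, reduces them with PCA (99%
#' variance), clusters with restarted k-means (K = 3, the number of
#' leads), maps clusters to leads with the Munkres assignment and
#' reports accuracy, micro-F1 and macro-F1 together with the
#' inverse-PCA centroid waveforms.
#'
#' @param nParticipants cohort size.
#' @param duration per-participant record length (s).
#' @param fs sampling rate (Hz).
#' @param electrode electrode kind string or [ElectrodeModel-class].
#' @param noise a [NoiseSpec-class].
#' @param seed integer seed controlling every stochastic stage.
#' @param config parameters as from [defaultConfig()].
#' @return report list with `task`, `metrics`, `mapping`, `centroids`
#'   (K x window matrix), `counts`, `k_pca` and `seed`.
#' @export
runLeadIdExperiment <- function(nParticipants = 39L, duration = 60,
                                fs = 200, electrode = "PPHG",
                                noise = noiseSpec(), seed = 1L,
                                config = defaultConfig()) {
  sim <- simulateCohortBeats(nParticipants, duration, fs, electrode, noise,
                             seed)
  beats <- sim$beats
  cl <- config$clustering
  emb <- pcaReduce(beats, cl$variance_target)
  km <- kmeansBest(emb$coords, K = cl$K_lead, restarts = cl$restarts,
                   iters = cl$iters, seed = deriveSeed(seed, 1001))
  truth <- SummarizedExperiment::colData(beats)$lead_id
  mapping <- munkresMap(truth, km$cluster)
  metrics <- clusteringMetrics(truth, km$cluster, mapping)
  list(task = "lead_id",
       metrics = list(accuracy = metrics$accuracy, micro_f1 = metrics$microF1,
                      macro_f1 = metrics$macroF1),
       mapping = as.list(mapping),
       centroids = centroidHeartbeats(km$centers, emb),
       counts = sim$counts, n_beats = ncol(beats), k_pca = emb$k,
       seed = seed)
}

#' Participant-identification experiment on a simulated cohort
#'
#' Same pipeline as [runLeadIdExperiment()] but run independently for
#' each lead, with K set to the number of participants present and
#' clusters mapped to participant identities.
#'
#' @inheritParams runLeadIdExperiment
#' @return report list with per-lead metrics (`per_lead`), counts and
#'   seed.
#' @export
runParticipantIdExperiment <- function(nParticipants = 39L, duration = 60,
                                       fs = 200, electrode = "PPHG",
                                       noise = noiseSpec(), seed = 1L,
                                       config = defaultConfig()) {
  if (nParticipants < 2L)
    stop("participant identification needs at least 2 participants",
         call. = FALSE)
  sim <- simulateCohortBeats(nParticipants, duration, fs, electrode, noise,
                             seed)
  beats <- sim$beats
  cd <- SummarizedExperiment::colData(beats)
  cl <- config$clustering
  perLead <- list()
  for (ld in sort(unique(cd$lead_id))) {
    sel <- cd$lead_id == ld
    sub <- beats[, sel]
    truth <- cd$participant_id[sel]
    K <- length(unique(truth))
    emb <- pcaReduce(sub, cl$variance_target)
    km <- kmeansBest(emb$coords, K = K, restarts = cl$restarts,
                     iters = cl$iters,
                     seed = deriveSeed(seed, 2000 + match(ld, sort(unique(cd$lead_id)))))
    mapping <- munkresMap(truth, km$cluster)
    metrics <- clusteringMetrics(truth, km$cluster, mapping)
    perLead[[ld]] <- list(lead = ld, K = K, n_beats = sum(sel),
                          accuracy = metrics$accuracy,
                          micro_f1 = metrics$microF1,
                          macro_f1 = metrics$macroF1, k_pca = emb$k)
  }
  list(task = "participant_id", per_lead = perLead, counts = sim$counts,
       seed = seed)
}

#' Cohort retention bookkeeping
#'
#' Records the exclusion accounting of a cohort: participants dropped
#' for missing data or bad quality, and the retained set.
#'
#' @param ids character vector of all enrolled participant ids.
#' @param missing ids excluded for missing data.
#' @param badQuality ids excluded for bad data quality.
#' @return list with `retained`, `n_initial`, `n_missing`, `n_bad`,
#'   `n_retained`.
#' @export
cohortRetention <- function(ids, missing = character(), badQuality = character()) {
  stopifnot(!anyDuplicated(ids))
  excluded <- union(missing, badQuality)
  bad <- setdiff(badQuality, missing)
  retained <- setdiff(ids, excluded)
  list(retained = retained, n_initial = length(ids),
       n_missing = length(intersect(missing, ids)),
       n_bad = length(intersect(bad, ids)),
       n_retained = length(retained))
}
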