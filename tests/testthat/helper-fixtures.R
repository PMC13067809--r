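# shared fixture builders

# wrap a numeric vector as a single-lead Recording
vecRecording <- function(x, fs = 200, lead = "I") {
  new("Recording", samples = matrix(x, nrow = 1), fs = fs,
      leadLabels = lead, participantId = "px", electrode = "ideal",
      truth = list())
}

# all permutations of 1..n (n small)
permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in permutations(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

# brute-force optimal injective cluster->class assignment cost
bruteForceAssignmentCost <- function(trueLabels, clusterLabels) {
  clusters <- sort(unique(as.character(clusterLabels)))
  classes <- sort(unique(as.character(trueLabels)))
  counts <- table(factor(clusterLabels, levels = clusters),
                  factor(trueLabels, levels = classes))
  K <- length(clusters); C <- length(classes)
  stopifnot(K <= C)
  best <- Inf
  for (p in permutations(C)) {
    cost <- -sum(counts[cbind(seq_len(K), p[seq_len(K)])])
    if (cost < best) best <- cost
  }
  as.numeric(best)
}

# mean silhouette of a 2-class labelling in a coordinate matrix
meanSilhouette <- function(X, labels) {
  D <- as.matrix(dist(X))
  vapply(seq_len(nrow(X)), function(i) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(nrow(X)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1)) |> mean()
}

# noiseless clean beat train fixture used by several files
cleanRecording <- function(rrMean = 1.0, duration = 30, fs = 200, seed = 2,
                           leads = 1) {
  synthesizeECG(beatTemplate(rrMean = rrMean, rrSd = 0), leads = leads,
                duration = duration, fs = fs, noise = noiseSpec(none = TRUE),
                electrode = electrodeModel("ideal"), seed = seed)
}
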