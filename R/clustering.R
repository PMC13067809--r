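#' PCA reduction of a heartbeat batch
#'
#' Principal component analysis on beats (one observation per beat),
#' retaining the smallest number of leading components whose cumulative
#' explained variance reaches `varianceTarget` (0.99 by default, which on
#' 121-sample heartbeats typically keeps about 10-20 dimensions).
#'
#' @param beats a [BeatMatrix-class] or an n x p matrix with one beat per
#'   row.
#' @param varianceTarget cumulative explained-variance fraction to retain.
#' @return list with `coords` (n x k scores), `basis` (p x k rotation),
#'   `center` (p-vector mean beat), `explainedVar` (per retained
#'   component), `cumVar`, and `k`.
#' @export
pcaReduce <- function(beats, varianceTarget = 0.99) {
  X <- if (is(beats, "BeatMatrix")) t(beatValues(beats)) else as.matrix(beats)
  if (nrow(X) < 2L) stop("need at least 2 beats", call. = FALSE)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  vars <- pc$sdev^2
  tot <- sum(vars)
  if (tot <= .Machine$double.eps * max(1, ncol(X)))
    stop("degenerate input: all beats identical", call. = FALSE)
  evf <- vars / tot
  k <- which(cumsum(evf) >= varianceTarget - 1e-12)[1]
  if (is.na(k)) k <- length(evf)
  list(coords = pc$x[, seq_len(k), drop = FALSE],
       basis = pc$rotation[, seq_len(k), drop = FALSE],
       center = pc$center,
       explainedVar = evf[seq_len(k)],
       cumVar = cumsum(evf)[k],
       k = k)
}

#' Reconstruct beats from reduced coordinates
#'
#' @param coords n x k score matrix.
#' @param embedding result of [pcaReduce()].
#' @return n x p matrix of reconstructed beats.
#' @export
pcaReconstruct <- function(coords, embedding) {
  coords <- as.matrix(coords)
  if (ncol(coords) != ncol(embedding$basis))
    stop("coordinate dimensionality does not match the embedding",
         call. = FALSE)
  sweep(coords %*% t(embedding$basis), 2, embedding$center, "+")
}

# k-means++ seeding: indices of K starting points
kppInit <- function(X, K) {
  n <- nrow(X)
  idx <- integer(K)
  idx[1] <- sample.int(n, 1L)
  if (K == 1L) return(idx)
  d2 <- rowSums(sweep(X, 2, X[idx[1], ], "-")^2)
  for (k in 2:K) {
    tot <- sum(d2)
    idx[k] <- if (tot <= 0) sample.int(n, 1L) else
      sample.int(n, 1L, prob = d2 / tot)
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx[k], ], "-")^2))
  }
  idx
}

#' Restarted k-means keeping the most spread centroid set
#'
#' Runs Lloyd's k-means `restarts` times (default 5) for up to `iters`
#' iterations (default 1000), each restart initialized with a seeded
#' k-means++ draw (first centroid uniform over the data, subsequent ones
#' drawn with probability proportional to squared distance from the
#' nearest chosen centroid), and returns the run maximizing the sum of
#' squared Euclidean distances over all unordered centroid pairs.
#' The ++ seeding spreads initial centroids across the data, avoiding
#' the systematic basin where one well-separated group receives two
#' centroids while two others share one.
#'
#' @param coords n x k coordinate matrix.
#' @param K number of clusters (K <= n).
#' @param restarts,iters restart count and per-run iteration cap.
#' @param seed integer RNG seed.
#' @return list with `centers` (K x k), `cluster` (per-point labels
#'   1..K), `spread` (the selection objective) and `restart` (index of
#'   the winning run).
#' @export
kmeansBest <- function(coords, K, restarts = 5L, iters = 1000L, seed = 1L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (K > n) stop("K must not exceed the number of points", call. = FALSE)
  if (K == 1L) {
    ctr <- matrix(colMeans(coords), 1, ncol(coords))
    return(list(centers = ctr, cluster = rep(1L, n), spread = 0,
                restart = 1L))
  }
  withSeed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      km <- NULL
      for (try in seq_len(50L)) {
        init <- coords[kppInit(coords, K), , drop = FALSE]
        km <- tryCatch(
          suppressWarnings(kmeans(coords, centers = init, iter.max = iters,
                                  algorithm = "Lloyd")),
          error = function(e) NULL)
        if (!is.null(km)) break
      }
      if (is.null(km))
        stop("k-means failed: fewer than K distinct points?", call. = FALSE)
      spread <- sum(dist(km$centers)^2)
      if (is.null(best) || spread > best$spread)
        best <- list(centers = km$centers, cluster = as.integer(km$cluster),
                     spread = spread, restart = r)
    }
    best
  })
}

#' Clustering performance metrics
#'
#' After mapping clusters to classes, computes accuracy
#' `A / N` (A = number of correctly assigned samples), micro-F1
#' `2A / (N + A)`, and macro-F1. Two macro variants are available:
#' `"aggregate"` (the default) averages per-class scores
#' `2 TP_c / (N + TP_c)` that use the global sample count N in each
#' denominator; `"standard"` is the conventional macro-F1 built from
#' per-class precision and recall. Unmapped clusters score as errors.
#'
#' @param trueLabels,clusterLabels equal-length label vectors.
#' @param mapping cluster-to-class mapping from [munkresMap()]; computed
#'   if omitted.
#' @param macro `"aggregate"` or `"standard"`.
#' @return list with `accuracy`, `microF1`, `macroF1`, `N`, `C`,
#'   `perClassTP`, `mapping` and `macroVariant`.
#' @export
clusteringMetrics <- function(trueLabels, clusterLabels, mapping = NULL,
                              macro = c("aggregate", "standard")) {
  macro <- match.arg(macro)
  N <- length(trueLabels)
  if (N == 0L || length(clusterLabels) != N)
    stop("labels must be non-empty and of equal length", call. = FALSE)
  if (is.null(mapping)) mapping <- munkresMap(trueLabels, clusterLabels)
  tr <- as.character(trueLabels)
  mapped <- unname(mapping[as.character(clusterLabels)])
  correct <- !is.na(mapped) & mapped == tr
  A <- sum(correct)
  classes <- sort(unique(tr))
  TPc <- vapply(classes, function(cl) sum(correct & tr == cl), numeric(1))
  macroF1 <- if (macro == "aggregate") {
    mean(2 * TPc / (N + TPc))
  } else {
    pred <- table(factor(mapped, levels = classes))
    act <- table(factor(tr, levels = classes))
    f1 <- mapply(function(tp, p, a) {
      if (p == 0 || a == 0 || tp == 0) return(0)
      pr <- tp / p; rc <- tp / a
      2 * pr * rc / (pr + rc)
    }, TPc, as.numeric(pred), as.numeric(act))
    mean(f1)
  }
  list(accuracy = A / N, microF1 = 2 * A / (N + A), macroF1 = macroF1,
       N = N, C = length(classes), perClassTP = TPc, mapping = mapping,
       macroVariant = macro)
}

#' Inverse-PCA centroid heartbeats
#'
#' Maps k-means centroids from the reduced space back to the original
#' heartbeat space (`waveform = centroid . basis' + mean`), giving one
#' representative beat waveform per cluster.
#'
#' @param centers K x k centroid matrix (e.g. from [kmeansBest()]).
#' @param embedding result of [pcaReduce()].
#' @return K x p matrix of centroid waveforms.
#' @export
centroidHeartbeats <- function(centers, embedding) {
  pcaReconstruct(centers, embedding)
}
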