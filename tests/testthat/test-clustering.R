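test_that("PCA keeps the smallest k reaching the variance target", {
  set.seed(1)
  # beats lying in a 2-D affine subspace plus relative noise power 1e-8
  n <- 200
  b1 <- sin(2 * pi * (1:121) / 121); b2 <- cos(2 * pi * (1:121) / 121)
  X <- outer(rnorm(n), b1) + outer(rnorm(n), b2) +
    matrix(rnorm(n * 121, sd = 1e-4), n, 121) + 0.3
  emb <- pcaReduce(X, 0.99)
  expect_identical(emb$k, 2L)
  # full retention on full-rank data
  Y <- matrix(rnorm(50 * 121), 50, 121)
  expect_identical(pcaReduce(Y, 1.0)$k, 49L)       # min(n - 1, 121)
  # reconstruction error bounded by the discarded variance
  rec <- cleanRecording(rrMean = 0.9, duration = 60, seed = 4)
  noisy <- synthesizeECG(beatTemplate(rrMean = 0.9, rrSd = 0.02), 1, 60, 200,
                         noiseSpec(artifactRate = 0), electrodeModel("PPHG"),
                         seed = 4)
  bm <- batchBeats(noisy, detectRPeaks(noisy))
  B <- t(beatValues(bm))
  e2 <- pcaReduce(B, 0.99)
  recon <- pcaReconstruct(e2$coords, e2)
  Bc <- sweep(B, 2, e2$center)
  relErr <- sqrt(sum((recon - B)^2) / sum(Bc^2))
  expect_lt(relErr, sqrt(1 - 0.99) * 1.01)
  expect_error(pcaReduce(matrix(1, 30, 121)), "degenerate")
})

test_that("restarted k-means recovers well-separated blobs exactly", {
  set.seed(3)
  mu <- rbind(c(0, 0), c(20, 0), c(0, 20))       # separation 20 x SD
  X <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(60 * 2), 60, 2), 2, mu[k, ], "+")))
  truth <- rep(1:3, each = 60)
  km <- kmeansBest(X, K = 3, seed = 5)
  expect_identical(clusteringMetrics(truth, km$cluster)$accuracy, 1)
  # K = 1: single centroid at the global mean
  k1 <- kmeansBest(X, K = 1, seed = 5)
  expect_equal(as.numeric(k1$centers), colMeans(X), tolerance = 1e-9)
  # seed determinism
  expect_identical(kmeansBest(X, K = 3, seed = 7),
                   kmeansBest(X, K = 3, seed = 7))
  expect_error(kmeansBest(X[1:2, ], K = 3), "exceed")
})

test_that("Munkres mapping matches brute-force enumeration for C <= 6", {
  set.seed(8)
  for (C in 2:6) {
    for (rep in 1:10) {
      n <- 120
      truth <- sample(letters[1:C], n, replace = TRUE)
      clus <- sample(seq_len(C), n, replace = TRUE)
      m <- munkresMap(truth, clus)
      expect_identical(attr(m, "totalCost"),
                       bruteForceAssignmentCost(truth, clus))
    }
  }
})

test_that("Munkres handles identity, permutations and documented ties", {
  truth <- rep(letters[1:3], times = c(30, 20, 10))
  expect_identical(unname(munkresMap(truth, truth)[letters[1:3]]),
                   letters[1:3])
  # clusters are a known permutation of classes -> inverse permutation
  perm <- c(b = "c", c = "a", a = "b")
  clus <- unname(perm[truth])
  m <- munkresMap(truth, clus)
  for (cl in names(perm)) expect_identical(unname(m[unname(perm[cl])]), cl)
  # two clusters tied on one class: lowest cluster index wins
  truthT <- c("a", "a", "a", "a", "b", "b", "b", "b")
  clusT <- c(1, 1, 2, 2, 1, 1, 2, 2)     # both clusters co-occur 2x with each
  mt <- munkresMap(truthT, clusT)
  expect_identical(unname(mt["1"]), "a")
  expect_identical(unname(mt["2"]), "b")
  expect_error(munkresMap(character(0), character(0)), "non-empty")
})

test_that("surplus clusters stay unmapped and score as errors", {
  truth <- rep(c("a", "b"), each = 10)
  clus <- c(rep(1, 10), rep(2, 5), rep(3, 5))
  m <- munkresMap(truth, clus)
  expect_identical(sum(is.na(m)), 1L)
  met <- clusteringMetrics(truth, clus, m)
  expect_equal(met$accuracy, 15 / 20)
})

test_that("metric formulas match their printed definitions", {
  # N = 1000 with 762 correct: accuracy 0.762, micro-F1 0.865
  truth <- rep("a", 1000)
  clus <- c(rep("a", 762), rep("b", 238))
  m <- setNames(c("a", "b"), c("a", "b"))
  met <- clusteringMetrics(truth, clus, m)
  expect_equal(met$accuracy, 0.762)
  expect_equal(round(met$microF1, 3), 0.865)
  # all correct
  met2 <- clusteringMetrics(truth, truth)
  expect_identical(met2$accuracy, 1)
  expect_identical(met2$microF1, 1)
  # N=4, C=2, TP=(2,1): aggregate macro = (2*2/6 + 2*1/5)/2
  truth3 <- c("a", "a", "b", "b")
  clus3 <- c(1, 1, 2, 1)
  met3 <- clusteringMetrics(truth3, clus3)
  expect_equal(met3$macroF1, (2 * 2 / 6 + 2 * 1 / 5) / 2)
  # the standard macro variant differs and uses precision/recall
  met4 <- clusteringMetrics(truth3, clus3, macro = "standard")
  pA <- 2 / 3; rA <- 1; f1A <- 2 * pA * rA / (pA + rA)
  pB <- 1; rB <- 1 / 2; f1B <- 2 * pB * rB / (pB + rB)
  expect_equal(met4$macroF1, (f1A + f1B) / 2)
  expect_error(clusteringMetrics(character(0), character(0)), "non-empty")
})

test_that("micro-F1 equals 2a/(1+a) on random label sets", {
  set.seed(12)
  for (i in 1:50) {
    n <- sample(20:200, 1)
    C <- sample(2:6, 1)
    truth <- sample(letters[1:C], n, replace = TRUE)
    clus <- sample(seq_len(C), n, replace = TRUE)
    met <- clusteringMetrics(truth, clus)
    a <- met$accuracy
    expect_equal(met$microF1, 2 * a / (1 + a), tolerance = 1e-12)
  }
})

test_that("centroid waveforms are the inverse-PCA images of centroids", {
  rec <- cleanRecording(rrMean = 0.9, duration = 40, seed = 4, leads = 3)
  bm <- batchBeats(rec, truthRTimes(rec))
  emb <- pcaReduce(bm, 0.99)
  # centroid = mean of a pure cluster's coords -> mean beat of the cluster
  lead <- beatLabels(bm)$lead_id
  sel <- lead == "II"
  ctr <- colMeans(emb$coords[sel, , drop = FALSE])
  wf <- centroidHeartbeats(matrix(ctr, 1), emb)
  meanBeat <- rowMeans(beatValues(bm)[, sel])
  expect_lt(max(abs(wf - meanBeat)), 0.01 * diff(range(meanBeat)))
  # zero-vector centroid -> embedding mean; K = 1 -> grand mean beat
  wf0 <- centroidHeartbeats(matrix(0, 1, emb$k), emb)
  expect_equal(as.numeric(wf0), unname(emb$center), tolerance = 1e-12)
  km <- kmeansBest(emb$coords, K = 1, seed = 2)
  wf1 <- centroidHeartbeats(km$centers, emb)
  expect_equal(as.numeric(wf1), unname(rowMeans(beatValues(bm))),
               tolerance = 1e-9)
  expect_error(centroidHeartbeats(matrix(0, 1, emb$k + 1), emb), "dimension")
})

test_that("t-SNE is seed-deterministic and separates distant blobs", {
  set.seed(5)
  X <- rbind(matrix(rnorm(60 * 5), 60, 5),
             matrix(rnorm(60 * 5, mean = 25), 60, 5))
  labels <- rep(1:2, each = 60)
  Y1 <- tsneProject(X, perplexity = 15, seed = 3, maxIter = 300)
  Y2 <- tsneProject(X, perplexity = 15, seed = 3, maxIter = 300)
  expect_identical(Y1, Y2)
  expect_gt(meanSilhouette(Y1, labels), 0.5)
  expect_error(tsneProject(X[1:10, ], perplexity = 30), "perplexity")
})
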