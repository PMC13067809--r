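#' t-SNE projection for visualization
#'
#' Exact (non-approximate) t-distributed stochastic neighbor embedding of
#' the PCA-reduced coordinates into 2-D, with Euclidean input distances,
#' a given perplexity (protocol default 30), early exaggeration and
#' momentum gradient descent. Intended for visual inspection of cluster
#' structure at moderate n (the O(n^2) exact gradient is deliberate);
#' deterministic for a fixed seed.
#'
#' @param coords n x k input coordinates; requires `n > 3 * perplexity`.
#' @param perplexity effective neighborhood size.
#' @param seed integer RNG seed.
#' @param maxIter gradient-descent iterations.
#' @param eta learning rate.
#' @return n x 2 embedding matrix.
#' @export
tsneProject <- function(coords, perplexity = 30, seed = 1L, maxIter = 500L,
                        eta = 200) {
  X <- as.matrix(coords)
  n <- nrow(X)
  if (n <= 3 * perplexity)
    stop("need more than 3 * perplexity points", call. = FALSE)

  # pairwise squared distances
  ss <- rowSums(X^2)
  D2 <- outer(ss, ss, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  diag(D2) <- Inf

  # per-point precision by binary search to the target entropy
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in seq_len(60L)) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { beta <- beta / 2; next }
      H <- log(sp) + beta * sum(di * p) / sp
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  withSeed(seed, {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    dY <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    exag <- 12
    for (iter in seq_len(maxIter)) {
      Pe <- if (iter <= 100L) P * exag else P
      ssy <- rowSums(Y^2)
      num <- 1 / (1 + outer(ssy, ssy, "+") - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      momentum <- if (iter < 250L) 0.5 else 0.8
      gains <- pmax(0.01, ifelse(sign(grad) != sign(dY), gains + 0.2,
                                 gains * 0.8))
      dY <- momentum * dY - eta * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}
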