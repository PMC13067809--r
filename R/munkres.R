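# Hungarian (Kuhn-Munkres) solver for the cluster-to-class assignment.
# Shortest-augmenting-path formulation with dual potentials, O(n^3).

# cost: n x m numeric, n <= m; returns for each row the assigned column.
solveAssignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  u <- numeric(n + 1)          # row potentials, index i+1 (i = 0..n)
  v <- numeric(m + 1)          # column potentials, index j+1 (j = 0..m)
  p <- integer(m + 1)          # p[j+1]: row matched to column j, 0 = free
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  assign
}

#' Optimal cluster-to-class mapping (Munkres assignment)
#'
#' Builds the cost matrix by assigning a negative cost to each
#' cluster-class pair for every sample in which they co-occur
#' (`cost = -co-occurrence count`) and solves the assignment problem
#' minimizing total cost with the Hungarian algorithm. Ties between
#' equally good assignments are broken deterministically in favor of the
#' lowest cluster index: each cluster's best class cell receives a
#' sub-integer bonus that decreases with cluster index and is too small
#' to overturn any strict cost difference.
#'
#' When there are more clusters than classes the surplus clusters remain
#' unmapped (`NA`) and score as errors downstream.
#'
#' @param trueLabels,clusterLabels equal-length label vectors.
#' @return named character vector: `mapping[cluster] = class` (`NA` for
#'   unmapped clusters), with the total assignment cost (on the unbiased
#'   integer costs) in `attr(, "totalCost")`.
#' @export
munkresMap <- function(trueLabels, clusterLabels) {
  if (!length(trueLabels) || length(trueLabels) != length(clusterLabels))
    stop("labels must be non-empty and of equal length", call. = FALSE)
  clusters <- sort(unique(as.character(clusterLabels)))
  classes <- sort(unique(as.character(trueLabels)))
  K <- length(clusters); C <- length(classes)
  counts <- table(factor(clusterLabels, levels = clusters),
                  factor(trueLabels, levels = classes))
  cost <- -matrix(as.numeric(counts), nrow = K, ncol = C)
  # lowest-cluster-index tie-break bias (cannot flip integer gaps)
  eps <- 0.4 / (K * K + 1)
  biased <- cost
  for (i in seq_len(K)) {
    best <- which.max(counts[i, ])        # lowest class index on ties
    biased[i, best] <- biased[i, best] - (K - i + 1L) * eps
  }
  if (K > C) biased <- cbind(biased, matrix(0, nrow = K, ncol = K - C))
  assign <- solveAssignment(biased)
  mapping <- setNames(rep(NA_character_, K), clusters)
  ok <- assign >= 1L & assign <= C
  mapping[ok] <- classes[assign[ok]]
  total <- sum(vapply(seq_len(K)[ok], function(i) cost[i, assign[i]],
                      numeric(1)))
  attr(mapping, "totalCost") <- total
  mapping
}
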