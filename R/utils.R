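# internal helpers shared across modules

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic derived seed streams; kept below 2^31.
deriveSeed <- function(seed, k) {
  (as.numeric(seed) * 1103515245 + 12345 * as.numeric(k)) %% 2147483647
}

# Truncated normal draw by rejection (bounds in SD units around the mean).
rnormTrunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- rnorm(length(need), mean, sd)
    ok <- x >= lower & x <= upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

hannWindow <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

hammingWindow <- function(n) {
  if (n == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

# signal vector from a Recording channel (by index or label)
leadVector <- function(rec, lead = 1L) {
  if (is.character(lead)) lead <- match(lead, rec@leadLabels)
  as.numeric(rec@samples[lead, ])
}

stopifnotScalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (positive && x <= 0))
    stop(sprintf("'%s' must be a single %s number", name,
                 if (positive) "positive" else "finite"), call. = FALSE)
  invisible(x)
}
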