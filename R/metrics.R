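## Scalar summary metrics for parameter-space maps, and multiscale entropy.

#' Global variance of a simulated time series
#'
#' Zero-centers every individual time series (each svar x node x mode
#' combination) and returns the population variance over all data points of
#' the rank-4 array. A scalar summary of overall fluctuation amplitude used
#' to map collective dynamics across parameter space.
#'
#' @param result a [TimeSeriesResult-class] or a rank-4 array.
#' @return non-negative scalar.
#' @export
globalVariance <- function(result) {
  x <- if (is(result, "TimeSeriesResult")) result@data else result
  if (length(x) == 0) stop("empty input")
  d <- dim(x)
  flat <- matrix(x, nrow = d[1])             # time x (svar*space*mode)
  centered <- sweep(flat, 2, colMeans(flat))
  sum(centered^2) / length(centered)
}

#' Variance of the node variances
#'
#' Zero-centers the output, concatenates each node's state-variable and
#' mode series over time, takes the variance of that concatenation per
#' node, and returns the (population) variance of the per-node variances: a
#' measure of how heterogeneous the nodes' temporal variability is.
#'
#' @param result a [TimeSeriesResult-class] or a rank-4 array
#'   `[time, svar, space, modes]`.
#' @return non-negative scalar.
#' @export
varianceOfNodeVariances <- function(result) {
  x <- if (is(result, "TimeSeriesResult")) result@data else result
  d <- dim(x)
  if (d[3] < 2) stop("at least 2 nodes are required")
  nodeVar <- vapply(seq_len(d[3]), function(i) {
    series <- x[, , i, , drop = FALSE]       # [time, svar, 1, modes]
    flat <- matrix(series, nrow = d[1])
    centered <- sweep(flat, 2, colMeans(flat))
    sum(centered^2) / length(centered)
  }, numeric(1))
  mean((nodeVar - mean(nodeVar))^2)
}

#' Coarse-grain a series for multiscale entropy
#'
#' Means over consecutive non-overlapping windows of `scale` samples
#' (scale 1 is the identity).
#'
#' @param series numeric vector.
#' @param scale window length (>= 1).
#' @export
coarseGrain <- function(series, scale) {
  scale <- as.integer(scale)
  if (scale < 1) stop("scale must be >= 1")
  if (scale == 1) return(series)
  nwin <- length(series) %/% scale
  if (nwin < 1) stop("series shorter than one window")
  colMeans(matrix(series[seq_len(nwin * scale)], nrow = scale))
}

#' Sample entropy
#'
#' `SampEn(m, r) = -log(A / B)` where `B` counts template pairs of length
#' `m` within Chebyshev distance `r` and `A` those of length `m + 1`.
#' Self-matches are excluded. A constant series yields 0 (all templates
#' match at both lengths).
#'
#' @param series numeric vector.
#' @param m template length.
#' @param r tolerance (absolute units).
#' @return non-negative scalar; `NaN` when no length-m matches exist.
#' @export
sampleEntropy <- function(series, m = 2, r = 0.15 * sd(series)) {
  n <- length(series)
  if (n < m + 2) stop("series too short: need at least ", m + 2, " samples")
  count <- function(len) {
    nt <- n - m                      # same template count for m and m + 1
    tem <- matrix(0, nt, len)
    for (k in seq_len(len)) tem[, k] <- series[k:(k + nt - 1L)]
    tot <- 0
    for (i in seq_len(nt - 1L)) {
      rest <- tem[(i + 1L):nt, , drop = FALSE]
      dmax <- abs(rest[, 1] - tem[i, 1])
      if (len > 1) for (k in 2:len)
        dmax <- pmax(dmax, abs(rest[, k] - tem[i, k]))
      tot <- tot + sum(dmax <= r)
    }
    tot
  }
  B <- count(m)
  A <- count(m + 1)
  if (B == 0) return(NaN)
  if (A == 0) return(Inf)
  -log(A / B)
}

#' Multiscale entropy
#'
#' Sample entropy of coarse-grained versions of the series across temporal
#' scales. The tolerance is `r * SD` of the original (scale-1) series and
#' is held fixed across scales, following the standard convention; defaults
#' `m = 2`, `r = 0.15`.
#'
#' @param series numeric vector.
#' @param scales number of scales (1..scales).
#' @param m template length.
#' @param r tolerance as a fraction of the series SD.
#' @return numeric vector of per-scale entropies.
#' @export
multiscaleEntropy <- function(series, scales = 5, m = 2, r = 0.15) {
  need <- 10 * (m + 1) * scales
  if (length(series) < need)
    stop("series too short for ", scales, " scales: need at least ", need,
         " samples, got ", length(series))
  tol <- r * sd(series)
  if (tol == 0) tol <- 0   # constant series: all templates match -> 0
  vapply(seq_len(scales), function(sc)
    sampleEntropy(coarseGrain(series, sc), m = m, r = tol), numeric(1))
}
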