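## Spatiotemporal stimulation: temporal profile functions combined with
## per-node (region) or per-vertex (surface) spatial weights. The evaluated
## pattern factorizes exactly: value(node, t) = weight[node] * temporal(t).

#' Spatiotemporal stimulation pattern
#'
#' @slot temporal function of time (ms) returning the stimulus amplitude.
#' @slot spatialWeights per-node (region mode) or per-vertex (surface mode)
#'   intensity weighting.
#' @slot focalPoints integer vertex indices the spatial profile was built
#'   from (surface mode; empty for region stimuli).
#' @export
setClass("StimulusPattern",
  representation(temporal = "function", spatialWeights = "numeric",
                 focalPoints = "integer"))

setValidity("StimulusPattern", function(object) {
  if (any(!is.finite(object@spatialWeights)))
    return("spatial weights must be finite")
  TRUE
})

setMethod("show", "StimulusPattern", function(object) {
  cat("StimulusPattern over", length(object@spatialWeights), "nodes;",
      sum(object@spatialWeights != 0), "receive the stimulus\n")
})

#' Rectangular pulse train
#'
#' Amplitude `amplitude` during `[onset + k * period, onset + k * period +
#' width)` for k = 0, 1, ..., zero elsewhere (half-open pulses, so sampling
#' on a step grid is unambiguous).
#'
#' @param t time (ms), vectorized.
#' @param onset first pulse onset (ms).
#' @param width pulse width (ms), `< period`.
#' @param period repetition period (ms).
#' @param amplitude pulse height.
#' @return numeric vector of amplitudes, same length as `t`.
#' @export
pulseTrain <- function(t, onset = 0, width = 5, period = 1000,
                       amplitude = 1) {
  if (period <= 0) stop("period must be positive")
  if (width >= period) stop("width must be smaller than period")
  phase <- (t - onset) %% period
  ifelse(t >= onset & phase < width, amplitude, 0)
}

#' @describeIn pulseTrain partially applied form: returns a function of time
#'   suitable for the `temporal` slot of a stimulus.
#' @export
pulseTrainFunction <- function(onset = 0, width = 5, period = 1000,
                               amplitude = 1) {
  if (width >= period) stop("width must be smaller than period")
  function(t) pulseTrain(t, onset, width, period, amplitude)
}

#' Gaussian spatial profile of distance
#'
#' `amplitude * exp(-dist^2 / (2 sigma^2))` for `dist <= cutoff`, exactly 0
#' beyond the cutoff (finite spatial support).
#'
#' @param dist distance (mm), vectorized.
#' @param amplitude peak value at distance 0.
#' @param sigma spatial width (mm).
#' @param cutoff support radius (mm).
#' @export
gaussianProfile <- function(dist, amplitude = 1, sigma = 5, cutoff = 3 * sigma)
  ifelse(dist <= cutoff, amplitude * exp(-dist^2 / (2 * sigma^2)), 0)

#' Evaluate a spatial profile on a mesh from focal points
#'
#' Each vertex gets the profile of its distance to the nearest focal point;
#' with `combine = "max"` (default) overlapping kernels do not add up, with
#' `"sum"` they do. Distances are Euclidean.
#'
#' @param mesh a mesh as returned by [triangularMesh()] (list with a
#'   `vertices` matrix).
#' @param focalPoints integer vertex indices.
#' @param equation profile function of distance (mm), e.g.
#'   [gaussianProfile()].
#' @param combine `"max"` or `"sum"` across focal points.
#' @return numeric per-vertex weights.
#' @export
spatialProfile <- function(mesh, focalPoints, equation = gaussianProfile,
                           combine = c("max", "sum")) {
  combine <- match.arg(combine)
  v <- mesh$vertices
  focalPoints <- as.integer(focalPoints)
  if (any(focalPoints < 1 | focalPoints > nrow(v)))
    stop("focal point index out of range [1, ", nrow(v), "]")
  per <- sapply(focalPoints, function(fp) {
    d <- sqrt(rowSums((v - matrix(v[fp, ], nrow(v), 3, byrow = TRUE))^2))
    equation(d)
  })
  per <- matrix(per, nrow = nrow(v))
  if (combine == "max") apply(per, 1, max) else rowSums(per)
}

#' Region-level stimulus from a weighting vector
#'
#' Region nodes have no spatial extent, so a region stimulus is purely time
#' dependent with per-node intensity weights.
#'
#' @param weighting numeric per-node weights (length = number of regions).
#' @param temporal function of time (ms), e.g. [pulseTrainFunction()].
#' @return a [StimulusPattern-class].
#' @export
regionStimulus <- function(weighting, temporal) {
  new("StimulusPattern", temporal = temporal,
      spatialWeights = as.numeric(weighting), focalPoints = integer(0))
}

#' Surface stimulus from focal points and a spatial profile
#'
#' @param mesh a [triangularMesh()].
#' @param focalPoints integer vertex indices.
#' @param temporal function of time (ms).
#' @param equation spatial profile function of distance.
#' @param combine how overlapping kernels combine; see [spatialProfile()].
#' @return a [StimulusPattern-class] with per-vertex weights.
#' @export
surfaceStimulus <- function(mesh, focalPoints, temporal,
                            equation = gaussianProfile,
                            combine = c("max", "sum")) {
  w <- spatialProfile(mesh, focalPoints, equation, combine)
  new("StimulusPattern", temporal = temporal, spatialWeights = w,
      focalPoints = as.integer(focalPoints))
}

#' Evaluate a stimulus pattern
#'
#' @param pattern a [StimulusPattern-class].
#' @param t time (ms, scalar).
#' @return per-node stimulus values `spatialWeights * temporal(t)`.
#' @export
evaluateStimulus <- function(pattern, t)
  pattern@spatialWeights * pattern@temporal(t)
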