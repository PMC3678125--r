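## Long-range coupling functions: elementwise transforms applied to the
## weighted sum of delayed afferent activity before it enters a node's
## equations.

#' Long-range coupling function
#'
#' Rescales the aggregated delayed input to a level appropriate for the
#' population model. The transform is applied elementwise to the weighted
#' sum over afferents (post-aggregation; see the methods vignette for the
#' pre-summation alternative).
#'
#' @slot kind `"linear"` or `"sigmoidal"`.
#' @slot a,b linear transform `a * x + b`.
#' @slot cmin,cmax,midpoint,steepness sigmoidal transform
#'   `cmin + (cmax - cmin) / (1 + exp(-steepness * (x - midpoint)))`.
#' @export
setClass("CouplingSpec",
  representation(kind = "character", a = "numeric", b = "numeric",
                 cmin = "numeric", cmax = "numeric", midpoint = "numeric",
                 steepness = "numeric"))

setValidity("CouplingSpec", function(object) {
  if (!object@kind %in% c("linear", "sigmoidal"))
    return("kind must be 'linear' or 'sigmoidal'")
  if (object@kind == "sigmoidal") {
    if (object@cmax < object@cmin) return("cmax must be >= cmin")
    if (object@steepness <= 0) return("steepness must be positive")
  }
  TRUE
})

setMethod("show", "CouplingSpec", function(object) {
  if (object@kind == "linear")
    cat(sprintf("Linear coupling: %g * x + %g\n", object@a, object@b))
  else
    cat(sprintf(
      "Sigmoidal coupling: [%g, %g], midpoint %g, steepness %g\n",
      object@cmin, object@cmax, object@midpoint, object@steepness))
})

#' @rdname CouplingSpec-class
#' @param a slope (often the global coupling strength `gcs`).
#' @param b offset.
#' @export
linearCoupling <- function(a = 1, b = 0) {
  new("CouplingSpec", kind = "linear", a = a, b = b,
      cmin = 0, cmax = 1, midpoint = 0, steepness = 1)
}

#' @rdname CouplingSpec-class
#' @param cmin,cmax output range of the sigmoid.
#' @param midpoint input at which the output is `(cmin + cmax) / 2`.
#' @param steepness slope parameter (> 0).
#' @export
sigmoidalCoupling <- function(cmin = 0, cmax = 1, midpoint = 0,
                              steepness = 1) {
  new("CouplingSpec", kind = "sigmoidal", a = 1, b = 0, cmin = cmin,
      cmax = cmax, midpoint = midpoint, steepness = steepness)
}

#' Apply a coupling function to aggregated afferent activity
#'
#' @param aggregate numeric array: per-node weighted sums of delayed
#'   coupling-variable states.
#' @param spec a [CouplingSpec-class].
#' @return array of the same shape.
#' @export
applyCoupling <- function(aggregate, spec) {
  stopifnot(is(spec, "CouplingSpec"))
  if (spec@kind == "linear") {
    spec@a * aggregate + spec@b
  } else {
    spec@cmin + (spec@cmax - spec@cmin) /
      (1 + exp(-spec@steepness * (aggregate - spec@midpoint)))
  }
}
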