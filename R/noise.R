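## Independently seedable random streams and the noise processes feeding the
## stochastic integration schemes.

#' Create an independently seeded random stream
#'
#' A stream is an environment carrying its own `.Random.seed`, so multiple
#' streams can be drawn from independently and reproducibly without touching
#' the session RNG. Streams use R's default Mersenne-Twister generator.
#'
#' @param seed integer seed.
#' @return an object of class `rng_stream`.
#' @export
makeStream <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$seed <- as.integer(seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(env$seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  class(env) <- "rng_stream"
  env
}

## Evaluate a drawing expression under the stream's RNG state.
.withStream <- function(stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", stream$state, globalenv())
  on.exit({
    stream$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  expr
}

#' @describeIn makeStream `n` standard normal draws from the stream.
#' @param stream an `rng_stream`.
#' @param n number of draws.
#' @export
streamNorm <- function(stream, n) .withStream(stream, rnorm(n))

#' @describeIn makeStream `n` uniform draws on `[min, max)` from the stream.
#' @param min,max uniform bounds.
#' @export
streamUnif <- function(stream, n, min = 0, max = 1)
  .withStream(stream, runif(n, min, max))

#' @describeIn makeStream snapshot of the stream state (for continuation).
#' @export
streamState <- function(stream) stream$state

#' @describeIn makeStream restore a previously saved state.
#' @param state a state returned by `streamState()`.
#' @export
setStreamState <- function(stream, state) {
  stream$state <- state
  invisible(stream)
}

#' Noise process specification for stochastic integration
#'
#' White noise contributes independent Gaussian increments of variance
#' `2 * D * dt` per step and state variable. Colored noise is an
#' Ornstein-Uhlenbeck process with correlation time `tau` advanced by its
#' exact update (`x' = x * exp(-dt/tau) + sqrt(D/tau * (1 - exp(-2 dt/tau)))
#' * xi`), contributing `x * dt` per step; its lag-k autocorrelation is
#' `exp(-k dt / tau)` for any dt. A multiplicative process scales the
#' increment by a function `g` of the current state (default `g(x) = x`).
#'
#' @slot kind `"additive"` or `"multiplicative"`.
#' @slot color `"white"` or `"colored"`.
#' @slot intensity noise intensity `D`, one value per state variable
#'   (recycled).
#' @slot tau correlation time in ms (colored noise).
#' @slot gfun state-dependence of multiplicative noise.
#' @slot cache environment holding the Ornstein-Uhlenbeck state between
#'   steps (reference semantics, so continuation resumes the process).
#' @export
setClass("NoiseSpec",
  representation(kind = "character", color = "character",
                 intensity = "numeric", tau = "numeric", gfun = "function",
                 cache = "environment"))

setValidity("NoiseSpec", function(object) {
  if (!object@kind %in% c("additive", "multiplicative"))
    return("kind must be 'additive' or 'multiplicative'")
  if (!object@color %in% c("white", "colored"))
    return("color must be 'white' or 'colored'")
  if (any(object@intensity < 0)) return("intensity D must be >= 0")
  if (object@color == "colored" && object@tau <= 0)
    return("correlation time tau must be positive for colored noise")
  TRUE
})

setMethod("show", "NoiseSpec", function(object) {
  cat(sprintf("%s %s noise, D = %s%s\n", object@color, object@kind,
              paste(object@intensity, collapse = "/"),
              if (object@color == "colored")
                sprintf(", tau = %g ms", object@tau) else ""))
})

#' @rdname NoiseSpec-class
#' @param intensity noise intensity `D` (scalar or per state variable).
#' @param color `"white"` or `"colored"`.
#' @param tau correlation time (ms), colored noise only.
#' @export
additiveNoise <- function(intensity = 1e-5, color = "white", tau = 10) {
  new("NoiseSpec", kind = "additive", color = color,
      intensity = intensity, tau = tau, gfun = identity,
      cache = new.env(parent = emptyenv()))
}

#' @rdname NoiseSpec-class
#' @param gfun state-dependence `g(x)` multiplying the increment.
#' @export
multiplicativeNoise <- function(intensity = 1e-5, color = "white",
                                tau = 10, gfun = identity) {
  new("NoiseSpec", kind = "multiplicative", color = color,
      intensity = intensity, tau = tau, gfun = gfun,
      cache = new.env(parent = emptyenv()))
}

#' Draw one noise increment
#'
#' Returns the raw additive increment for one integration step; the
#' integrator applies the multiplicative state factor when required. A zero
#' intensity short-circuits to an exact zero array without consuming random
#' numbers, so a stochastic scheme with `D = 0` reproduces its deterministic
#' counterpart bit for bit.
#'
#' @param shape integer dimensions `[nodes, svars, modes]` of the increment.
#' @param dt step size (ms).
#' @param spec a [NoiseSpec-class].
#' @param stream an `rng_stream` supplying the Gaussian draws.
#' @return numeric array of dimension `shape`.
#' @export
noiseIncrement <- function(shape, dt, spec, stream) {
  stopifnot(is(spec, "NoiseSpec"))
  .assertScalarNumeric(dt, "dt", positive = TRUE)
  if (any(spec@intensity < 0)) stop("intensity D must be >= 0")
  ntot <- prod(shape)
  if (all(spec@intensity == 0))
    return(array(0, dim = shape))
  ## per-svar intensity broadcast over [nodes, svars, modes]
  D <- array(rep(rep(spec@intensity, length.out = shape[2]),
                 each = shape[1]), dim = shape)
  if (spec@color == "white") {
    xi <- array(streamNorm(stream, ntot), dim = shape)
    sqrt(2 * D * dt) * xi
  } else {
    rho <- exp(-dt / spec@tau)
    sig <- sqrt(D / spec@tau * (1 - rho^2))
    cache <- spec@cache
    if (is.null(cache$ou) || !identical(dim(cache$ou), as.integer(shape))) {
      ## start from the stationary distribution
      cache$ou <- array(sqrt(D / spec@tau) * streamNorm(stream, ntot),
                        dim = shape)
    }
    xi <- array(streamNorm(stream, ntot), dim = shape)
    cache$ou <- rho * cache$ou + sig * xi
    cache$ou * dt
  }
}
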