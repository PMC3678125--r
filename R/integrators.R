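## Fixed-step deterministic and stochastic time-stepping schemes, applicable
## to any model derivative function with frozen per-step inputs.

#' Integration scheme specification
#'
#' @slot scheme `"euler"`, `"heun"` or `"rk4"`.
#' @slot stochastic logical; RK4 is deterministic-only (stochastic
#'   Runge-Kutta variants with reliable convergence are not provided).
#' @slot dt step size in ms.
#' @slot noise a [NoiseSpec-class] (stochastic schemes only).
#' @export
setClass("IntegratorSpec",
  representation(scheme = "character", stochastic = "logical",
                 dt = "numeric", noise = "ANY"))

setValidity("IntegratorSpec", function(object) {
  if (!object@scheme %in% c("euler", "heun", "rk4"))
    return("scheme must be euler, heun or rk4")
  if (object@dt <= 0) return("dt must be positive")
  if (object@scheme == "rk4" && object@stochastic)
    return("rk4 is available for deterministic integration only")
  if (object@stochastic && !is(object@noise, "NoiseSpec"))
    return("stochastic integration requires a NoiseSpec")
  TRUE
})

setMethod("show", "IntegratorSpec", function(object) {
  cat(sprintf("%s%s integrator, dt = %g ms\n",
              if (object@stochastic) "stochastic " else "",
              object@scheme, object@dt))
})

#' @rdname IntegratorSpec-class
#' @param dt step size (ms). The schemes are routinely used with
#'   `dt` between 2^-2 and 2^-6 ms for neural mass networks.
#' @param noise optional [NoiseSpec-class]; supplying one makes the scheme
#'   stochastic (Euler-Maruyama / stochastic Heun).
#' @export
eulerIntegrator <- function(dt = 0.0625, noise = NULL) {
  new("IntegratorSpec", scheme = "euler", stochastic = !is.null(noise),
      dt = dt, noise = noise)
}

#' @rdname IntegratorSpec-class
#' @export
heunIntegrator <- function(dt = 0.0625, noise = NULL) {
  new("IntegratorSpec", scheme = "heun", stochastic = !is.null(noise),
      dt = dt, noise = noise)
}

#' @rdname IntegratorSpec-class
#' @export
rk4Integrator <- function(dt = 0.0625) {
  new("IntegratorSpec", scheme = "rk4", stochastic = FALSE, dt = dt,
      noise = NULL)
}

#' Advance the state by one integration step
#'
#' Inputs to the derivative are frozen for the step, so `deriv` is a
#' function of the state alone. Stochastic Heun uses the same Wiener
#' increment in predictor and corrector (Stratonovich-consistent), which
#' makes the zero-intensity stochastic scheme coincide bit for bit with the
#' deterministic one.
#'
#' @param state numeric array `[nodes, svars, modes]` (any array works for
#'   plain ODE use).
#' @param deriv function of the state returning its time derivative, same
#'   shape.
#' @param spec an [IntegratorSpec-class].
#' @param stream `rng_stream` used by stochastic schemes.
#' @param noise optional precomputed additive increment array (same shape as
#'   `state`); overrides drawing from the stream. Intended for strong-order
#'   tests and externally supplied noise paths.
#' @return the state after one step, same shape.
#' @export
integrateStep <- function(state, deriv, spec, stream = NULL, noise = NULL) {
  stopifnot(is(spec, "IntegratorSpec"))
  dt <- spec@dt
  n <- 0
  mult <- NULL
  if (spec@stochastic || !is.null(noise)) {
    if (is.null(noise)) {
      shape <- dim(state)
      if (is.null(shape)) shape <- c(length(state), 1L, 1L)
      noise <- noiseIncrement(shape, dt, spec@noise, stream)
      dim(noise) <- dim(state) %||% length(state)
      if (spec@noise@kind == "multiplicative")
        mult <- spec@noise@gfun
    }
    n <- noise
  }
  switch(spec@scheme,
    euler = {
      if (!is.null(mult)) n <- n * mult(state)
      state + dt * deriv(state) + n
    },
    heun = {
      f0 <- deriv(state)
      if (!is.null(mult)) n <- n * mult(state)
      pred <- state + dt * f0 + n
      state + dt / 2 * (f0 + deriv(pred)) + n
    },
    rk4 = {
      k1 <- deriv(state)
      k2 <- deriv(state + dt / 2 * k1)
      k3 <- deriv(state + dt / 2 * k2)
      k4 <- deriv(state + dt * k3)
      state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    })
}

#' Empirical convergence order of a scheme
#'
#' Integrates `dy/dt = -y`, `y(0) = 1` over 1 ms at `dt` and `dt/2` and
#' returns the Richardson estimate `log2(e(dt) / e(dt/2))` of the global
#' order against the exact solution `exp(-t)`.
#'
#' @param scheme `"euler"`, `"heun"` or `"rk4"`.
#' @param dt coarse step size (ms); must divide 1 ms evenly.
#' @return estimated order (about 1, 2 and 4 for the three schemes).
#' @export
convergenceOrder <- function(scheme, dt = 0.1) {
  runTo1 <- function(h) {
    spec <- switch(scheme, euler = eulerIntegrator(h),
                   heun = heunIntegrator(h), rk4 = rk4Integrator(h),
                   stop("unknown scheme: ", scheme))
    y <- 1
    for (i in seq_len(round(1 / h))) y <- integrateStep(y, function(x) -x, spec)
    y
  }
  e1 <- abs(runTo1(dt) - exp(-1))
  e2 <- abs(runTo1(dt / 2) - exp(-1))
  log2(e1 / e2)
}
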