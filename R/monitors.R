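## Online monitors: raw/down-sampling observers of the state stream and
## biophysical forward models (lead-field projection, intracranial point
## dipoles, balloon-windkessel BOLD).

#' Monitor output: a rank-4 simulated time series
#'
#' Raw-family monitors produce `[time, state variables, space, modes]`;
#' biophysical monitors produce `[time, 1, sensors, 1]`.
#'
#' @slot data rank-4 numeric array.
#' @slot samplePeriod sampling period in ms.
#' @slot startTime time of the first sample (ms).
#' @slot labels named list of axis labels (`svar`, `space`, `mode`).
#' @export
setClass("TimeSeriesResult",
  representation(data = "array", samplePeriod = "numeric",
                 startTime = "numeric", labels = "list"))

setValidity("TimeSeriesResult", function(object) {
  if (length(dim(object@data)) != 4) return("data must be a rank-4 array")
  if (object@samplePeriod <= 0) return("samplePeriod must be positive")
  TRUE
})

setMethod("show", "TimeSeriesResult", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "TimeSeriesResult: %d samples x %d svar x %d space x %d modes @ %g ms\n",
    d[1], d[2], d[3], d[4], object@samplePeriod))
})

#' @describeIn TimeSeriesResult the rank-4 data array.
#' @param x a `TimeSeriesResult`.
#' @export
tsData <- function(x) x@data

#' @describeIn TimeSeriesResult sampling period (ms).
#' @export
samplePeriod <- function(x) x@samplePeriod

#' @describeIn TimeSeriesResult sample times (ms).
#' @export
tsTime <- function(x)
  x@startTime + (seq_len(dim(x@data)[1]) - 1L) * x@samplePeriod

#' Lead-field (gain) matrix mapping sources to sensors
#'
#' @slot gain sensors x sources matrix.
#' @slot sensorLabels per-sensor labels.
#' @slot sourceSpace `"region"` or `"vertex"`.
#' @export
setClass("ProjectionMatrix",
  representation(gain = "matrix", sensorLabels = "character",
                 sourceSpace = "character"))

setValidity("ProjectionMatrix", function(object) {
  if (length(object@sensorLabels) &&
      length(object@sensorLabels) != nrow(object@gain))
    return("sensorLabels length must equal the number of sensors")
  TRUE
})

setMethod("show", "ProjectionMatrix", function(object) {
  cat(sprintf("ProjectionMatrix: %d sensors x %d %s sources\n",
              nrow(object@gain), ncol(object@gain), object@sourceSpace))
})

#' @rdname ProjectionMatrix-class
#' @param gain sensors x sources numeric matrix.
#' @param sensorLabels optional sensor names.
#' @param sourceSpace `"region"` or `"vertex"`.
#' @export
projectionMatrix <- function(gain, sensorLabels = character(0),
                             sourceSpace = "region") {
  gain <- as.matrix(gain)
  new("ProjectionMatrix", gain = gain,
      sensorLabels = as.character(sensorLabels), sourceSpace = sourceSpace)
}

#' Read a projection matrix from delimited text
#'
#' Expects an optional one-line header of sensor labels followed by a
#' sensors x sources numeric matrix.
#'
#' @param path text file path.
#' @param sourceSpace `"region"` or `"vertex"`.
#' @export
readProjectionMatrix <- function(path, sourceSpace = "region") {
  first <- readLines(path, n = 1L)
  fields <- strsplit(trimws(first), "[,[:space:]]+")[[1]]
  hasHeader <- anyNA(suppressWarnings(as.numeric(fields)))
  if (hasHeader) {
    tmp <- tempfile()
    writeLines(readLines(path)[-1], tmp)
    gain <- .readDelimMatrix(tmp)
    unlink(tmp)
    projectionMatrix(gain, sensorLabels = fields, sourceSpace = sourceSpace)
  } else {
    projectionMatrix(.readDelimMatrix(path), sourceSpace = sourceSpace)
  }
}

#' Point-dipole gain in an infinite homogeneous medium
#'
#' Electric potential of unit current dipoles at the sources, evaluated at
#' intracranial sensor positions:
#' `gain[k, i] = q_i . (r_k - r_i) / (4 pi sigma |r_k - r_i|^3)`.
#'
#' @param dipolePositions sources x 3 matrix (mm).
#' @param dipoleOrientations sources x 3 matrix of unit dipole moments.
#' @param sensorPositions sensors x 3 matrix (mm).
#' @param sigma medium conductivity (S/m; scale factor only in this
#'   homogeneous model).
#' @return a [ProjectionMatrix-class].
#' @export
seegGain <- function(dipolePositions, dipoleOrientations, sensorPositions,
                     sigma = 1) {
  dp <- as.matrix(dipolePositions)
  dq <- as.matrix(dipoleOrientations)
  sp <- as.matrix(sensorPositions)
  gain <- matrix(0, nrow(sp), nrow(dp))
  for (k in seq_len(nrow(sp))) {
    rel <- sp[rep(k, nrow(dp)), , drop = FALSE] - dp
    r3 <- rowSums(rel^2)^1.5
    if (any(r3 == 0))
      stop("sensor ", k, " coincides with a source position")
    gain[k, ] <- rowSums(dq * rel) / (4 * pi * sigma * r3)
  }
  projectionMatrix(gain, sourceSpace = "region")
}

## ---- monitor specifications ---------------------------------------------

#' Monitor specifications
#'
#' Monitors observe the state stream online. `rawMonitor()` returns every
#' step and every state variable. `subsampleMonitor()` returns the variables
#' of interest every `period` ms. `temporalAverageMonitor()` returns their
#' mean over each period window. `spatialAverageMonitor()` averages over
#' node masks and subsamples. `projectionMonitor()` multiplies a lead-field
#' gain into the source activity (sum or mean over the variables of interest
#' and modes) — use for EEG/MEG/sEEG sensors. `boldMonitor()` drives a
#' balloon-windkessel hemodynamic model per node and samples the BOLD
#' signal.
#'
#' @slot period sampling period (ms); must be an integer multiple of the
#'   integrator step.
#' @name monitors
NULL

#' @rdname monitors
#' @export
setClass("Monitor", representation("VIRTUAL", period = "numeric"))

#' @rdname monitors
#' @export
setClass("RawMonitor", contains = "Monitor")

#' @rdname monitors
#' @export
setClass("SubsampleMonitor", contains = "Monitor")

#' @rdname monitors
#' @export
setClass("TemporalAverageMonitor", contains = "Monitor")

#' @rdname monitors
#' @export
setClass("SpatialAverageMonitor", contains = "Monitor",
         representation(masks = "list"))

#' @rdname monitors
#' @export
setClass("ProjectionMonitor", contains = "Monitor",
         representation(projection = "ProjectionMatrix",
                        reduce = "character"))

#' @rdname monitors
#' @export
setClass("BoldMonitor", contains = "Monitor",
         representation(hemodynamics = "list"))

#' @rdname monitors
#' @export
rawMonitor <- function() new("RawMonitor", period = NA_real_)

#' @rdname monitors
#' @param period sampling period in ms.
#' @export
subsampleMonitor <- function(period = 1) new("SubsampleMonitor", period = period)

#' @rdname monitors
#' @export
temporalAverageMonitor <- function(period = 1)
  new("TemporalAverageMonitor", period = period)

#' @rdname monitors
#' @param masks list of node index vectors to average over; `NULL` means one
#'   mask covering the whole network.
#' @export
spatialAverageMonitor <- function(period = 1, masks = NULL)
  new("SpatialAverageMonitor", period = period, masks = masks %||% list())

#' @rdname monitors
#' @param projection a [ProjectionMatrix-class].
#' @param reduce `"sum"` or `"mean"` over the variables of interest and
#'   modes before projecting.
#' @export
projectionMonitor <- function(projection, period = 1, reduce = c("sum", "mean")) {
  new("ProjectionMonitor", period = period, projection = projection,
      reduce = match.arg(reduce))
}

#' Balloon-windkessel default constants
#'
#' Standard hemodynamic parameter set (rates per second): signal decay
#' `kappa = 0.65`, feedback `gamma = 0.41`, transit time `tau = 0.98` s,
#' stiffness `alpha = 0.32`, resting oxygen extraction `rho = 0.34`,
#' resting blood volume `V0 = 0.02`, output coefficients `k1 = 7 rho`,
#' `k2 = 2`, `k3 = 2 rho - 0.2`.
#'
#' @export
boldDefaults <- function() {
  rho <- 0.34
  list(kappa = 0.65, gamma = 0.41, tau = 0.98, alpha = 0.32, rho = rho,
       V0 = 0.02, k1 = 7 * rho, k2 = 2, k3 = 2 * rho - 0.2)
}

#' @rdname monitors
#' @param hemodynamics named list overriding [boldDefaults()].
#' @export
boldMonitor <- function(period = 500, hemodynamics = list()) {
  h <- boldDefaults()
  h[names(hemodynamics)] <- hemodynamics
  if (h$tau <= 0 || h$alpha <= 0 || h$rho <= 0)
    stop("tau, alpha and rho must be positive")
  new("BoldMonitor", period = period, hemodynamics = h)
}

## ---- balloon-windkessel dynamics ----------------------------------------

#' Oxygen extraction fraction of the balloon model
#'
#' `E(f, rho) = 1 - (1 - rho)^(1/f)`; `E(1, rho) = rho` at rest.
#'
#' @param f normalized inflow.
#' @param rho resting extraction fraction.
#' @export
oxygenExtraction <- function(f, rho) 1 - (1 - rho)^(1 / f)

#' Balloon-windkessel derivative
#'
#' States per node: vasodilatory signal `s`, inflow `f`, volume `v`,
#' deoxyhemoglobin `q`; resting fixed point `(0, 1, 1, 1)`:
#' \deqn{\dot s = x - \kappa s - \gamma (f - 1),\quad \dot f = s}
#' \deqn{\tau \dot v = f - v^{1/\alpha},\quad
#'       \tau \dot q = f E(f,\rho)/\rho - v^{1/\alpha} q / v}
#'
#' @param state nodes x 4 matrix `(s, f, v, q)`.
#' @param x per-node neural drive.
#' @param h hemodynamic constants, see [boldDefaults()]. Rates are per
#'   second; time is measured in seconds here.
#' @return nodes x 4 matrix of derivatives.
#' @export
balloonDfun <- function(state, x, h) {
  s <- state[, 1]; f <- state[, 2]; v <- state[, 3]; q <- state[, 4]
  via <- v^(1 / h$alpha)
  cbind(x - h$kappa * s - h$gamma * (f - 1),
        s,
        (f - via) / h$tau,
        (f * oxygenExtraction(f, h$rho) / h$rho - via * q / v) / h$tau)
}

#' BOLD signal readout
#'
#' `y = V0 (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v))`; zero at rest.
#'
#' @param v,q balloon volume and deoxyhemoglobin.
#' @param h hemodynamic constants.
#' @export
boldReadout <- function(v, q, h)
  h$V0 * (h$k1 * (1 - q) + h$k2 * (1 - q / v) + h$k3 * (1 - v))

## ---- offline monitor application (stream producers live in simulator.R) --

#' Project source activity through a lead field
#'
#' Applies `gain %*% source` per sample: raw-family input
#' `[time, svar, space, modes]` is reduced over the selected state variables
#' and modes, then mapped to sensors, giving `[time, 1, sensors, 1]`.
#'
#' @param result a raw-family [TimeSeriesResult-class].
#' @param projection a [ProjectionMatrix-class] with `sources =` space
#'   length.
#' @param svars state-variable indices to reduce over (default: all in the
#'   result).
#' @param reduce `"sum"` or `"mean"`.
#' @return a biophysical-family [TimeSeriesResult-class].
#' @export
projectSensors <- function(result, projection, svars = NULL,
                           reduce = c("sum", "mean")) {
  reduce <- match.arg(reduce)
  gain <- projection@gain
  d <- dim(result@data)
  if (ncol(gain) != d[3])
    stop("gain has ", ncol(gain), " source columns but the result has ",
         d[3], " nodes")
  svars <- svars %||% seq_len(d[2])
  src <- result@data[, svars, , , drop = FALSE]
  red <- apply(src, c(1, 3), if (reduce == "sum") sum else mean)  # [time, space]
  sens <- red %*% t(gain)                                        # [time, sensors]
  new("TimeSeriesResult",
      data = array(sens, c(d[1], 1, nrow(gain), 1)),
      samplePeriod = result@samplePeriod, startTime = result@startTime,
      labels = list(svar = "projected", space = projection@sensorLabels,
                    mode = "1"))
}

#' Write a time series result as delimited text
#'
#' Flattens the rank-4 array into a `time x (svar * space * mode)` table
#' with a metadata header line (`# sample_period_ms=...`) and labelled
#' columns.
#'
#' @param result a [TimeSeriesResult-class].
#' @param path output file.
#' @export
writeTimeSeries <- function(result, path) {
  d <- dim(result@data)
  flat <- matrix(result@data, nrow = d[1])
  lab <- expand.grid(sv = seq_len(d[2]), sp = seq_len(d[3]),
                     md = seq_len(d[4]))
  colnames(flat) <- sprintf("sv%d_sp%d_m%d", lab$sv, lab$sp, lab$md)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_period_ms=%g start_time_ms=%g",
                     result@samplePeriod, result@startTime), con)
  utils::write.table(cbind(time = tsTime(result), flat), con,
                     row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
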