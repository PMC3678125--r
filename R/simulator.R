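## Simulator core: assembles connectome, model, coupling, integrator, noise,
## stimulus and monitors; maintains the delayed-state ring buffer; runs the
## configure/step loop; supports continuation and toy-scale surface mode.

#' Ring buffer of past coupling-variable states
#'
#' Holds the last `horizon` steps of the coupling variables. The slot of
#' step `k` is `k %% horizon`, so writing overwrites the oldest entry, and
#' reading delay `d` at step `s` returns what was stored at step `s - d`.
#'
#' @slot buffer array `[horizon, nodes, coupling variables, modes]`.
#' @slot writeStep step index of the most recent entry.
#' @export
setClass("HistoryBuffer",
  representation(buffer = "array", writeStep = "integer"))

setMethod("show", "HistoryBuffer", function(object) {
  d <- dim(object@buffer)
  cat(sprintf("HistoryBuffer: horizon %d, %d nodes, %d cvar, %d modes (at step %d)\n",
              d[1], d[2], d[3], d[4], object@writeStep))
})

#' @rdname HistoryBuffer-class
#' @param horizon buffer depth in steps.
#' @param nNodes,nCvar,nModes remaining dimensions.
#' @param init optional array `[horizon, nNodes, nCvar, nModes]` holding the
#'   pre-t=0 history; row `horizon` is the most recent (step 0).
#' @export
historyBuffer <- function(horizon, nNodes, nCvar = 1, nModes = 1,
                          init = NULL) {
  buf <- array(0, c(horizon, nNodes, nCvar, nModes))
  if (!is.null(init)) {
    stopifnot(all(dim(init) == dim(buf)))
    ## init rows 1..horizon are steps (1 - horizon)..0; map into ring slots
    for (t in seq_len(horizon)) {
      k <- t - horizon                      # step index, -(horizon-1)..0
      buf[k %% horizon + 1L, , , ] <- init[t, , , ]
    }
  }
  new("HistoryBuffer", buffer = buf, writeStep = 0L)
}

#' @rdname HistoryBuffer-class
#' @param h a `HistoryBuffer`.
#' @param cvarState array `[nodes, nCvar, nModes]` for the next step.
#' @export
historyPush <- function(h, cvarState) {
  k <- h@writeStep + 1L
  hor <- dim(h@buffer)[1]
  h@buffer[k %% hor + 1L, , , ] <- cvarState
  h@writeStep <- k
  h
}

## Delayed weighted aggregation, shared by nodeCoupling() and the run loop.
## buf: [horizon, n, ncvar, nmodes]; step: step index whose state sits in
## the most recent slot; offJ: precomputed (j-1)*horizon matrix.
.delayedAggregate <- function(buf, horizon, step, weights, dmat, offJ) {
  n <- nrow(weights)
  ncv <- dim(buf)[3]
  nm <- dim(buf)[4]
  ## flatten to a plain vector: a matrix subscript would be read as
  ## coordinate rows whenever n happens to equal the array rank
  rows1 <- as.vector((step - dmat) %% horizon + offJ) + 1
  out <- array(0, c(n, ncv, nm))
  block <- horizon * n
  for (m in seq_len(nm)) {
    for (cv in seq_len(ncv)) {
      off <- (cv - 1L + (m - 1L) * ncv) * block
      delayed <- buf[rows1 + off]
      dim(delayed) <- c(n, n)
      out[, cv, m] <- rowSums(weights * delayed)
    }
  }
  out
}

#' Delayed, weighted, transformed network input
#'
#' Computes, per node i, coupling variable and mode, the long-range input
#' `coupling( sum_j weights[i, j] * cvar_j(step - delaySteps[i, j]) )`: the
#' dot product between the weights matrix and the delayed coupling-variable
#' state, transformed by the coupling function.
#'
#' @param history a [HistoryBuffer-class].
#' @param weights n x n connection strengths (row = target node).
#' @param delaySteps n x n integer delays in steps (all `< horizon`).
#' @param coupling a [CouplingSpec-class].
#' @return array `[nodes, coupling variables, modes]`.
#' @export
nodeCoupling <- function(history, weights, delaySteps, coupling) {
  hor <- dim(history@buffer)[1]
  if (max(delaySteps) >= hor)
    stop("delays exceed the history horizon")
  n <- nrow(weights)
  offJ <- matrix((seq_len(n) - 1L) * hor, n, n, byrow = TRUE)
  agg <- .delayedAggregate(history@buffer, hor, history@writeStep, weights,
                          delaySteps, offJ)
  applyCoupling(agg, coupling)
}

## ---- meshes and local coupling ------------------------------------------

#' Triangular cortical mesh (toy scale)
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @return a list of class `triangular_mesh`.
#' @export
triangularMesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3)
  if (any(triangles < 1 | triangles > nrow(vertices)))
    stop("triangle indices out of range")
  structure(list(vertices = vertices, triangles = triangles),
            class = "triangular_mesh")
}

#' Instantaneous local coupling kernel on a mesh
#'
#' Sparse vertex-to-vertex weights `equation(distance)` for pairs within the
#' cutoff. Local propagation carries no delay, an acceptable approximation
#' at the short distances involved.
#'
#' @param mesh a [triangularMesh()].
#' @param equation weight as a function of distance (mm), e.g.
#'   [gaussianProfile()].
#' @param cutoff support radius (mm, > 0); pairs farther apart get weight 0.
#' @param includeDiagonal keep the self-term `equation(0)`? Default drops
#'   it.
#' @return a sparse `dgCMatrix` (vertices x vertices).
#' @export
buildLocalKernel <- function(mesh, equation = gaussianProfile, cutoff,
                             includeDiagonal = FALSE) {
  if (cutoff <= 0) stop("cutoff must be positive")
  v <- mesh$vertices
  n <- nrow(v)
  d <- as.matrix(dist(v))
  w <- matrix(0, n, n)
  inside <- d <= cutoff
  if (!includeDiagonal) diag(inside) <- FALSE
  w[inside] <- equation(d[inside])
  Matrix::Matrix(w, sparse = TRUE)
}

## ---- simulation configuration -------------------------------------------

#' Simulation configuration
#'
#' Bundles every component needed to build a brain network model. In
#' surface mode (`surface` given) the nodes are mesh vertices: long-range
#' input is computed on region-averaged vertex activity through the region
#' connectome and mapped back to vertices, while `localKernel` couples
#' neighbouring vertices instantaneously.
#'
#' @param connectome a [Connectome-class].
#' @param model a [ModelSpec-class].
#' @param coupling a [CouplingSpec-class].
#' @param integrator an [IntegratorSpec-class].
#' @param monitors named list of [monitors].
#' @param stimulus optional [StimulusPattern-class] (weights per node, or
#'   per vertex in surface mode).
#' @param seed integer seed for initial conditions and noise.
#' @param initialConditions optional array
#'   `[steps, nodes, svar, modes]`; if shorter than the delay horizon it is
#'   padded with random history at the older slots (the supplied part stays
#'   most recent).
#' @param surface optional list `(mesh, regionMapping, localKernel)`;
#'   `regionMapping` maps each vertex to its region index.
#' @param simulationLength default run length (ms) for [simulateNetwork()].
#' @return object of class `simulation_config`.
#' @export
simulationConfig <- function(connectome, model, coupling = linearCoupling(),
                             integrator = heunIntegrator(),
                             monitors = list(raw = rawMonitor()),
                             stimulus = NULL, seed = 42,
                             initialConditions = NULL, surface = NULL,
                             simulationLength = 1000) {
  stopifnot(is(connectome, "Connectome"), is(model, "ModelSpec"),
            is(coupling, "CouplingSpec"), is(integrator, "IntegratorSpec"))
  if (simulationLength <= 0) stop("simulationLength must be positive")
  if (!length(monitors)) stop("at least one monitor is required")
  if (is.null(names(monitors)))
    names(monitors) <- paste0("monitor", seq_along(monitors))
  structure(list(connectome = connectome, model = model,
                 coupling = coupling, integrator = integrator,
                 monitors = monitors, stimulus = stimulus, seed = seed,
                 initialConditions = initialConditions, surface = surface,
                 simulationLength = simulationLength),
            class = "simulation_config")
}

#' Whole-brain network simulator
#'
#' Created by [configureSimulator()]; holds the configuration and a state
#' environment (history ring buffer, current state, random stream, monitor
#' accumulators) so that repeated [runSimulation()] calls continue the same
#' simulation.
#'
#' @slot config the `simulation_config`.
#' @slot state internal environment.
#' @export
setClass("Simulator", representation(config = "list", state = "environment"))

setMethod("show", "Simulator", function(object) {
  e <- object@state
  cat(sprintf(
    "Simulator: %d nodes (%s), model %s, dt = %g ms, horizon %d steps, at t = %g ms\n",
    e$n, if (e$surfaceMode) "vertices" else "regions",
    object@config$model@name, e$dt, e$horizon, e$stepCount * e$dt))
})

#' Configure a simulator
#'
#' Computes the delay table, spatializes model parameters, initializes (and
#' pads) the history from the initial conditions or random draws within the
#' model's state ranges, and prepares the monitors.
#'
#' @param config a [simulationConfig()].
#' @return a [Simulator-class], ready to [runSimulation()].
#' @export
configureSimulator <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  e <- new.env(parent = emptyenv())
  conn <- config$connectome
  model <- config$model
  integ <- config$integrator
  e$dt <- integ@dt
  e$surfaceMode <- !is.null(config$surface)

  nr <- nRegions(conn)
  dtab <- computeDelayTable(conn, e$dt)
  e$delayTable <- dtab
  e$horizon <- horizon(dtab)
  e$dmat <- delaySteps(dtab)
  e$weights <- weightsMatrix(conn)
  e$offJ <- matrix((seq_len(nr) - 1L) * e$horizon, nr, nr, byrow = TRUE)
  e$nRegions <- nr

  if (e$surfaceMode) {
    surf <- config$surface
    if (is.null(surf$mesh) || is.null(surf$regionMapping))
      stop("surface mode needs fields 'mesh' and 'regionMapping'")
    nv <- nrow(surf$mesh$vertices)
    rm_ <- as.integer(surf$regionMapping)
    if (length(rm_) != nv)
      stop("regionMapping length ", length(rm_), " != vertices ", nv)
    if (any(rm_ < 1 | rm_ > nr))
      stop("regionMapping refers to unknown regions")
    e$n <- nv
    e$regionMapping <- rm_
    ## vertex -> region averaging operator
    cnt <- tabulate(rm_, nbins = nr)
    if (any(cnt == 0))
      stop("every region must own at least one vertex in surface mode")
    e$regionAvg <- Matrix::sparseMatrix(i = rm_, j = seq_len(nv),
                                        x = 1 / cnt[rm_], dims = c(nr, nv))
    e$localKernel <- surf$localKernel
  } else {
    e$n <- nr
    e$localKernel <- NULL
  }

  e$model <- .spatializeModel(model, e$n)
  e$nsvar <- model@nSvar
  e$nmodes <- model@nModes
  e$cvar <- model@cvar
  e$voi <- model@voi
  e$ncvar <- length(model@cvar)
  e$coupling <- config$coupling
  e$integrator <- integ
  e$stream <- makeStream(config$seed)
  rw <- model@stateRanges[, 2] - model@stateRanges[, 1]
  e$guard <- 1e6 * max(rw, 1)

  if (!is.null(config$stimulus)) {
    sw <- config$stimulus@spatialWeights
    if (length(sw) != e$n)
      stop("stimulus weighting length ", length(sw),
           " does not match the number of nodes ", e$n)
    e$stimulus <- config$stimulus
  } else e$stimulus <- NULL

  ## initial full-state history [horizon, n, nsvar, nmodes]
  fs <- randomInitialState(e$model, e$n, e$horizon, seed = e$stream)
  ic <- config$initialConditions
  if (!is.null(ic)) {
    dic <- dim(ic)
    if (length(dic) != 4 || any(dic[-1] != c(e$n, e$nsvar, e$nmodes)))
      stop("initialConditions must be [steps, ", e$n, ", ", e$nsvar, ", ",
           e$nmodes, "]")
    keep <- min(dic[1], e$horizon)
    ## supplied data occupies the most recent slots; random padding is older
    fs[(e$horizon - keep + 1):e$horizon, , , ] <-
      ic[(dic[1] - keep + 1):dic[1], , , , drop = FALSE]
  }
  e$curState <- array(fs[e$horizon, , , ], c(e$n, e$nsvar, e$nmodes))
  histFull <- if (e$surfaceMode) {
    rh <- array(0, c(e$horizon, nr, e$nsvar, e$nmodes))
    for (t in seq_len(e$horizon))
      rh[t, , , ] <- .toRegions(e, array(fs[t, , , , drop = FALSE],
                                         dim(fs)[-1]))
    rh
  } else fs
  buf <- array(0, c(e$horizon, nr, e$ncvar, e$nmodes))
  for (t in seq_len(e$horizon)) {
    k <- t - e$horizon
    buf[k %% e$horizon + 1L, , , ] <-
      histFull[t, , e$cvar, , drop = FALSE]
  }
  e$buf <- buf
  e$stepCount <- 0L

  e$monitors <- lapply(names(config$monitors), function(nm) {
    mon <- config$monitors[[nm]]
    .monitorInit(mon, nm, e)
  })
  names(e$monitors) <- names(config$monitors)
  new("Simulator", config = unclass(config), state = e)
}

## region-average an array [n, svar-or-cvar, modes] in surface mode
.toRegions <- function(e, x) {
  d <- dim(x)
  flat <- matrix(x, nrow = d[1])
  out <- as.matrix(e$regionAvg %*% flat)
  array(out, c(e$nRegions, d[2], d[3]))
}

## ---- monitor engines -----------------------------------------------------

.monitorInit <- function(mon, name, e) {
  menv <- new.env(parent = emptyenv())
  menv$spec <- mon
  menv$name <- name
  period <- mon@period
  if (is(mon, "RawMonitor") || is.na(period)) period <- e$dt
  per <- period / e$dt
  if (abs(per - round(per)) > 1e-9)
    stop("monitor '", name, "' period ", period,
         " ms is not an integer multiple of dt = ", e$dt, " ms")
  menv$per <- as.integer(round(per))
  menv$period <- menv$per * e$dt
  if (is(mon, "TemporalAverageMonitor"))
    menv$acc <- array(0, c(e$n, length(e$voi), e$nmodes))
  if (is(mon, "SpatialAverageMonitor")) {
    masks <- mon@masks
    if (!length(masks)) masks <- list(all = seq_len(e$n))
    if (is.null(names(masks)))
      names(masks) <- paste0("mask", seq_along(masks))
    menv$masks <- masks
  }
  if (is(mon, "ProjectionMonitor")) {
    if (ncol(mon@projection@gain) != e$n)
      stop("monitor '", name, "': gain has ", ncol(mon@projection@gain),
           " source columns but the simulation has ", e$n, " nodes")
    menv$gain <- mon@projection@gain
  }
  if (is(mon, "BoldMonitor")) {
    menv$h <- mon@hemodynamics
    menv$balloon <- cbind(s = rep(0, e$n), f = rep(1, e$n),
                          v = rep(1, e$n), q = rep(1, e$n))
  }
  menv
}

## dimensions of one emitted sample: c(svar, space, modes)
.monitorSampleDim <- function(menv, e) {
  mon <- menv$spec
  if (is(mon, "RawMonitor")) c(e$nsvar, e$n, e$nmodes)
  else if (is(mon, "SpatialAverageMonitor"))
    c(length(e$voi), length(menv$masks), e$nmodes)
  else if (is(mon, "ProjectionMonitor")) c(1L, nrow(menv$gain), 1L)
  else if (is(mon, "BoldMonitor")) c(1L, e$n, 1L)
  else c(length(e$voi), e$n, e$nmodes)
}

## advance a monitor by one integration step; returns a sample or NULL
.monitorStep <- function(menv, e, state) {
  mon <- menv$spec
  due <- e$stepCount %% menv$per == 0L
  if (is(mon, "RawMonitor")) {
    return(aperm(state, c(2, 1, 3)))
  }
  if (is(mon, "SubsampleMonitor")) {
    if (!due) return(NULL)
    return(aperm(state[, e$voi, , drop = FALSE], c(2, 1, 3)))
  }
  if (is(mon, "TemporalAverageMonitor")) {
    menv$acc <- menv$acc + state[, e$voi, , drop = FALSE]
    if (!due) return(NULL)
    out <- menv$acc / menv$per
    menv$acc[] <- 0
    return(aperm(out, c(2, 1, 3)))
  }
  if (is(mon, "SpatialAverageMonitor")) {
    if (!due) return(NULL)
    sub <- state[, e$voi, , drop = FALSE]
    out <- array(0, c(length(e$voi), length(menv$masks), e$nmodes))
    for (k in seq_along(menv$masks))
      out[, k, ] <- apply(sub[menv$masks[[k]], , , drop = FALSE],
                          c(2, 3), mean)
    return(out)
  }
  if (is(mon, "ProjectionMonitor")) {
    if (!due) return(NULL)
    sub <- state[, e$voi, , drop = FALSE]
    src <- if (mon@reduce == "sum") rowSums(sub) else rowMeans(sub)
    return(array(menv$gain %*% src, c(1, nrow(menv$gain), 1)))
  }
  if (is(mon, "BoldMonitor")) {
    ## neural drive: the model's first variable of interest, mode-averaged
    sub <- state[, e$voi[1], , drop = FALSE]
    x <- rowSums(array(sub, c(e$n, e$nmodes))) / e$nmodes
    dts <- e$dt / 1000                # balloon time in seconds
    ## classical RK4 with the neural drive frozen over the step
    b <- menv$balloon; h <- menv$h
    k1 <- balloonDfun(b, x, h)
    k2 <- balloonDfun(b + dts / 2 * k1, x, h)
    k3 <- balloonDfun(b + dts / 2 * k2, x, h)
    k4 <- balloonDfun(b + dts * k3, x, h)
    menv$balloon <- b + dts / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!due) return(NULL)
    y <- boldReadout(menv$balloon[, 3], menv$balloon[, 4], menv$h)
    return(array(y, c(1, e$n, 1)))
  }
  stop("unknown monitor class: ", class(mon))
}

## ---- run loop ------------------------------------------------------------

#' Run (or continue) a simulation
#'
#' Advances the simulator by `round(length / dt)` steps. Each step computes
#' the delayed long-range input, adds instantaneous local coupling (surface
#' mode) and the stimulus, advances the state with the integrator, pushes
#' the coupling variables into the history ring, and offers the new state
#' to every monitor. Calling `runSimulation` again continues seamlessly
#' from the stored history, stream and monitor state; a deterministic
#' two-segment run concatenates bit-exactly to a single uninterrupted run.
#'
#' @param sim a [Simulator-class].
#' @param length simulated time in ms (default: the configured
#'   `simulationLength`).
#' @return named list of [TimeSeriesResult-class], one per monitor, for the
#'   newly simulated segment.
#' @export
runSimulation <- function(sim, length = NULL) {
  e <- sim@state
  length <- length %||% sim@config$simulationLength
  nSteps <- as.integer(round(length / e$dt))
  if (nSteps < 1) stop("length must cover at least one step")
  model <- e$model
  dfun <- model@dfun
  params <- model@params
  integ <- e$integrator
  coupling <- e$coupling
  s0 <- e$stepCount
  dt <- e$dt

  ## preallocate per-monitor output
  out <- lapply(e$monitors, function(menv) {
    ns <- (s0 + nSteps) %/% menv$per - s0 %/% menv$per
    sdim <- .monitorSampleDim(menv, e)
    list(data = array(NA_real_, c(ns, sdim)), i = 0L, menv = menv)
  })

  cvar <- e$cvar
  surface <- e$surfaceMode
  stim <- e$stimulus
  buf <- e$buf
  hor <- e$horizon
  weights <- e$weights
  dmat <- e$dmat
  offJ <- e$offJ
  state <- e$curState
  stream <- e$stream
  guard <- e$guard

  for (step in seq_len(nSteps)) {
    sc <- e$stepCount
    agg <- .delayedAggregate(buf, hor, sc, weights, dmat, offJ)
    cIn <- applyCoupling(agg, coupling)
    if (surface)
      cIn <- array(cIn[e$regionMapping, , , drop = FALSE],
                   c(e$n, e$ncvar, e$nmodes))
    t <- sc * dt
    local <- 0
    if (surface && !is.null(e$localKernel))
      local <- as.numeric(e$localKernel %*% state[, cvar[1], 1])
    if (!is.null(stim))
      local <- local + evaluateStimulus(stim, t)
    if (is.numeric(local) && length(local) == 1L) local <- rep(local, e$n)
    deriv <- function(x) dfun(x, cIn, local, params)
    state <- integrateStep(state, deriv, integ, stream)
    if (!all(is.finite(state)) || max(abs(state)) > guard) {
      bad <- which(!is.finite(state) | abs(state) > guard,
                   arr.ind = TRUE)
      stop("simulation diverged at step ", sc + 1L, " (t = ",
           (sc + 1L) * dt, " ms), node ", bad[1, 1])
    }
    e$stepCount <- sc + 1L
    newCvar <- state[, cvar, , drop = FALSE]
    if (surface) newCvar <- .toRegions(e, newCvar)
    buf[e$stepCount %% hor + 1L, , , ] <- newCvar
    for (k in seq_along(out)) {
      smp <- .monitorStep(out[[k]]$menv, e, state)
      if (!is.null(smp)) {
        i <- out[[k]]$i + 1L
        out[[k]]$data[i, , , ] <- smp
        out[[k]]$i <- i
      }
    }
  }
  e$buf <- buf
  e$curState <- state

  spaceLabels <- if (surface) as.character(seq_len(e$n))
                 else regionLabels(sim@config$connectome)
  results <- lapply(out, function(o) {
    menv <- o$menv
    first <- (s0 %/% menv$per + 1L) * menv$per
    sdim <- .monitorSampleDim(menv, e)
    lab <- list(svar = as.character(seq_len(sdim[1])),
                space = spaceLabels[seq_len(min(sdim[2], length(spaceLabels)))],
                mode = as.character(seq_len(sdim[3])))
    if (is(menv$spec, "ProjectionMonitor"))
      lab$space <- menv$spec@projection@sensorLabels
    new("TimeSeriesResult", data = o$data,
        samplePeriod = menv$period, startTime = first * e$dt,
        labels = lab)
  })
  names(results) <- names(e$monitors)
  results
}

#' Continue a simulation with optional parameter changes
#'
#' Resumes from the stored history and random-stream state. Only model,
#' coupling and noise parameters may change mid-run; the step size, the
#' transmission speed (hence the delay table) and the spatial support are
#' fixed at configuration.
#'
#' @param sim a [Simulator-class] that has already run.
#' @param length additional simulated time (ms).
#' @param modifiedParams named list of changes, keys like `model.Iext`,
#'   `coupling.a`, `noise.intensity`.
#' @return named list of [TimeSeriesResult-class] for the new segment.
#' @export
continueRun <- function(sim, length, modifiedParams = list()) {
  e <- sim@state
  for (key in names(modifiedParams)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("modifiedParams keys must look like 'model.<name>'")
    val <- modifiedParams[[key]]
    switch(parts[1],
      model = {
        if (!parts[2] %in% names(e$model@params))
          stop("unknown model parameter '", parts[2], "'")
        e$model@params[[parts[2]]] <- spatializeParameter(val, e$n)
      },
      coupling = {
        if (!parts[2] %in% slotNames("CouplingSpec"))
          stop("unknown coupling field '", parts[2], "'")
        slot(e$coupling, parts[2]) <- val
        validObject(e$coupling)
      },
      noise = {
        if (!e$integrator@stochastic)
          stop("the integrator has no noise process")
        if (!parts[2] %in% c("intensity", "tau"))
          stop("only noise.intensity and noise.tau can change mid-run")
        slot(e$integrator@noise, parts[2]) <- val
        validObject(e$integrator@noise)
      },
      integrator = stop("integrator settings (dt, scheme) cannot change mid-run"),
      connectome = stop("the connectome (weights, lengths, speed) cannot change mid-run"),
      surface = stop("the spatial support cannot change mid-run"),
      stop("unknown component '", parts[1], "'"))
  }
  runSimulation(sim, length)
}

#' Configure and run in one call
#'
#' @param config a [simulationConfig()].
#' @param length simulated time in ms (default: the configured length).
#' @return named list of [TimeSeriesResult-class].
#' @export
simulateNetwork <- function(config, length = NULL) {
  sim <- configureSimulator(config)
  runSimulation(sim, length)
}
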