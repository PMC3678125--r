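## JSON configuration files: a declarative mirror of simulationConfig() for
## shell-driven use (see inst/scripts/neuromass-cli.R).

.modelFromList <- function(x) {
  ctor <- switch(tolower(x$name %||% "genericoscillator2d"),
    genericoscillator2d = genericOscillator2d,
    generic2doscillator = genericOscillator2d,
    wilsoncowan = wilsonCowan,
    jansenrit = jansenRit,
    reducedwongwang = reducedWongWang,
    stefanescujirsa2d = stefanescuJirsa2d,
    stop("unknown model '", x$name, "'"))
  do.call(ctor, x$parameters %||% list())
}

.couplingFromList <- function(x) {
  if (is.null(x)) return(linearCoupling())
  switch(tolower(x$kind %||% "linear"),
    linear = linearCoupling(a = x$a %||% 1, b = x$b %||% 0),
    sigmoidal = sigmoidalCoupling(cmin = x$cmin %||% 0, cmax = x$cmax %||% 1,
                                  midpoint = x$midpoint %||% 0,
                                  steepness = x$steepness %||% 1),
    stop("unknown coupling kind '", x$kind, "'"))
}

.noiseFromList <- function(x) {
  if (is.null(x)) return(NULL)
  if (identical(x$kind %||% "additive", "multiplicative"))
    multiplicativeNoise(intensity = unlist(x$intensity) %||% 1e-5,
                        color = x$color %||% "white", tau = x$tau %||% 10)
  else
    additiveNoise(intensity = unlist(x$intensity) %||% 1e-5,
                  color = x$color %||% "white", tau = x$tau %||% 10)
}

.integratorFromList <- function(x) {
  if (is.null(x)) return(heunIntegrator())
  noise <- .noiseFromList(x$noise)
  switch(tolower(x$scheme %||% "heun"),
    euler = eulerIntegrator(dt = x$dt %||% 0.0625, noise = noise),
    heun = heunIntegrator(dt = x$dt %||% 0.0625, noise = noise),
    rk4 = {
      if (!is.null(noise)) stop("rk4 is deterministic-only")
      rk4Integrator(dt = x$dt %||% 0.0625)
    },
    stop("unknown scheme '", x$scheme, "'"))
}

.monitorFromList <- function(x) {
  switch(tolower(x$kind),
    raw = rawMonitor(),
    subsample = subsampleMonitor(period = x$period %||% 1),
    temporal_average = temporalAverageMonitor(period = x$period %||% 1),
    spatial_average = spatialAverageMonitor(period = x$period %||% 1,
                                            masks = x$masks),
    projection = projectionMonitor(
      readProjectionMatrix(x$projection_file),
      period = x$period %||% 1, reduce = x$reduce %||% "sum"),
    bold = boldMonitor(period = x$period %||% 500,
                       hemodynamics = x$hemodynamics %||% list()),
    stop("unknown monitor kind '", x$kind, "'"))
}

.stimulusFromList <- function(x, nNodes) {
  if (is.null(x)) return(NULL)
  temporal <- switch(tolower(x$temporal$kind %||% "pulse_train"),
    pulse_train = pulseTrainFunction(onset = x$temporal$onset %||% 0,
                                     width = x$temporal$width %||% 5,
                                     period = x$temporal$period %||% 1000,
                                     amplitude = x$temporal$amplitude %||% 1),
    stop("unknown temporal equation '", x$temporal$kind, "'"))
  w <- unlist(x$weighting)
  if (length(w) != nNodes)
    stop("stimulus weighting length ", length(w), " != nodes ", nNodes)
  regionStimulus(w, temporal)
}

#' Read a simulation configuration from JSON
#'
#' Fields: `connectome` (either `zip` path or
#' `synthetic: {n_regions, weight_levels, seed}`, plus `speed`), `model`
#' (`name`, `parameters`), `coupling`, `integrator` (`scheme`, `dt`,
#' optional `noise`), `monitors` (named objects with `kind` and `period`),
#' optional `stimulus` (`temporal`, `weighting`), `seed`,
#' `simulation_length`.
#'
#' @param path JSON file.
#' @return a [simulationConfig()].
#' @export
readSimulationConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  cx <- x$connectome
  conn <- if (!is.null(cx$zip))
    readConnectomeZip(cx$zip, speed = cx$speed %||% 4)
  else if (!is.null(cx$synthetic))
    generateSyntheticConnectome(
      nRegions = cx$synthetic$n_regions %||% 74,
      weightLevels = cx$synthetic$weight_levels %||% 4,
      seed = cx$synthetic$seed %||% 42,
      speed = cx$speed %||% 4)
  else stop("connectome must give 'zip' or 'synthetic'")
  monitors <- lapply(x$monitors %||% list(raw = list(kind = "raw")),
                     .monitorFromList)
  simulationConfig(
    connectome = conn,
    model = .modelFromList(x$model %||% list()),
    coupling = .couplingFromList(x$coupling),
    integrator = .integratorFromList(x$integrator),
    monitors = monitors,
    stimulus = .stimulusFromList(x$stimulus, nRegions(conn)),
    seed = x$seed %||% 42,
    simulationLength = x$simulation_length %||% 1000)
}
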