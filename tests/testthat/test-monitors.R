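## a degenerate "model" whose state grows by 1 per ms: handy for testing
## monitor timing because the state value equals simulated time
rampModel <- function() {
  new("ModelSpec", name = "Ramp", nSvar = 1L, nModes = 1L, params = list(),
      stateRanges = rbind(c(0, 0)), voi = 1L, cvar = 1L,
      dfun = function(state, coupling, local, p) array(1, dim(state)))
}

rampConfig <- function(n = 3, dt = 0.5, monitors) {
  cn <- connectome(matrix(0, n, n), matrix(0, n, n))
  simulationConfig(cn, rampModel(), integrator = eulerIntegrator(dt = dt),
                   monitors = monitors, seed = 1,
                   initialConditions = array(0, c(1, n, 1, 1)))
}

test_that("monitor output shapes follow the [time, svar, space, modes] and
           [time, 1, sensors, 1] contracts", {
  cn <- randomConnectome(4, seed = 1)
  gain <- matrix(rnorm(3 * 4), 3, 4)
  cfg <- simulationConfig(
    cn, demoOscillator(), linearCoupling(a = 0.01),
    heunIntegrator(dt = 0.25),
    monitors = list(raw = rawMonitor(),
                    sub = subsampleMonitor(1),
                    tav = temporalAverageMonitor(1),
                    sav = spatialAverageMonitor(1),
                    eeg = projectionMonitor(projectionMatrix(gain), 1),
                    bold = boldMonitor(period = 10)),
    seed = 2)
  res <- simulateNetwork(cfg, 20)
  expect_identical(dim(tsData(res$raw)), c(80L, 2L, 4L, 1L))
  expect_identical(dim(tsData(res$sub)), c(20L, 1L, 4L, 1L))
  expect_identical(dim(tsData(res$tav)), c(20L, 1L, 4L, 1L))
  expect_identical(dim(tsData(res$sav)), c(20L, 1L, 1L, 1L))
  expect_identical(dim(tsData(res$eeg)), c(20L, 1L, 3L, 1L))
  expect_identical(dim(tsData(res$bold)), c(2L, 1L, 4L, 1L))
  expect_equal(samplePeriod(res$raw), 0.25)
  expect_equal(samplePeriod(res$tav), 1)

  ## period must divide into whole steps
  expect_error(simulateNetwork(simulationConfig(
    cn, demoOscillator(), integrator = heunIntegrator(dt = 0.3),
    monitors = list(bad = subsampleMonitor(1)), seed = 1)),
    "integer multiple")
})

test_that("subsampling picks exact step multiples and averaging windows
           match the raw stream", {
  res <- simulateNetwork(rampConfig(monitors = list(
    raw = rawMonitor(), sub = subsampleMonitor(2),
    tav = temporalAverageMonitor(2))), 10)
  ## the ramp state equals time, so subsamples sit at 2, 4, ..., 10 ms
  expect_equal(tsData(res$sub)[, 1, 1, 1], seq(2, 10, by = 2))
  expect_equal(tsTime(res$sub), seq(2, 10, by = 2))
  ## temporal average equals the window mean of the raw monitor
  raw <- tsData(res$raw)[, 1, 1, 1]
  expect_equal(tsData(res$tav)[, 1, 1, 1],
               colMeans(matrix(raw, nrow = 4)))
  ## raw monitor keeps every step
  expect_identical(length(raw), 20L)
})

test_that("temporal average of a constant is that constant", {
  m <- new("ModelSpec", name = "Const", nSvar = 1L, nModes = 1L,
           params = list(), stateRanges = rbind(c(1, 1)), voi = 1L,
           cvar = 1L,
           dfun = function(state, coupling, local, p) array(0, dim(state)))
  cn <- connectome(matrix(0, 2, 2), matrix(0, 2, 2))
  cfg <- simulationConfig(cn, m, integrator = heunIntegrator(dt = 0.5),
                          monitors = list(tav = temporalAverageMonitor(2)),
                          seed = 1,
                          initialConditions = array(7, c(1, 2, 1, 1)))
  res <- simulateNetwork(cfg, 10)
  expect_true(all(tsData(res$tav) == 7))
})

test_that("spatial averaging respects node masks", {
  res <- simulateNetwork(rampConfig(n = 4, monitors = list(
    sav = spatialAverageMonitor(1, masks = list(a = 1:2, b = 3:4)))), 5)
  expect_identical(dim(tsData(res$sav))[3], 2L)
  ## all nodes carry the same ramp, so each mask average equals the ramp
  expect_equal(tsData(res$sav)[, 1, 1, 1], 1:5)
  expect_equal(tsData(res$sav)[, 1, 2, 1], 1:5)
})

test_that("sensor projection is the expected linear mixture", {
  ## identity gain reproduces the sources
  n <- 4
  cn <- randomConnectome(n, seed = 5)
  cfgI <- simulationConfig(
    cn, demoOscillator(), linearCoupling(a = 0.01),
    heunIntegrator(dt = 0.25),
    monitors = list(sub = subsampleMonitor(1),
                    eeg = projectionMonitor(projectionMatrix(diag(n)), 1)),
    seed = 3)
  res <- simulateNetwork(cfgI, 50)
  expect_equal(tsData(res$eeg)[, 1, , 1], tsData(res$sub)[, 1, , 1],
               tolerance = 1e-14)

  ## random gain equals an independent per-sensor dot-product loop
  gain <- matrix(rnorm(62 * n), 62, n)
  res2 <- simulateNetwork(simulationConfig(
    cn, demoOscillator(), linearCoupling(a = 0.01),
    heunIntegrator(dt = 0.25),
    monitors = list(sub = subsampleMonitor(1),
                    eeg = projectionMonitor(projectionMatrix(gain), 1)),
    seed = 3), 50)
  src <- tsData(res2$sub)[, 1, , 1]
  eeg <- tsData(res2$eeg)
  expect_identical(dim(eeg), c(50L, 1L, 62L, 1L))
  for (k in c(1, 31, 62)) {
    manual <- vapply(seq_len(50), function(t) sum(gain[k, ] * src[t, ]),
                     numeric(1))
    expect_equal(eeg[, 1, k, 1], manual, tolerance = 1e-12)
  }

  ## projection is linear in the sources (offline application)
  raw <- new("TimeSeriesResult",
             data = array(rnorm(10 * 1 * n), c(10, 1, n, 1)),
             samplePeriod = 1, startTime = 1, labels = list())
  raw2 <- new("TimeSeriesResult",
              data = array(rnorm(10 * 1 * n), c(10, 1, n, 1)),
              samplePeriod = 1, startTime = 1, labels = list())
  pm <- projectionMatrix(gain)
  mix <- raw
  mix@data <- 2 * raw@data + 3 * raw2@data
  expect_equal(tsData(projectSensors(mix, pm)),
               2 * tsData(projectSensors(raw, pm)) +
                 3 * tsData(projectSensors(raw2, pm)),
               tolerance = 1e-12)
  expect_error(projectSensors(raw, projectionMatrix(matrix(0, 3, n + 1))),
               "source columns")
})

test_that("point-dipole gains follow the homogeneous-medium formula", {
  sigma <- 0.7
  ## dipole at origin along z, sensor on the +z axis at distance d:
  ## potential 1 / (4 pi sigma d^2)
  for (d in c(5, 10)) {
    g <- seegGain(rbind(c(0, 0, 0)), rbind(c(0, 0, 1)),
                  rbind(c(0, 0, d)), sigma = sigma)
    expect_equal(g@gain[1, 1], 1 / (4 * pi * sigma * d^2),
                 tolerance = 1e-12)
  }
  ## equatorial sensor sees zero; off-axis value matches a hand evaluation
  g <- seegGain(rbind(c(0, 0, 0)), rbind(c(0, 0, 1)),
                rbind(c(3, 0, 0), c(1, 2, 2)), sigma = 1)
  expect_equal(g@gain[1, 1], 0)
  expect_equal(g@gain[2, 1], 2 / (4 * pi * 27), tolerance = 1e-12)
  ## 1/d^2 falloff on the axis
  g2 <- seegGain(rbind(c(0, 0, 0)), rbind(c(0, 0, 1)),
                 rbind(c(0, 0, 4), c(0, 0, 8)))
  expect_equal(g2@gain[1, 1] / g2@gain[2, 1], 4, tolerance = 1e-12)
  expect_error(seegGain(rbind(c(0, 0, 0)), rbind(c(0, 0, 1)),
                        rbind(c(0, 0, 0))), "coincides")
})

test_that("balloon model rests at zero, responds to a pulse with peak and
           undershoot, and matches a fine-step oracle", {
  h <- boldDefaults()
  expect_equal(oxygenExtraction(1, h$rho), h$rho)

  ## zero neural input from rest gives an identically zero BOLD signal
  m <- new("ModelSpec", name = "Zero", nSvar = 1L, nModes = 1L,
           params = list(), stateRanges = rbind(c(0, 0)), voi = 1L,
           cvar = 1L,
           dfun = function(state, coupling, local, p) array(0, dim(state)))
  cn <- connectome(matrix(0, 2, 2), matrix(0, 2, 2))
  cfg0 <- simulationConfig(cn, m, integrator = heunIntegrator(dt = 0.5),
                           monitors = list(bold = boldMonitor(period = 100)),
                           seed = 1,
                           initialConditions = array(0, c(1, 2, 1, 1)))
  res0 <- simulateNetwork(cfg0, 2000)
  expect_true(all(tsData(res0$bold) == 0))

  ## a brief activity pulse: positive peak, later undershoot, return to 0.
  ## The neural drive is a leaky integrator of a 500 ms stimulus pulse, so
  ## it rises, plateaus and decays back to zero.
  pulse <- new("ModelSpec", name = "LeakyDrive", nSvar = 1L, nModes = 1L,
               params = list(), stateRanges = rbind(c(0, 0)), voi = 1L,
               cvar = 1L,
               dfun = function(state, coupling, local, p)
                 array(local, dim(state)) - state / 10)
  stim <- regionStimulus(c(1, 1), function(t)
    ifelse(t >= 0 & t < 500, 0.1, 0))
  dt <- 0.5
  cfgP <- simulationConfig(cn, pulse, integrator = eulerIntegrator(dt = dt),
                           monitors = list(bold = boldMonitor(period = 100),
                                           raw = rawMonitor()),
                           seed = 1, stimulus = stim,
                           initialConditions = array(0, c(1, 2, 1, 1)))
  simP <- configureSimulator(cfgP)
  resP <- runSimulation(simP, 20000)
  ## hemodynamic state stays positive (f, v, q) for this bounded input
  expect_true(all(simP@state$monitors$bold$balloon[, 2:4] > 0))
  y <- tsData(resP$bold)[, 1, 1, 1]
  expect_gt(max(y), 0)
  expect_lt(min(y), 0)
  expect_lt(which.max(y), which.min(y))          # undershoot follows peak
  expect_lt(abs(y[length(y)]), 1e-4)             # back near rest

  ## fine-step independent RK4 oracle on the same neural drive
  xs <- tsData(resP$raw)[, 1, 1, 1]              # state per 0.5 ms step
  xFun <- function(tSec) {
    idx <- pmin(floor(tSec / (dt / 1000)) + 1, length(xs))
    xs[idx]
  }
  ref <- naiveBalloon(xFun, boldDefaults(), tEnd = 20, dtFine = dt / 2000)
  tRef <- seq_len(nrow(ref)) * dt / 2000
  yRef <- boldReadout(ref[, 3], ref[, 4], boldDefaults())
  at <- vapply(tsTime(resP$bold) / 1000, function(tt)
    yRef[which.min(abs(tRef - tt))], numeric(1))
  expect_lt(max(abs(y - at)), 1e-6)

  expect_error(boldMonitor(hemodynamics = list(tau = -1)), "positive")
})
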