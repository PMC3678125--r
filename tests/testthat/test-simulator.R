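test_that("history ring buffer stores and retrieves delayed states", {
  h <- historyBuffer(horizon = 4, nNodes = 2)
  for (k in 1:6)
    h <- historyPush(h, array(c(k, -k), c(2, 1, 1)))
  ## most recent is step 6; delay d reads step 6 - d
  w <- diag(2)
  for (d in 0:3) {
    cpl <- nodeCoupling(h, w, matrix(d, 2, 2), linearCoupling())
    expect_equal(as.vector(cpl[, 1, 1]), c(6 - d, -(6 - d)))
  }
  expect_error(nodeCoupling(h, w, matrix(5, 2, 2), linearCoupling()),
               "horizon")
})

test_that("node coupling equals a naive triple loop, bit-exact", {
  set.seed(33)
  n <- 3; hor <- 8
  h <- historyBuffer(hor, n)
  vals <- matrix(rnorm(20 * n), 20, n)
  for (k in 1:20) h <- historyPush(h, array(vals[k, ], c(n, 1, 1)))
  W <- matrix(runif(n * n), n, n)
  D <- matrix(sample(0:5, n * n, replace = TRUE), n, n); diag(D) <- 0
  got <- nodeCoupling(h, W, D, linearCoupling(a = 1.7, b = -0.2))
  for (i in seq_len(n)) {
    delayed <- vapply(seq_len(n), function(j) vals[20 - D[i, j], j],
                      numeric(1))
    ## sum() matches the implementation's extended-precision accumulation
    expect_identical(got[i, 1, 1], 1.7 * sum(W[i, ] * delayed) - 0.2)
  }
})

test_that("degenerate delays reduce coupling to a matrix-vector product and
           zero weights to zero input", {
  n <- 4
  h <- historyBuffer(3, n)
  cur <- rnorm(n)
  h <- historyPush(h, array(rnorm(n), c(n, 1, 1)))
  h <- historyPush(h, array(cur, c(n, 1, 1)))
  W <- matrix(runif(n * n), n, n)
  got <- nodeCoupling(h, W, matrix(0L, n, n), linearCoupling())
  expect_equal(as.vector(got[, 1, 1]), as.vector(W %*% cur),
               tolerance = 1e-14)
  expect_equal(as.vector(nodeCoupling(h, matrix(0, n, n),
                                      matrix(0L, n, n),
                                      linearCoupling())[, 1, 1]),
               rep(0, n))
})

test_that("configuration computes the documented horizon and pads short
           initial conditions at the old end", {
  cn <- fixtureConnectome(matrix(1, 2, 2) - diag(2),
                          matrix(c(0, 80, 80, 0), 2, 2), speed = 4)
  cfg <- simulationConfig(cn, demoOscillator(),
                          integrator = heunIntegrator(dt = 0.0625),
                          monitors = list(raw = rawMonitor()), seed = 1)
  sim <- configureSimulator(cfg)
  expect_identical(sim@state$horizon, 321L)   # 320 past states + current

  ## random history stays inside the state ranges
  m <- demoOscillator()
  buf <- sim@state$buf
  expect_true(all(buf >= m@stateRanges[1, 1] & buf <= m@stateRanges[1, 2]))

  ## supplied initial conditions shorter than the horizon sit at the most
  ## recent slots, slot by slot
  short <- array(seq_len(100 * 2 * 2) / 100, c(100, 2, 2, 1))
  cfg2 <- simulationConfig(cn, demoOscillator(),
                           integrator = heunIntegrator(dt = 0.0625),
                           monitors = list(raw = rawMonitor()), seed = 1,
                           initialConditions = short)
  sim2 <- configureSimulator(cfg2)
  e <- sim2@state
  for (t in 1:100) {
    k <- (321 - 100 + t) - 321          # step index of supplied row t
    slot <- k %% 321 + 1
    expect_identical(e$buf[slot, , 1, 1], short[t, , 1, 1])
  }
  expect_identical(e$curState[, , 1], short[100, , , 1])

  expect_error(configureSimulator(
    simulationConfig(cn, demoOscillator(),
                     monitors = list(raw = rawMonitor()),
                     initialConditions = array(0, c(5, 3, 2, 1)))),
    "initialConditions")
})

test_that("a small delayed network matches an independent naive reference
           sample for sample", {
  n <- 5
  cn <- randomConnectome(n, seed = 2, maxLength = 8, speed = 4)
  dt <- 0.1
  m <- demoOscillator()
  dtab <- computeDelayTable(cn, dt)
  ic <- randomInitialState(m, n, horizon(dtab), seed = 9)
  cfg <- simulationConfig(cn, m, linearCoupling(a = 0.02, b = 0.01),
                          heunIntegrator(dt = dt),
                          monitors = list(raw = rawMonitor()), seed = 1,
                          initialConditions = ic)
  res <- simulateNetwork(cfg, 100)
  ref <- naiveHeunNetwork(weightsMatrix(cn), delaySteps(dtab), dt,
                          nsteps = 1000, icFull = ic, p = m@params,
                          couplA = 0.02, couplB = 0.01)
  got <- aperm(tsData(res$raw)[, , , 1], c(1, 3, 2))
  expect_lt(max(abs(got - ref)), 1e-12)
})

test_that("a pulse propagates along a feed-forward pair with the exact
           step delay, never earlier", {
  ## node 2 listens to node 1 over a 16-step tract; node 1 is stimulated
  W <- matrix(0, 2, 2); W[2, 1] <- 1
  L <- matrix(0, 2, 2); L[2, 1] <- 16; L[1, 2] <- 16
  cn <- fixtureConnectome(W, L, speed = 4)     # 4 ms delay
  dt <- 0.25
  d <- delaySteps(computeDelayTable(cn, dt))[2, 1]
  expect_identical(d, 16L)
  m <- genericOscillator2d()                   # quiescent, excitable
  ic <- array(0, c(1, 2, 2, 1))
  base <- simulationConfig(cn, m, linearCoupling(a = 0.5),
                           heunIntegrator(dt = dt),
                           monitors = list(raw = rawMonitor()), seed = 1,
                           initialConditions = ic)
  onset <- 5
  stim <- regionStimulus(c(1, 0), pulseTrainFunction(onset = onset,
                                                     width = 2,
                                                     period = 1e4,
                                                     amplitude = 2))
  withStim <- base; withStim$stimulus <- stim
  r0 <- tsData(simulateNetwork(base, 40)$raw)
  r1 <- tsData(simulateNetwork(withStim, 40)$raw)
  first <- function(node) which(r1[, 1, node, 1] != r0[, 1, node, 1])[1]
  sOn <- as.integer(onset / dt + 1)       # first step sampling t >= onset
  expect_identical(first(1), sOn)
  ## downstream response: conduction delay, plus the one explicit update
  ## step that writes node 1's perturbed state into the history
  expect_identical(first(2), sOn + d + 1L)
})

test_that("disconnected nodes evolve exactly like isolated simulations", {
  m <- demoOscillator()
  ic3 <- randomInitialState(m, 3, 1, seed = 12)
  cn3 <- fixtureConnectome(matrix(0, 3, 3), matrix(0, 3, 3))
  res3 <- simulateNetwork(simulationConfig(
    cn3, m, integrator = heunIntegrator(dt = 0.25),
    monitors = list(raw = rawMonitor()), seed = 1,
    initialConditions = ic3), 50)
  for (i in 1:3) {
    res1 <- simulateNetwork(simulationConfig(
      oneNodeConnectome(), m, integrator = heunIntegrator(dt = 0.25),
      monitors = list(raw = rawMonitor()), seed = 1,
      initialConditions = ic3[, i, , , drop = FALSE]), 50)
    expect_identical(tsData(res1$raw)[, , 1, 1],
                     tsData(res3$raw)[, , i, 1])
  }
})

test_that("continuation is bit-exact and guards immutable settings", {
  cn <- randomConnectome(4, seed = 3, maxLength = 10)
  m <- demoOscillator()
  cfg <- simulationConfig(cn, m, linearCoupling(a = 0.02),
                          heunIntegrator(dt = 0.25),
                          monitors = list(raw = rawMonitor(),
                                          tav = temporalAverageMonitor(1)),
                          seed = 6)
  full <- simulateNetwork(cfg, 1000)
  sim <- configureSimulator(cfg)
  a <- runSimulation(sim, 500)
  b <- runSimulation(sim, 500)
  for (nm in c("raw", "tav")) {
    joined <- array(0, dim(tsData(full[[nm]])))
    na <- dim(tsData(a[[nm]]))[1]
    joined[seq_len(na), , , ] <- tsData(a[[nm]])
    joined[-seq_len(na), , , ] <- tsData(b[[nm]])
    expect_identical(joined, tsData(full[[nm]]))
  }

  ## stochastic runs continue exactly through the stored stream state
  cfgS <- simulationConfig(cn, m, linearCoupling(a = 0.02),
                           heunIntegrator(dt = 0.25,
                                          noise = additiveNoise(1e-4)),
                           monitors = list(raw = rawMonitor()), seed = 6)
  fullS <- simulateNetwork(cfgS, 600)
  simS <- configureSimulator(cfgS)
  aS <- runSimulation(simS, 300)
  bS <- runSimulation(simS, 300)
  joined <- array(0, dim(tsData(fullS$raw)))
  joined[1:1200, , , ] <- tsData(aS$raw)
  joined[1201:2400, , , ] <- tsData(bS$raw)
  expect_identical(joined, tsData(fullS$raw))

  ## parameter changes apply mid-run; earlier samples stay untouched
  sim2 <- configureSimulator(cfg)
  first <- runSimulation(sim2, 200)
  cont <- continueRun(sim2, 200, modifiedParams = list(model.Iext = 0))
  sim3 <- configureSimulator(cfg)
  firstRef <- runSimulation(sim3, 200)
  contRef <- runSimulation(sim3, 200)
  expect_identical(tsData(first$raw), tsData(firstRef$raw))
  expect_false(identical(tsData(cont$raw), tsData(contRef$raw)))

  expect_error(continueRun(sim2, 10, list(integrator.dt = 0.1)),
               "cannot change")
  expect_error(continueRun(sim2, 10, list(connectome.speed = 2)),
               "cannot change")
  expect_error(continueRun(sim2, 10, list(model.nosuch = 1)), "unknown")
})

test_that("step counts and divergence reporting follow the run contract", {
  cn <- oneNodeConnectome()
  cfg <- simulationConfig(cn, demoOscillator(),
                          integrator = heunIntegrator(dt = 0.0625),
                          monitors = list(raw = rawMonitor()), seed = 1)
  res <- simulateNetwork(cfg, 1000)
  expect_identical(dim(tsData(res$raw))[1], 16000L)

  ## runaway dynamics abort with step and node diagnostics
  unstable <- genericOscillator2d(f = -1, g = 5, Iext = 10, d = 5)
  cfgU <- simulationConfig(cn, unstable,
                           integrator = eulerIntegrator(dt = 1),
                           monitors = list(raw = rawMonitor()), seed = 1)
  expect_error(simulateNetwork(cfgU, 1000), "diverged at step")
})

test_that("local kernels match a dense distance-loop oracle on a toy mesh", {
  mesh <- toyMesh()
  eq <- function(d) gaussianProfile(d, amplitude = 0.5, sigma = 3,
                                    cutoff = 9)
  K <- buildLocalKernel(mesh, eq, cutoff = 9)
  v <- mesh$vertices
  n <- nrow(v)
  dense <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dd <- sqrt(sum((v[i, ] - v[j, ])^2))
    if (dd <= 9) dense[i, j] <- 0.5 * exp(-dd^2 / 18)
  }
  expect_equal(as.matrix(K), dense, ignore_attr = TRUE)
  ## symmetric equation on the same point set gives a symmetric kernel
  expect_true(Matrix::isSymmetric(K))
  ## cutoff below the minimal inter-vertex distance leaves nothing
  dmin <- min(dist(v))
  K0 <- buildLocalKernel(mesh, eq, cutoff = dmin * 0.9)
  expect_equal(sum(K0 != 0), 0)
  expect_error(buildLocalKernel(mesh, eq, cutoff = 0), "positive")
})

test_that("surface mode expands regional coupling to vertices and applies
           instantaneous local coupling", {
  mesh <- toyMesh()
  rmap <- rep(1:2, each = 10)
  kern <- buildLocalKernel(mesh, function(d)
    gaussianProfile(d, amplitude = 0.02, sigma = 4, cutoff = 12),
    cutoff = 12)
  cn <- fixtureConnectome(matrix(c(0, 1, 1, 0), 2, 2),
                          matrix(c(0, 60, 60, 0), 2, 2))
  cfg <- simulationConfig(cn, demoOscillator(), linearCoupling(a = 0.05),
                          heunIntegrator(dt = 0.25),
                          monitors = list(raw = rawMonitor()), seed = 4,
                          surface = list(mesh = mesh, regionMapping = rmap,
                                         localKernel = kern))
  sim <- configureSimulator(cfg)
  expect_identical(sim@state$n, 20L)
  res <- runSimulation(sim, 50)
  expect_identical(dim(tsData(res$raw))[3], 20L)
  expect_true(all(is.finite(tsData(res$raw))))

  ## with zero long-range weights and no kernel, vertices behave as
  ## isolated nodes (region averaging must not leak activity)
  cn0 <- fixtureConnectome(matrix(0, 2, 2), matrix(0, 2, 2))
  ic <- randomInitialState(demoOscillator(), 20, 1, seed = 8)
  cfg0 <- simulationConfig(cn0, demoOscillator(),
                           integrator = heunIntegrator(dt = 0.25),
                           monitors = list(raw = rawMonitor()), seed = 4,
                           initialConditions = ic,
                           surface = list(mesh = mesh,
                                          regionMapping = rmap,
                                          localKernel = NULL))
  res0 <- simulateNetwork(cfg0, 25)
  resIso <- simulateNetwork(simulationConfig(
    connectome(matrix(0, 20, 20), matrix(0, 20, 20)), demoOscillator(),
    integrator = heunIntegrator(dt = 0.25),
    monitors = list(raw = rawMonitor()), seed = 4,
    initialConditions = ic), 25)
  expect_identical(tsData(res0$raw), tsData(resIso$raw))
})
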