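## Independent reference implementations used as oracles. These are written
## from scratch with naive loops and scalar arithmetic and never call the
## package's vectorized paths.

## Naive delay-network reference: FitzHugh-Nagumo-form plane oscillator at
## every node, linear coupling a * sum + b applied post-aggregation,
## deterministic Heun, delays in whole steps. p is the parameter list of
## genericOscillator2d(). Returns [nsteps, n, 2] state trajectory.
naiveHeunNetwork <- function(W, delaySteps, dt, nsteps, icFull, p,
                             couplA = 1, couplB = 0, stimW = NULL,
                             stimF = NULL) {
  n <- nrow(W)
  horizon <- dim(icFull)[1]
  X <- array(0, c(horizon + nsteps, n, 2))
  X[seq_len(horizon), , ] <- icFull[, , , 1]
  f <- function(v, w, I) {
    c(p$d * p$tau * (p$alpha * w - p$f * v^3 + p$e * v^2 + p$g * v +
                       p$gamma * I),
      p$d * (p$a + p$b * v + p$c * v^2 - p$beta * w) / p$tau)
  }
  for (s in seq_len(nsteps)) {
    cur <- horizon + s - 1          # row of the current state
    newRow <- matrix(0, n, 2)
    for (i in seq_len(n)) {
      acc <- 0
      for (j in seq_len(n))
        acc <- acc + W[i, j] * X[cur - delaySteps[i, j], j, 1]
      cIn <- couplA * acc + couplB
      stim <- if (is.null(stimW)) 0 else stimW[i] * stimF((cur - horizon) * dt)
      I <- p$Iext + cIn + stim
      v <- X[cur, i, 1]; w <- X[cur, i, 2]
      f0 <- f(v, w, I)
      pv <- v + dt * f0[1]; pw <- w + dt * f0[2]
      f1 <- f(pv, pw, I)
      newRow[i, ] <- c(v + dt / 2 * (f0[1] + f1[1]),
                       w + dt / 2 * (f0[2] + f1[2]))
    }
    X[cur + 1, , ] <- newRow
  }
  X[horizon + seq_len(nsteps), , , drop = FALSE]
}

## trapezoid quadrature on a fine grid (independent of stats::integrate)
trapezoidQuad <- function(f, lo, hi, n = 200001) {
  x <- seq(lo, hi, length.out = n)
  y <- f(x)
  h <- (hi - lo) / (n - 1)
  h * (sum(y) - (y[1] + y[n]) / 2)
}

## naive balloon-windkessel reference at a fine step (simple RK4 on the
## 4-state system with piecewise-constant neural drive)
naiveBalloon <- function(xFun, h, tEnd, dtFine) {
  st <- c(0, 1, 1, 1)
  deriv <- function(st, x) {
    s <- st[1]; f <- st[2]; v <- st[3]; q <- st[4]
    via <- v^(1 / h$alpha)
    E <- 1 - (1 - h$rho)^(1 / f)
    c(x - h$kappa * s - h$gamma * (f - 1),
      s,
      (f - via) / h$tau,
      (f * E / h$rho - via * q / v) / h$tau)
  }
  nst <- round(tEnd / dtFine)
  out <- matrix(0, nst, 4)
  for (k in seq_len(nst)) {
    t <- (k - 1) * dtFine
    x <- xFun(t)
    k1 <- deriv(st, x)
    k2 <- deriv(st + dtFine / 2 * k1, x)
    k3 <- deriv(st + dtFine / 2 * k2, x)
    k4 <- deriv(st + dtFine * k3, x)
    st <- st + dtFine / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[k, ] <- st
  }
  out
}
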