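## Phase-plane sampling for two-variable views of a model: vector field on
## a grid, RK4 example trajectories, nullcline points by sign change and
## bisection.

## single "network" of one node with all but the plane variables clamped
.planeDeriv <- function(model, planeVars, clamp) {
  nsv <- model@nSvar
  base <- array(0, c(1, nsv, model@nModes))
  for (s in seq_len(nsv)) base[1, s, ] <- clamp[s]
  function(x, y) {
    st <- base
    st[1, planeVars[1], ] <- x
    st[1, planeVars[2], ] <- y
    d <- evalDfun(model, st, coupling = 0, local = 0)
    c(d[1, planeVars[1], 1], d[1, planeVars[2], 1])
  }
}

#' Sample the phase plane of a model
#'
#' Evaluates the model derivative over a rectangular grid of two designated
#' state variables (others clamped), integrates example trajectories with
#' the deterministic RK4 scheme, and locates nullcline crossings along the
#' grid lines by sign change plus bisection.
#'
#' @param model a [ModelSpec-class].
#' @param box list `(xlim, ylim)` for the two plane variables.
#' @param planeVars indices of the two state variables spanning the plane.
#' @param clamp values for the remaining state variables (length `nSvar`;
#'   entries for the plane variables are ignored).
#' @param gridN grid points per axis.
#' @param starts matrix of trajectory starting points (rows = `(x, y)`).
#' @param trajectoryLength integration time per trajectory (ms).
#' @param dt RK4 step (ms).
#' @return list with `x`, `y` (grid axes), `U`, `V` (vector field),
#'   `trajectories` (list of two-column matrices), `nullclines` (list of
#'   two-column point matrices, one per plane variable).
#' @export
phasePlaneSample <- function(model, box, planeVars = c(1L, 2L),
                             clamp = numeric(model@nSvar), gridN = 20,
                             starts = NULL, trajectoryLength = 100,
                             dt = 0.05) {
  stopifnot(is(model, "ModelSpec"))
  if (length(box$xlim) != 2 || length(box$ylim) != 2 ||
      diff(box$xlim) <= 0 || diff(box$ylim) <= 0)
    stop("box must give increasing xlim and ylim")
  f <- .planeDeriv(model, planeVars, clamp)
  xs <- seq(box$xlim[1], box$xlim[2], length.out = gridN)
  ys <- seq(box$ylim[1], box$ylim[2], length.out = gridN)
  U <- V <- matrix(0, gridN, gridN)
  for (i in seq_len(gridN)) for (j in seq_len(gridN)) {
    d <- f(xs[i], ys[j])
    U[i, j] <- d[1]
    V[i, j] <- d[2]
  }

  spec <- rk4Integrator(dt)
  trajectories <- list()
  if (!is.null(starts)) {
    starts <- matrix(starts, ncol = 2)
    nstep <- round(trajectoryLength / dt)
    for (r in seq_len(nrow(starts))) {
      path <- matrix(0, nstep + 1, 2)
      path[1, ] <- starts[r, ]
      p <- starts[r, ]
      for (s in seq_len(nstep)) {
        p <- integrateStep(p, function(z) f(z[1], z[2]), spec)
        path[s + 1, ] <- p
      }
      trajectories[[r]] <- path
    }
  }

  ## nullclines: for each grid line, bisect sign changes of each component
  bisect <- function(g, lo, hi) {
    flo <- g(lo)
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      fm <- g(mid)
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    (lo + hi) / 2
  }
  nullclines <- list(matrix(0, 0, 2), matrix(0, 0, 2))
  for (comp in 1:2) {
    pts <- matrix(0, 0, 2)
    for (j in seq_len(gridN)) {          # scan along x at fixed y
      vals <- if (comp == 1) U[, j] else V[, j]
      sw <- which(diff(sign(vals)) != 0 & is.finite(vals[-gridN]))
      for (i in sw) {
        g <- function(x) f(x, ys[j])[comp]
        pts <- rbind(pts, c(bisect(g, xs[i], xs[i + 1]), ys[j]))
      }
    }
    for (i in seq_len(gridN)) {          # scan along y at fixed x
      vals <- if (comp == 1) U[i, ] else V[i, ]
      sw <- which(diff(sign(vals)) != 0 & is.finite(vals[-gridN]))
      for (j in sw) {
        g <- function(y) f(xs[i], y)[comp]
        pts <- rbind(pts, c(xs[i], bisect(g, ys[j], ys[j + 1])))
      }
    }
    nullclines[[comp]] <- pts
  }
  list(x = xs, y = ys, U = U, V = V, trajectories = trajectories,
       nullclines = nullclines)
}

#' Dominant spectral frequency of a time series
#'
#' Utility for spectral-peak checks on simulated activity: FFT power
#' spectrum of a (detrended) series, returning the frequency of maximum
#' power within an optional band.
#'
#' @param series numeric vector.
#' @param samplePeriod sampling period in ms.
#' @param band optional `c(lo, hi)` frequency band in Hz.
#' @return peak frequency (Hz).
#' @export
dominantFrequency <- function(series, samplePeriod, band = NULL) {
  x <- series - mean(series)
  n <- length(x)
  pw <- Mod(fft(x))^2
  freq <- (seq_len(n) - 1) / (n * samplePeriod / 1000)  # Hz
  half <- seq(2, floor(n / 2))
  pw <- pw[half]; freq <- freq[half]
  if (!is.null(band)) {
    keep <- freq >= band[1] & freq <= band[2]
    pw <- pw[keep]; freq <- freq[keep]
  }
  freq[which.max(pw)]
}
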