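## Neural mass models: right-hand-side derivative functions, state ranges,
## variables of interest and coupling variables, plus parameter
## spatialization and random initial histories.
##
## Every derivative function (dfun) is pure and vectorized over nodes. The
## state is a rank-3 array [nodes, state variables, modes]; the long-range
## coupling input has shape [nodes, coupling variables, modes]; the local
## input (instantaneous local coupling plus stimulation) is a per-node
## vector entering the model's designated drive term.

#' Neural mass model specification
#'
#' @slot name model identifier.
#' @slot nSvar number of state variables per node (N).
#' @slot nModes number of modes (M, 1 except for dispersed mean-field
#'   models).
#' @slot params named list; each entry a numeric vector of length 1 (shared)
#'   or `nNodes` (spatialized), plus any derived constant tables.
#' @slot stateRanges nSvar x 2 matrix of `[low, high]` per state variable,
#'   used for random initial conditions.
#' @slot voi integer indices of the variables of interest (what monitors
#'   record by default).
#' @slot cvar integer indices of the coupling variables (what propagates
#'   over long-range connections).
#' @slot dfun function `(state, coupling, local, params)` returning the time
#'   derivative with the same shape as `state`.
#' @export
setClass("ModelSpec",
  representation(name = "character", nSvar = "integer", nModes = "integer",
                 params = "list", stateRanges = "matrix", voi = "integer",
                 cvar = "integer", dfun = "function"))

setValidity("ModelSpec", function(object) {
  if (object@nSvar < 1L) return("nSvar must be >= 1")
  if (object@nModes < 1L) return("nModes must be >= 1")
  if (!all(dim(object@stateRanges) == c(object@nSvar, 2)))
    return("stateRanges must be nSvar x 2")
  if (any(object@stateRanges[, 2] < object@stateRanges[, 1]))
    return("stateRanges rows must be [low, high]")
  if (any(object@voi < 1 | object@voi > object@nSvar))
    return("voi out of range")
  if (any(object@cvar < 1 | object@cvar > object@nSvar))
    return("cvar out of range")
  TRUE
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec '%s': N = %d state variable(s), M = %d mode(s)\n",
              object@name, object@nSvar, object@nModes))
  cat("  coupling variable(s):", paste(object@cvar, collapse = ", "),
      " variables of interest:", paste(object@voi, collapse = ", "), "\n")
})

#' @describeIn ModelSpec evaluate the model derivative.
#' @param model a `ModelSpec`.
#' @param state array `[nodes, nSvar, nModes]`.
#' @param coupling long-range input, array `[nodes, length(cvar), nModes]`
#'   (or a scalar, broadcast).
#' @param local per-node instantaneous drive (local coupling + stimulus);
#'   scalar or length-nodes vector.
#' @export
evalDfun <- function(model, state, coupling = 0, local = 0) {
  stopifnot(is(model, "ModelSpec"))
  d <- dim(state)
  if (is.null(d) || length(d) != 3 || d[2] != model@nSvar ||
      d[3] != model@nModes)
    stop("state must be [nodes, ", model@nSvar, ", ", model@nModes, "]")
  n <- d[1]
  if (length(coupling) == 1)
    coupling <- array(coupling, c(n, length(model@cvar), model@nModes))
  cd <- dim(coupling)
  if (is.null(cd) || cd[1] != n || cd[2] != length(model@cvar))
    stop("coupling input shape does not match [nodes, n_cvar, modes]")
  if (length(local) == 1) local <- rep(local, n)
  if (length(local) != n) stop("local input must be scalar or length nodes")
  out <- model@dfun(state, coupling, local, model@params)
  if (!identical(dim(out), d)) stop("dfun returned a wrong shape")
  out
}

## parameter lookup broadcast over nodes: returns scalar or length-n vector
.p <- function(params, name) params[[name]]

#' Broadcast a model parameter over network nodes
#'
#' Length-1 values apply to every node; length-`nNodes` values are per-node
#' (spatialized parameters). Any other length is an error.
#'
#' @param value numeric vector of length 1 or `nNodes`.
#' @param nNodes number of nodes.
#' @return numeric vector of length `nNodes`.
#' @export
spatializeParameter <- function(value, nNodes) {
  if (!is.numeric(value)) stop("parameter must be numeric")
  if (length(value) == 1L) return(rep(value, nNodes))
  if (length(value) == nNodes) return(as.numeric(value))
  stop("parameter length ", length(value), " is neither 1 nor nNodes = ",
       nNodes)
}

## spatialize every plain numeric parameter of a model for an n-node network
.spatializeModel <- function(model, nNodes) {
  model@params <- lapply(model@params, function(p) {
    if (is.numeric(p) && is.null(dim(p)) && length(p) %in% c(1L, nNodes))
      spatializeParameter(p, nNodes)
    else p
  })
  model
}

#' Generic two-dimensional phase-plane oscillator
#'
#' A plane oscillator with a cubic nullcline, able to express excitable,
#' oscillatory and bistable population dynamics:
#' \deqn{\dot v = d\,\tau\,(\alpha w - f v^3 + e v^2 + g v + \gamma I)}
#' \deqn{\dot w = d\,(a + b v + c v^2 - \beta w)/\tau}
#' where `I` is the sum of the external current `Iext`, the long-range
#' coupling input and the local input. The defaults reduce it to the classic
#' FitzHugh-Nagumo oscillator (`alpha = -1`, `f = 1/3`, `g = 1`); `d`
#' rescales both time derivatives and so sets the oscillation frequency.
#'
#' @param tau time-scale separation between `v` and `w`.
#' @param a,b,c coefficients of the `w` nullcline polynomial.
#' @param d global rate scaling (1/ms).
#' @param e,f,g coefficients of the cubic `v` nullcline.
#' @param alpha,beta,gamma input gains on `w`, `w`-decay, and current.
#' @param Iext constant external current.
#' @return a [ModelSpec-class] with N = 2 (`v`, `w`), coupling variable `v`.
#' @export
genericOscillator2d <- function(tau = 3, a = 0.7, b = 1, c = 0, d = 1,
                                e = 0, f = 1 / 3, g = 1, alpha = -1,
                                beta = 0.8, gamma = 1, Iext = 0) {
  dfun <- function(state, coupling, local, p) {
    v <- state[, 1, , drop = FALSE]
    w <- state[, 2, , drop = FALSE]
    I <- p$Iext + coupling[, 1, , drop = FALSE] + local
    dv <- p$d * p$tau *
      (p$alpha * w - p$f * v^3 + p$e * v^2 + p$g * v + p$gamma * I)
    dw <- p$d * (p$a + p$b * v + p$c * v^2 - p$beta * w) / p$tau
    out <- array(0, dim(state))
    out[, 1, ] <- dv
    out[, 2, ] <- dw
    out
  }
  new("ModelSpec", name = "Generic2dOscillator", nSvar = 2L, nModes = 1L,
      params = list(tau = tau, a = a, b = b, c = c, d = d, e = e, f = f,
                    g = g, alpha = alpha, beta = beta, gamma = gamma,
                    Iext = Iext),
      stateRanges = rbind(c(-2, 2), c(-1, 1)), voi = 1L, cvar = 1L,
      dfun = dfun)
}

#' Wilson-Cowan firing-rate model
#'
#' Two coupled populations (excitatory `E`, inhibitory `I`) with logistic
#' response functions, per the classical 1972 formulation:
#' \deqn{\tau_e \dot E = -E + (k_e - r_e E)\,S_e(c_1 E - c_2 I + P + c_{lr})}
#' \deqn{\tau_i \dot I = -I + (k_i - r_i I)\,S_i(c_3 E - c_4 I + Q)}
#' with `S(x) = 1/(1 + exp(-a (x - theta))) - 1/(1 + exp(a theta))`, shifted
#' so `S(0) = 0`. Long-range coupling and local input enter the excitatory
#' drive.
#'
#' @param c1,c2,c3,c4 population coupling constants.
#' @param ae,thetaE,ai,thetaI sigmoid slope/threshold per population.
#' @param tauE,tauI population time constants (ms).
#' @param re,ri refractory parameters.
#' @param ke,ki maximal response.
#' @param P,Q constant external drives.
#' @return a [ModelSpec-class] with N = 2 (`E`, `I`), coupling variable `E`.
#' @export
wilsonCowan <- function(c1 = 12, c2 = 4, c3 = 13, c4 = 11, ae = 1.2,
                        thetaE = 2.8, ai = 1, thetaI = 4, tauE = 10,
                        tauI = 10, re = 1, ri = 1, ke = 1, ki = 1,
                        P = 0, Q = 0) {
  sig <- function(x, a, th) 1 / (1 + exp(-a * (x - th))) - 1 / (1 + exp(a * th))
  dfun <- function(state, coupling, local, p) {
    E <- state[, 1, , drop = FALSE]
    I <- state[, 2, , drop = FALSE]
    xe <- p$c1 * E - p$c2 * I + p$P + coupling[, 1, , drop = FALSE] + local
    xi <- p$c3 * E - p$c4 * I + p$Q
    out <- array(0, dim(state))
    out[, 1, ] <- (-E + (p$ke - p$re * E) * sig(xe, p$ae, p$thetaE)) / p$tauE
    out[, 2, ] <- (-I + (p$ki - p$ri * I) * sig(xi, p$ai, p$thetaI)) / p$tauI
    out
  }
  new("ModelSpec", name = "WilsonCowan", nSvar = 2L, nModes = 1L,
      params = list(c1 = c1, c2 = c2, c3 = c3, c4 = c4, ae = ae,
                    thetaE = thetaE, ai = ai, thetaI = thetaI, tauE = tauE,
                    tauI = tauI, re = re, ri = ri, ke = ke, ki = ki,
                    P = P, Q = Q),
      stateRanges = rbind(c(0, 0.5), c(0, 0.5)), voi = 1L, cvar = 1L,
      dfun = dfun)
}

#' Jansen-Rit sigmoid
#'
#' Population potential-to-rate function
#' `Sigm(v) = 2 e0 / (1 + exp(r (v0 - v)))`; `Sigm(v0) = e0`.
#'
#' @param v average membrane potential (mV).
#' @param e0 half-maximum firing rate (1/ms).
#' @param v0 potential at half maximum (mV).
#' @param r slope (1/mV).
#' @export
jansenRitSigmoid <- function(v, e0 = 0.0025, v0 = 6, r = 0.56)
  2 * e0 / (1 + exp(r * (v0 - v)))

#' Jansen-Rit cortical column model
#'
#' Three coupled subpopulations (pyramidal cells plus excitatory and
#' inhibitory interneurons), each a second-order synaptic kinetic, rewritten
#' as 6 first-order equations. States `y0..y5` (here indices 1..6):
#' \deqn{\dot y_0 = y_3,\quad \dot y_3 = A a\,S(y_1 - y_2) - 2 a y_3 - a^2 y_0}
#' \deqn{\dot y_1 = y_4,\quad \dot y_4 = A a (p + c_{lr} + C_2 S(C_1 y_0)) - 2 a y_4 - a^2 y_1}
#' \deqn{\dot y_2 = y_5,\quad \dot y_5 = B b C_4 S(C_3 y_0) - 2 b y_5 - b^2 y_2}
#' with `S` = [jansenRitSigmoid()]. Long-range coupling and local input are
#' added to the pyramidal drive `p`. With the classical parameters and a
#' constant drive in the working range the column oscillates in the alpha
#' band (~10 Hz).
#'
#' @param A,B excitatory/inhibitory synaptic gains (mV).
#' @param a,b lumped rate constants (1/ms).
#' @param C connectivity scale; `C1..C4` default to the usual fractions.
#' @param C1,C2,C3,C4 intra-column connectivity constants.
#' @param e0,v0,r sigmoid parameters, see [jansenRitSigmoid()].
#' @param p constant pyramidal input drive (1/ms).
#' @return a [ModelSpec-class] with N = 6; variables of interest `y1`, `y2`
#'   (their difference is the usual EEG proxy); coupling variable `y1`.
#' @export
jansenRit <- function(A = 3.25, B = 22, a = 0.1, b = 0.05, C = 135,
                      C1 = C, C2 = 0.8 * C, C3 = 0.25 * C, C4 = 0.25 * C,
                      e0 = 0.0025, v0 = 6, r = 0.56, p = 0.22) {
  dfun <- function(state, coupling, local, p_) {
    y0 <- state[, 1, , drop = FALSE]; y1 <- state[, 2, , drop = FALSE]
    y2 <- state[, 3, , drop = FALSE]; y3 <- state[, 4, , drop = FALSE]
    y4 <- state[, 5, , drop = FALSE]; y5 <- state[, 6, , drop = FALSE]
    S <- function(v) 2 * p_$e0 / (1 + exp(p_$r * (p_$v0 - v)))
    drive <- p_$p + coupling[, 1, , drop = FALSE] + local
    out <- array(0, dim(state))
    out[, 1, ] <- y3
    out[, 2, ] <- y4
    out[, 3, ] <- y5
    out[, 4, ] <- p_$A * p_$a * S(y1 - y2) - 2 * p_$a * y3 - p_$a^2 * y0
    out[, 5, ] <- p_$A * p_$a * (drive + p_$C2 * S(p_$C1 * y0)) -
      2 * p_$a * y4 - p_$a^2 * y1
    out[, 6, ] <- p_$B * p_$b * p_$C4 * S(p_$C3 * y0) -
      2 * p_$b * y5 - p_$b^2 * y2
    out
  }
  new("ModelSpec", name = "JansenRit", nSvar = 6L, nModes = 1L,
      params = list(A = A, B = B, a = a, b = b, C1 = C1, C2 = C2, C3 = C3,
                    C4 = C4, e0 = e0, v0 = v0, r = r, p = p),
      stateRanges = rbind(c(-1, 1), c(0, 25), c(0, 25), c(-2, 2),
                          c(-5, 5), c(-5, 5)),
      voi = c(2L, 3L), cvar = 2L, dfun = dfun)
}

#' Transfer function of the reduced Wong-Wang model
#'
#' `H(x) = (a x - b) / (1 - exp(-d (a x - b)))`, the effective
#' input-to-rate function; the singularity at `a x = b` is removable with
#' limit `1/d` (series `1/d + u/2 + d u^2 / 12` used near it for numerical
#' stability).
#'
#' @param x input current.
#' @param a,b,d transfer coefficients.
#' @export
wongWangH <- function(x, a = 270, b = 108, d = 0.154) {
  u <- a * x - b
  du <- d * u
  out <- ifelse(abs(du) < 1e-6,
                1 / d + u / 2 + d * u^2 / 12,
                u / (1 - exp(-du)))
  out
}

#' Reduced Wong-Wang two-variable decision model
#'
#' Two selective population gating variables `s1`, `s2` with slow NMDA
#' kinetics:
#' \deqn{\dot s_i = -s_i/\tau_s + (1 - s_i)\,\gamma\,H(x_i)}
#' \deqn{x_1 = J_{11} s_1 - J_{12} s_2 + I_0 + I_{ext} + c_{lr},\qquad
#'       x_2 = J_{22} s_2 - J_{21} s_1 + I_0}
#' with `H` = [wongWangH()] (rate in Hz; `gamma` carries the Hz-to-1/ms
#' conversion). Long-range coupling and local input enter `x1`.
#'
#' @param a,b,d transfer function coefficients.
#' @param gamma kinetic rate (per ms per Hz).
#' @param tauS gating time constant (ms).
#' @param J11,J22 recurrent self-coupling (nA).
#' @param J12,J21 cross inhibition (nA).
#' @param I0 common background current (nA).
#' @param Iext additional external current into population 1 (nA).
#' @return a [ModelSpec-class] with N = 2, coupling variable `s1`.
#' @export
reducedWongWang <- function(a = 270, b = 108, d = 0.154, gamma = 0.641e-3,
                            tauS = 100, J11 = 0.2609, J22 = 0.2609,
                            J12 = 0.0497, J21 = 0.0497, I0 = 0.3255,
                            Iext = 0) {
  dfun <- function(state, coupling, local, p) {
    s1 <- state[, 1, , drop = FALSE]
    s2 <- state[, 2, , drop = FALSE]
    x1 <- p$J11 * s1 - p$J12 * s2 + p$I0 + p$Iext +
      coupling[, 1, , drop = FALSE] + local
    x2 <- p$J22 * s2 - p$J21 * s1 + p$I0
    out <- array(0, dim(state))
    out[, 1, ] <- -s1 / p$tauS +
      (1 - s1) * p$gamma * wongWangH(x1, p$a, p$b, p$d)
    out[, 2, ] <- -s2 / p$tauS +
      (1 - s2) * p$gamma * wongWangH(x2, p$a, p$b, p$d)
    out
  }
  new("ModelSpec", name = "ReducedWongWang", nSvar = 2L, nModes = 1L,
      params = list(a = a, b = b, d = d, gamma = gamma, tauS = tauS,
                    J11 = J11, J22 = J22, J12 = J12, J21 = J21, I0 = I0,
                    Iext = Iext),
      stateRanges = rbind(c(0, 1), c(0, 1)), voi = 1L, cvar = 1L,
      dfun = dfun)
}

#' Mode-partition constants for a dispersed Gaussian parameter
#'
#' The dispersed-parameter mean field partitions a Gaussian-distributed
#' parameter `I ~ N(mu, sigma^2)` into three equal-probability intervals
#' (split at the 1/3 and 2/3 quantiles). Each mode carries the conditional
#' mean of `I` over its interval; the mode-mixing matrices hold the interval
#' probability masses. Both are obtained by numerical quadrature of the
#' Gaussian density (`sigma = 0` degenerates to three identical modes).
#'
#' @param mu mean of the dispersed parameter.
#' @param sigma dispersion width (>= 0).
#' @return list with `m` (3 conditional means), `mass` (3 interval masses)
#'   and `mix` (3 x 3 mixing matrix, rows identical to `mass`).
#' @export
dispersedModeConstants <- function(mu, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0)
    return(list(m = rep(mu, 3), mass = rep(1 / 3, 3),
                mix = matrix(1 / 3, 3, 3)))
  qs <- qnorm(c(1 / 3, 2 / 3), mean = mu, sd = sigma)
  lo <- c(-Inf, qs)
  hi <- c(qs, Inf)
  mass <- numeric(3)
  m <- numeric(3)
  for (i in 1:3) {
    mass[i] <- integrate(function(x) dnorm(x, mu, sigma), lo[i], hi[i],
                         rel.tol = 1e-10)$value
    m[i] <- integrate(function(x) x * dnorm(x, mu, sigma), lo[i], hi[i],
                      rel.tol = 1e-10)$value / mass[i]
  }
  list(m = m, mass = mass, mix = matrix(rep(mass, each = 3), 3, 3))
}

#' Three-mode FitzHugh-Nagumo mean field (dispersed parameter)
#'
#' Mean-field equations for globally coupled excitatory and inhibitory
#' FitzHugh-Nagumo populations whose external current is Gaussian-dispersed
#' across neurons. The dispersion partitions each population into M = 3
#' modes (see [dispersedModeConstants()]); per node and mode `i`:
#' \deqn{\dot\xi_i = d\,[\tau(\xi_i - f\xi_i^3 - \eta_i)
#'   + K_{11}(\textstyle\sum_j A_{ij}\xi_j - \xi_i)
#'   - K_{12}(\sum_j B_{ij}\alpha_j - \xi_i) + \tau(m_i + c_{lr} + local)]}
#' \deqn{\dot\eta_i = d\,(\xi_i + a - b\eta_i)/\tau}
#' \deqn{\dot\alpha_i = d\,[\tau(\alpha_i - f\alpha_i^3 - \beta_i)
#'   + K_{21}(\sum_j C_{ij}\xi_j - \alpha_i) + \tau m_i]}
#' \deqn{\dot\beta_i = d\,(\alpha_i + a - b\beta_i)/\tau}
#' State `[xi, eta, alpha, beta]` x 3 modes = 12 variables per node. With
#' `sigma = 0` all three modes carry identical dynamics.
#'
#' @param tau,a,b,f FitzHugh-Nagumo constants.
#' @param d global rate scaling (1/ms).
#' @param K11,K12,K21 excitatory-excitatory, inhibitory-to-excitatory and
#'   excitatory-to-inhibitory coupling strengths.
#' @param mu,sigma mean and width of the dispersed external current.
#' @return a [ModelSpec-class] with N = 4, M = 3, coupling variable `xi`.
#' @export
stefanescuJirsa2d <- function(tau = 3, a = 0.7, b = 0.8, f = 1 / 3, d = 1,
                              K11 = 0.5, K12 = 0.15, K21 = 0.15,
                              mu = 0.5, sigma = 0.35) {
  mc <- dispersedModeConstants(mu, sigma)
  dfun <- function(state, coupling, local, p) {
    xi <- state[, 1, , drop = TRUE]     # [nodes, 3]
    eta <- state[, 2, , drop = TRUE]
    al <- state[, 3, , drop = TRUE]
    be <- state[, 4, , drop = TRUE]
    if (is.null(dim(xi))) {             # single node: keep [1, 3]
      xi <- matrix(xi, 1); eta <- matrix(eta, 1)
      al <- matrix(al, 1); be <- matrix(be, 1)
    }
    mix <- p$modeConstants$mix
    m <- p$modeConstants$m
    xiMix <- xi %*% t(mix)              # [nodes, 3]: sum_j mix[i,j] xi_j
    alMix <- al %*% t(mix)
    cin <- coupling[, 1, , drop = TRUE]
    if (is.null(dim(cin))) cin <- matrix(cin, nrow(xi))
    mrow <- matrix(m, nrow(xi), 3, byrow = TRUE)
    dxi <- p$d * (p$tau * (xi - p$f * xi^3 - eta) +
                    p$K11 * (xiMix - xi) - p$K12 * (alMix - xi) +
                    p$tau * (mrow + cin + local))
    deta <- p$d * (xi + p$a - p$b * eta) / p$tau
    dal <- p$d * (p$tau * (al - p$f * al^3 - be) +
                    p$K21 * (xiMix - al) + p$tau * mrow)
    dbe <- p$d * (al + p$a - p$b * be) / p$tau
    out <- array(0, dim(state))
    out[, 1, ] <- dxi
    out[, 2, ] <- deta
    out[, 3, ] <- dal
    out[, 4, ] <- dbe
    out
  }
  new("ModelSpec", name = "StefanescuJirsa2D", nSvar = 4L, nModes = 3L,
      params = list(tau = tau, a = a, b = b, f = f, d = d, K11 = K11,
                    K12 = K12, K21 = K21, mu = mu, sigma = sigma,
                    modeConstants = mc),
      stateRanges = rbind(c(-2, 2), c(-1, 1), c(-2, 2), c(-1, 1)),
      voi = 1L, cvar = 1L, dfun = dfun)
}

#' Random initial history for a model
#'
#' Fills the delay horizon with uniform draws inside each state variable's
#' range, the minimal network state with time delays before t = 0.
#'
#' @param model a [ModelSpec-class].
#' @param nNodes number of nodes.
#' @param horizon history depth in steps (>= 1).
#' @param seed integer seed, or an `rng_stream` to draw from.
#' @return array `[horizon, nNodes, nSvar, nModes]`.
#' @export
randomInitialState <- function(model, nNodes, horizon, seed = 42) {
  stopifnot(is(model, "ModelSpec"))
  if (horizon < 1) stop("horizon must be >= 1")
  rng <- model@stateRanges
  if (any(!is.finite(rng))) stop("state ranges must be finite")
  stream <- if (inherits(seed, "rng_stream")) seed else makeStream(seed)
  out <- array(0, c(horizon, nNodes, model@nSvar, model@nModes))
  for (s in seq_len(model@nSvar)) {
    nd <- horizon * nNodes * model@nModes
    out[, , s, ] <- array(streamUnif(stream, nd, rng[s, 1], rng[s, 2]),
                          c(horizon, nNodes, model@nModes))
  }
  out
}
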