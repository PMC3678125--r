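---
title: "Simulating delay-coupled neural mass networks with neuromass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating delay-coupled neural mass networks with neuromass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromass)
```

## The model class

A whole-brain network model couples `n` neural mass models — low-dimensional
ODE systems for the mean activity of a neuronal population — through a
weighted connectome with conduction delays. Writing the state of node `i`
as a vector $x_i$ (with $N$ state variables and, for dispersed mean-field
models, $M$ modes), the dynamics integrated by this package are

$$\dot x_i(t) = f_\theta\!\big(x_i(t)\big)
  + g\!\Big(\textstyle\sum_j W_{ij}\, \xi_j\big(t - \tau_{ij}\big)\Big)
  + L_i(t) + u_i(t) + \text{noise},$$

where $f_\theta$ is the local model, $\xi_j$ the coupling variables of node
`j` (the subset of its state transmitted over long-range connections),
$W_{ij}$ the connection strength *into* `i` *from* `j`, $\tau_{ij} =
\ell_{ij}/v$ the conduction delay from tract length and transmission speed,
$g$ the long-range coupling function (linear or sigmoidal), $L_i$
instantaneous local (mesh-neighbourhood) coupling in surface mode, and
$u_i$ the stimulus.

Delays are discretized to whole integration steps by rounding
$\ell_{ij}/v/\Delta t$ half away from zero; sub-step delays round to zero
(no minimum-one-step floor is imposed). The *horizon* — the depth of the
coupling-variable ring buffer — is the maximum delay plus one slot for the
current state; at $\Delta t = 2^{-4}$ ms a 20 ms maximal delay therefore
keeps 320 past states.

The coupling transform is applied **after** aggregation, i.e. to the
weighted sum of delayed afferent activity, which makes the delayed network
input literally a matrix product with the connectome followed by an
elementwise transform. Applying a sigmoid per afferent before summation is
a different (also defensible) convention; the post-aggregation form was
chosen because it keeps the update a single dot product and covers the
linear case exactly. Coupling input read at a step always refers to state
strictly before that step's write; for zero-step delays this is the
standard explicit-scheme approximation (and it is exact for delays of one
step or more).

## Population models

The paperwork of every model is the same: a derivative function that is
pure and vectorized over nodes, a state-range table used for random
initial histories, declared coupling variables and variables of interest,
and parameters that may be scalars (shared) or per-node vectors
(spatialized). The implemented models:

* `genericOscillator2d()` — a plane oscillator with a cubic nullcline,
  $\dot v = d\,\tau(\alpha w - f v^3 + e v^2 + g v + \gamma I)$,
  $\dot w = d\,(a + b v + c v^2 - \beta w)/\tau$. The defaults reduce it to
  the classical FitzHugh–Nagumo system ($\alpha = -1$, $f = 1/3$, $g = 1$,
  $\beta = 0.8$, $a = 0.7$, $\tau = 3$). The rate scale `d` multiplies both
  equations and therefore sets the oscillation frequency without changing
  the orbit's shape: with `Iext = 0.5` (inside the limit-cycle regime) and
  `d = 0.42` an isolated node oscillates near 40 Hz, the configuration
  used as `demoOscillator()` throughout the tests. The exact parameter set
  is a package choice: it was fixed once from the frequency-scaling
  property of `d`, and the spectral check asserts a band (30–50 Hz), not a
  point value.
* `wilsonCowan()` — the classical excitatory/inhibitory firing-rate pair
  with logistic response functions shifted so $S(0) = 0$; long-range input
  enters the excitatory drive.
* `jansenRit()` — the three-population cortical column (pyramidal cells,
  excitatory and inhibitory interneurons) as six first-order equations
  with the sigmoid $\mathrm{Sigm}(v) = 2e_0/(1+e^{r(v_0 - v)})$. With the
  standard constants and a constant drive `p = 0.22` (inside the
  physiological 0.12–0.32 range) an isolated column oscillates near 10 Hz;
  the EEG proxy is $y_1 - y_2$.
* `reducedWongWang()` — two slow NMDA gating variables with the
  divisive-singularity transfer $H(x) = (ax - b)/(1 - e^{-d(ax-b)})$,
  whose removable singularity at $ax = b$ (value $1/d$) is evaluated by a
  series expansion near the switch point.
* `stefanescuJirsa2d()` — a three-mode mean field of coupled
  FitzHugh–Nagumo excitatory and inhibitory populations whose external
  current is Gaussian-dispersed across neurons ($N = 4$, $M = 3$; 12 state
  variables per node).

### Mode partitioning in the dispersed mean field

The source material defines the multi-modal models by citation rather than
printed equations, so the mode machinery here is the package's own
faithful construction: the dispersed current $I \sim \mathcal N(\mu,
\sigma^2)$ is partitioned into three equal-probability intervals at the
$1/3$ and $2/3$ Gaussian quantiles. Each mode carries the conditional mean
of $I$ over its interval (its effective drive), and modes mix through the
interval probability masses. Both sets of constants are computed by
numerical quadrature of the Gaussian density (`stats::integrate`, relative
tolerance $10^{-10}$) at model construction; the tests recompute them with
an independent trapezoid rule. With $\sigma = 0$ the three modes collapse
onto identical dynamics, which the tests verify trajectory-for-trajectory.

## Integration and noise

Euler and Heun support deterministic and stochastic use; classical RK4 is
deterministic-only (stochastic Runge–Kutta variants with dependable
convergence are a research topic of their own) and is used for
phase-plane trajectories. Stochastic Heun applies the *same* Wiener
increment in predictor and corrector (the Stratonovich-consistent
construction), which has two useful consequences: the scheme degenerates
bit-for-bit to deterministic Heun at zero noise intensity, and empirical
convergence orders on $\dot y = -y$ come out at 1, 2 and 4 for the three
schemes.

White noise contributes Gaussian increments of variance $2 D \Delta t$ per
step and state variable. Colored noise is an Ornstein–Uhlenbeck process
advanced by its exact update
$x' = x e^{-\Delta t/\tau_c} + \sqrt{(D/\tau_c)(1 - e^{-2\Delta
t/\tau_c})}\,\xi$ — exact rather than Euler-approximated so that its lag
autocorrelation is $e^{-k\Delta t/\tau_c}$ at any step size. Multiplicative
noise scales the increment by a user function of the state (default
$g(x) = x$). Random streams are independently seedable environments
wrapping R's generator; their state can be saved and restored, which is
what makes stochastic continuation exact.

Step sizes follow the conventions of neural-mass work: $\Delta t$ between
$2^{-2}$ and $2^{-6}$ ms depending on the model's fastest rates. These are
explicit schemes: the cubic branches of the plane oscillator put a
stability bound near $\Delta t\,|f'| \lesssim 2$, and the divergence guard
aborts with the offending step and node when a trajectory passes $10^6$
times the state-range width.

## The simulation loop, history and continuation

`configureSimulator()` computes the delay table, spatializes parameters,
and fills the history ring buffer — only the coupling variables are
stored, which is the memory contract that makes large delay horizons
affordable. Initial conditions may be supplied as a
`[steps, nodes, svar, modes]` array; if shorter than the horizon, the
supplied slice occupies the *most recent* slots and the older remainder is
drawn uniformly from the model's state ranges (the same rule as a fully
random start). Which end counts as "recent" is a convention; it is stated
here and asserted slot-by-slot in the tests.

Each step computes the delayed aggregate input (a gather over the ring
buffer followed by a row-sum against the weights), applies the coupling
function, adds local coupling and stimulus, advances the state, pushes the
new coupling variables into the ring, and offers the state to each
monitor. Monitors see the post-integration state. Because the history, the
random-stream state and all monitor accumulators live in the simulator's
environment, a run can be stopped, parameters modified, and resumed:
an unmodified 2 × 500 ms resumed run equals a single 1000 ms run
bit-exactly, deterministic or stochastic. The step size, transmission
speed and spatial support are frozen at configuration — changing them
mid-run is refused, since they would silently invalidate the delay table
or the history shape.

## Stimulation and surface mode

Stimuli factorize exactly into a temporal equation times per-node spatial
weights. Pulse trains use half-open `[onset, onset + width)` windows so
step-grid sampling is unambiguous. On meshes, spatial profiles are
evaluated as a function of Euclidean distance from focal vertices
(geodesic distance would be the refinement for folded cortices); profiles
have finite support and multiple focal points combine by maximum by
default — summation is available, but max avoids double-counting where
kernels overlap.

Surface mode is implemented at toy scale (up to ~10^3 vertices): vertices
are the simulated nodes, long-range input is computed on region-averaged
vertex activity through the region connectome and expanded back to
vertices, and a sparse local kernel couples neighbouring vertices with no
delay. Non-cortical structures are not appended as extra nodes in this
implementation — the toy meshes in the tests are fully cortical — and
mesh sizes beyond toy scale would want the dense distance computations
replaced with spatial indexing. Both are known limitations, not
contracts.

## Monitors and forward models

Raw-family monitors return `[time, state variables, space, modes]`; the
raw monitor keeps every step and every state variable, while subsampling,
temporal averaging and spatial averaging reduce the stream online (the
temporal average of a window equals the arithmetic mean of the raw stream
over that window, a cross-monitor identity the tests check). Biophysical
monitors return `[time, 1, sensors, 1]`: EEG/MEG multiply a consumed
lead-field gain matrix into the source activity (sum, optionally mean,
over the variables of interest); computing gain matrices from head models
is out of scope, but intracranial point-dipole gains in a homogeneous
medium are provided
($q\cdot(r_k - r_i)/4\pi\sigma\|r_k - r_i\|^3$, with conductivity
defaulting to 1 S/m — a scale factor only in this model).

The BOLD monitor drives a balloon–windkessel system per node (vasodilatory
signal, inflow, volume, deoxyhemoglobin; resting point $(0,1,1,1)$) with
the standard constants $\kappa = 0.65\,\mathrm{s^{-1}}$, $\gamma =
0.41\,\mathrm{s^{-1}}$, $\tau = 0.98$ s, $\alpha = 0.32$, $\rho = 0.34$,
$V_0 = 0.02$, $k_1 = 7\rho$, $k_2 = 2$, $k_3 = 2\rho - 0.2$ (all
overridable). The neural drive is the model's first variable of interest,
mode-averaged. The hemodynamic states advance by RK4 with the drive frozen
over each integration step, so the monitor agrees with a fine-step
reference integration to well below $10^{-6}$ while sampling the readout
$y = V_0\big(k_1(1-q) + k_2(1 - q/v) + k_3(1 - v)\big)$ only every few
hundred ms.

## Metrics and parameter sweeps

Two scalar map metrics summarise a simulated array: the *global variance*
(zero-center every individual series, population variance over all points)
and the *variance of node variances* (per node, variance of the
concatenated centered svar × mode series; then the population variance of
those per-node values). Population (divide-by-$n$) denominators are used
throughout — the convention is stated because either choice is common.

Multiscale entropy coarse-grains a series by non-overlapping window means
and computes sample entropy per scale with $m = 2$ and tolerance $r =
0.15\,\mathrm{SD}$ of the original series, the SD held fixed across scales
per the standard procedure. A constant series scores 0 at every scale;
white noise is non-increasing across scales on seed-averaged data.

`parameterSweep()` runs one simulation per cell of a two-axis grid — each
cell a pure function of its parameters and seed, so the grid is trivially
parallelizable by any external scheduler — and reduces a chosen monitor to
the metric grids. The demonstration sweep in the acceptance material uses
the 74-node, two-hemisphere synthetic connectome (integer weights 0–3,
tract lengths from inter-centre distances) with the 40 Hz plane-oscillator
configuration, an 8 × 8 grid of coupling strength ($2 \times 10^{-4}$
doubling to $2.56 \times 10^{-2}$) against transmission speed (1–16
mm/ms), 500 ms per cell at $\Delta t = 0.25$ ms with a 100 ms transient
discarded — sizes chosen to keep a full sweep under a minute on one core
while leaving the weak-coupling plateau, the collapse under strong
coupling, and the speed-dependent transition zone clearly resolved. The
coupling axis stops below the explicit-scheme stability edge identified
above.

## Synthetic data: what it does and does not emulate

`generateSyntheticConnectome()` reproduces the *structure* of a
parcellation-level demonstration connectome: two hemispheres, symmetric
integer weights in `0..weightLevels-1`, zero diagonals, centres on ~70 mm
hemispheric shells, tract lengths equal to Euclidean inter-centre
distances. It does not emulate the topology of real tractography (no
distance-dependent connection probability, no homotopic emphasis, no
log-normal weight tails), so passing tests demonstrate the *mechanics* of
delay-coupled simulation and metric mapping, not anatomical realism.
Likewise the white/OU noise has no spatial correlation across nodes, and
lead fields in the tests are synthetic mixing matrices, not head-model
solutions.

## Numerical conventions, in one place

* Delay rounding: half away from zero; sub-step delays are instantaneous.
* Horizon: max delay + 1 (the current state occupies one slot).
* Heun freezes coupling, local and stimulus inputs within the step.
* Zero-intensity noise short-circuits to exact zeros without consuming
  random numbers (so stochastic and deterministic code paths coincide).
* Nullclines in the phase-plane tool are located by sign change plus 60
  bisection iterations along both grid directions.
* Divergence guard: any state magnitude beyond $10^6 \times$ the state
  range width aborts with step and node diagnostics.
* ZIP archives are written with stored (uncompressed) entries and numbers
  at 17 significant digits, so a write/read cycle is bit-exact.
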