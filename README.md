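# neuromass

Delay-coupled neural mass network simulation on connectomes, in R.

Whole-brain network models place a neural mass model — a small ODE system
for the mean activity of a neuronal population — at every region of a
structural connectome and couple the regions through weighted connections
with conduction delays. `neuromass` implements the full simulation chain
for such models:

* **Connectomes**: import from ZIP archives of delimited ASCII matrices
  (`weights.txt` — the historical `weigths.txt` spelling is accepted —
  `tract_lengths.txt`, optional positions/areas/orientations), a synthetic
  two-hemisphere generator, and conversion of tract lengths and
  transmission speed into integer step delays.
* **Population models**: a generic plane oscillator (FitzHugh–Nagumo as its
  default special case), Wilson–Cowan, Jansen–Rit, the reduced Wong–Wang
  decision model, and a three-mode dispersed-parameter FitzHugh–Nagumo
  mean field (N = 4, M = 3).
* **Dynamics**: node equations

  $$\dot x_i = f(x_i) + g\Big(\sum_j W_{ij}\,\xi_j(t - \ell_{ij}/v)\Big)
    + L_i + u_i(t) + \text{noise},$$

  with linear or sigmoidal coupling functions `g`, a ring-buffer history
  over the delay horizon, spatiotemporal stimuli `u`, and instantaneous
  local coupling `L` on toy cortical meshes.
* **Integration**: fixed-step Euler, Heun and RK4; stochastic Euler and
  Heun with seedable white or Ornstein–Uhlenbeck (colored) noise streams;
  bit-exact simulation continuation with mid-run parameter changes.
* **Monitors**: raw, subsampled, temporally/spatially averaged state
  streams (`[time, svar, space, modes]`); EEG/MEG lead-field projection,
  intracranial point-dipole gains, and a balloon–windkessel BOLD forward
  model (`[time, 1, sensors, 1]`).
* **Exploration**: two-axis parameter sweeps reduced to the global
  variance and the variance of node variances, multiscale (sample)
  entropy, and a phase-plane sampler (vector field, RK4 trajectories,
  nullclines).

## Worked example

Simulate half a second of a 74-region network whose nodes are plane
oscillators tuned so an isolated node fires at ~40 Hz, and summarise the
collective dynamics:

```r
library(neuromass)

conn <- generateSyntheticConnectome(nRegions = 74, weightLevels = 4,
                                    seed = 42)
conn
#> Connectome with 74 regions
#>   weights: [ 0, 3 ], 3992 non-zero connections
#>   tract lengths (mm): max 140.4233
#>   speed (mm/ms): 4

cfg <- simulationConfig(
  connectome = conn,
  model      = genericOscillator2d(Iext = 0.5, d = 0.42),  # ~40 Hz node
  coupling   = linearCoupling(a = 0.01),                   # global strength
  integrator = heunIntegrator(dt = 0.25),                  # ms
  monitors   = list(tavg = temporalAverageMonitor(period = 1)),
  seed = 1)

res <- simulateNetwork(cfg, length = 500)   # ms
res$tavg
#> TimeSeriesResult: 500 samples x 1 svar x 74 space x 1 modes @ 1 ms

globalVariance(res$tavg)
#> [1] 0.2882586
varianceOfNodeVariances(res$tavg)
#> [1] 0.003874187
```

The global variance summarises overall fluctuation amplitude; the
variance of node variances measures how heterogeneous the regions'
temporal variability is. At this coupling strength (`a = 0.01`) the
network sits past the weak-coupling plateau: the same run with
`a = 0.0004` gives a global variance near 1.63 (independent oscillators),
and `parameterSweep()` maps the whole transition over a coupling ×
transmission-speed grid.

A thin command-line wrapper over the same functions lives at
`inst/scripts/neuromass-cli.R` (`simulate`, `sweep`, `analyze`,
`phase-plane` subcommands on a JSON configuration; see
`readSimulationConfig()`).

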