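Package: neuromass
Title: Delay-Coupled Neural Mass Network Simulation on Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation of whole-brain network dynamics built from neural mass
    models coupled through a weighted connectome with conduction delays.
    Provides connectome import from ZIP archives of ASCII matrices, a set of
    population models (generic plane oscillator, Wilson-Cowan, Jansen-Rit,
    reduced Wong-Wang, and a three-mode dispersed-parameter FitzHugh-Nagumo
    mean field), linear and sigmoidal long-range coupling, deterministic and
    stochastic fixed-step integration (Euler, Heun, RK4) with seedable white
    and Ornstein-Uhlenbeck noise streams, spatiotemporal stimulation patterns,
    raw and biophysical monitors (temporal/spatial averaging, EEG/MEG lead
    field projection, intracranial point-dipole gains, balloon-windkessel
    BOLD), toy-scale surface simulation with instantaneous local coupling,
    simulation continuation, and parameter-sweep drivers with variance and
    multiscale-entropy summary metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
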