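Package: popdens
Title: Population Density Simulation of Spiking Neural Populations on
    State-Space Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates networks of interacting populations of 1D/2D point
    neurons with the grid-based population density technique. The state
    space of an arbitrary user-supplied neuron model is discretised into a
    rectangular grid; a sparse stochastic transition matrix for the
    deterministic dynamics is pre-computed geometrically by translating
    each grid cell one time step and measuring exact area overlaps via
    recursive triangulation. During simulation, Poisson shot noise is
    applied by integrating a master equation with per-connection jump
    matrices, and threshold-reset dynamics with refractory queues yield
    population firing rates. Networks of populations with typed, delayed
    connections are described in an XML dialect. A direct Monte-Carlo
    simulator of finite neuron ensembles is included as a validation
    reference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'grid.R'
    'neuron-models.R'
    'transition.R'
    'jump.R'
    'master.R'
    'model-io.R'
    'reset.R'
    'network.R'
    'sim-config.R'
    'reporting.R'
    'monte-carlo.R'
    'popdens-package.R'
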