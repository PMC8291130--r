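#' @include AllGenerics.R
NULL

#' Point-neuron model with a 2D vector field
#'
#' A `NeuronModel` bundles the deterministic dynamics of a 1D or 2D point
#' neuron with the parameters needed to simulate a population of such
#' neurons with the grid population density technique: the integration
#' time step, the threshold/reset mechanic and the orientation in which
#' incoming spikes displace the state.
#'
#' The vector field is a function `f(y, t)` where `y` is a list of two
#' numeric vectors (first and second state variable; vectorised evaluation
#' is required) and `t` is a placeholder time argument that is accepted but
#' ignored (only autonomous systems are supported). It must return a list
#' of the two time derivatives *in model time units*. `timescale` is the
#' number of seconds per model time unit (e.g. `1e-3` for a model written
#' in milliseconds), so one Euler step of `dt` seconds advances the state
#' by `(dt / timescale) * f(y)`.
#'
#' 1D models are represented in 2D with an inert second variable
#' (`d h/dt = 0`); the vertical axis of the grid then carries no meaning.
#'
#' @slot name identifier of the model.
#' @slot vectorField function of `(y, t)`, see Details.
#' @slot timestep default simulation time step, seconds.
#' @slot timescale seconds per model time unit.
#' @slot thresholdV membrane-potential threshold; `Inf` disables the
#'   threshold-reset mechanic.
#' @slot resetV membrane potential to which mass/neurons are reset.
#' @slot resetShiftH additive shift applied to the second variable on reset
#'   (e.g. the `d` parameter of the Izhikevich simple model).
#' @slot refractoryPeriod seconds of hold time after a threshold crossing.
#' @slot efficacyOrientation `"v"` or `"h"`: the dimension in which an
#'   incoming spike causes an instantaneous jump.
#' @slot tolerance maximum allowed per-step state displacement; exceeding
#'   it triggers a warning during transition-matrix generation.
#' @seealso [neuronModel()], [modelArchive()], [eulerStep()]
#' @export
setClass("NeuronModel",
  representation(
    name = "character",
    vectorField = "function",
    timestep = "numeric",
    timescale = "numeric",
    thresholdV = "numeric",
    resetV = "numeric",
    resetShiftH = "numeric",
    refractoryPeriod = "numeric",
    efficacyOrientation = "character",
    tolerance = "numeric"
  )
)

setValidity("NeuronModel", function(object) {
  msg <- character(0)
  if (length(object@timestep) != 1 || !is.finite(object@timestep) ||
      object@timestep <= 0)
    msg <- c(msg, "'timestep' must be a single positive number")
  if (length(object@timescale) != 1 || !is.finite(object@timescale) ||
      object@timescale <= 0)
    msg <- c(msg, "'timescale' must be a single positive number")
  if (length(object@refractoryPeriod) != 1 || object@refractoryPeriod < 0)
    msg <- c(msg, "'refractoryPeriod' must be >= 0")
  if (!object@efficacyOrientation %in% c("v", "h"))
    msg <- c(msg, "'efficacyOrientation' must be \"v\" or \"h\"")
  if (is.finite(object@thresholdV) && object@resetV >= object@thresholdV)
    msg <- c(msg, "'resetV' must be below 'thresholdV'")
  if (length(msg)) msg else TRUE
})

#' Rectangular discretisation of a 2D state space
#'
#' A `StateGrid` splits the rectangle
#' \eqn{[v_{min}, v_{max}] \times [h_{min}, h_{max}]} into
#' `nV * nH` identical axis-aligned rectangular cells. Cell `(i, j)`
#' (1-based; `i` = column along the first dimension, `j` = row along the
#' second) spans the half-open rectangle
#' \eqn{[v_{min} + (i-1) w, v_{min} + i w) \times
#'      [h_{min} + (j-1) c, h_{min} + j c)}
#' with `w = cellWidth(grid)` and `c = cellHeight(grid)`; a point exactly
#' on the upper bound of the grid belongs to the last column/row. The
#' linear cell index is `(j - 1) * nV + i`.
#'
#' @slot vMin,vMax bounds of the first (v) dimension.
#' @slot hMin,hMax bounds of the second (h) dimension.
#' @slot nV,nH number of columns and rows.
#' @seealso [buildGrid()], [cellIndex()], [cellOf()]
#' @export
setClass("StateGrid",
  representation(
    vMin = "numeric", vMax = "numeric",
    hMin = "numeric", hMax = "numeric",
    nV = "integer", nH = "integer"
  )
)

setValidity("StateGrid", function(object) {
  msg <- character(0)
  if (!(is.finite(object@vMin) && is.finite(object@vMax) &&
        object@vMin < object@vMax))
    msg <- c(msg, "v bounds must be finite with vMin < vMax")
  if (!(is.finite(object@hMin) && is.finite(object@hMax) &&
        object@hMin < object@hMax))
    msg <- c(msg, "h bounds must be finite with hMin < hMax")
  if (object@nV < 1L || object@nH < 1L)
    msg <- c(msg, "resolution must be at least 1 in each dimension")
  if (length(msg)) msg else TRUE
})

#' Sparse stochastic transition matrix over a state-space grid
#'
#' Stores the proportions of probability mass moved between grid cells,
#' either by one deterministic time step of the neuron dynamics
#' (`kind = "deterministic"`) or by a single incoming spike
#' (`kind = "jump"`). The matrix is held as a sparse `dgCMatrix` `P` with
#' `P[target, source]` equal to the proportion of the source cell's mass
#' delivered to the target cell, so that one application is
#' `P %*% mass` and every column sums to 1 (mass conservation under the
#' boundary policy).
#'
#' @slot matrix the `dgCMatrix` propagator (target x source).
#' @slot dt the generating time step in seconds (`NA` for jump matrices).
#' @slot kind `"deterministic"` or `"jump"`.
#' @slot nV,nH resolution of the generating grid, for compatibility checks.
#' @seealso [generateDeterministicMatrix()], [buildJumpMatrix()],
#'   [writeTmat()], [readTmat()]
#' @export
setClass("TransitionMatrix",
  representation(
    matrix = "dgCMatrix",
    dt = "numeric",
    kind = "character",
    nV = "integer",
    nH = "integer"
  )
)

setValidity("TransitionMatrix", function(object) {
  msg <- character(0)
  if (!object@kind %in% c("deterministic", "jump"))
    msg <- c(msg, "'kind' must be \"deterministic\" or \"jump\"")
  m <- object@matrix
  if (nrow(m) != ncol(m))
    msg <- c(msg, "transition matrix must be square")
  if (nrow(m) != as.integer(object@nV) * as.integer(object@nH))
    msg <- c(msg, "matrix dimension does not match the grid resolution")
  if (length(m@x) && min(m@x) < 0)
    msg <- c(msg, "all proportions must be >= 0")
  cs <- Matrix::colSums(m)
  if (any(abs(cs - 1) > 1e-9))
    msg <- c(msg, sprintf(
      "source-cell proportions must sum to 1 within 1e-9 (worst deviation %.3g)",
      max(abs(cs - 1))))
  if (length(msg)) msg else TRUE
})

#' Mapping from threshold cells to reset cells, with refractory queues
#'
#' Cells whose lower v-edge lies at or above the threshold column are
#' "threshold cells": probability mass arriving there is removed from the
#' grid (generating the population firing rate) and held in a per-cell
#' refractory queue before being re-injected at the reset potential.
#' Each threshold cell `(i, j)` maps to the reset cell in the column
#' containing `resetV`, in row `j + round(resetShiftH / cellHeight)`.
#'
#' Queues have `max(1, ceiling(r / dt)) + 1` slots where `r` is the
#' refractory period; the final slot is the Fig.-4-style "final place".
#' Each step the queue shifts one slot, and the mass delivered to the
#' reset cell is `q[last] + w * q[last - 1]` with delivery weight
#' `w = 1 - (r/dt - floor(r/dt))` (so an integer-multiple refractory
#' period delivers each packet in a single step, and e.g. `r = 1.5 dt`
#' splits a packet 0.5/0.5 over two consecutive steps).
#'
#' @slot thresholdCells integer linear indices of the threshold cells
#'   (possibly empty, which disables the threshold-reset mechanic).
#' @slot resetCells integer linear indices, parallel to `thresholdCells`.
#' @slot queueLength number of slots per refractory queue.
#' @slot deliveryWeight the interpolation weight `w` above.
#' @slot refractoryPeriod,dt the values the queue geometry was derived from.
#' @slot aggregator sparse matrix (nCells x nThresholdCells) accumulating
#'   delivered queue mass into reset cells.
#' @seealso [buildResetMapping()], [stepReset()]
#' @export
setClass("ResetMapping",
  representation(
    thresholdCells = "integer",
    resetCells = "integer",
    queueLength = "integer",
    deliveryWeight = "numeric",
    refractoryPeriod = "numeric",
    dt = "numeric",
    aggregator = "dgCMatrix"
  )
)

setValidity("ResetMapping", function(object) {
  msg <- character(0)
  if (length(object@thresholdCells) != length(object@resetCells))
    msg <- c(msg, "'thresholdCells' and 'resetCells' must be parallel")
  if (object@queueLength < 2L)
    msg <- c(msg, "queues need at least two slots (head and final place)")
  if (object@deliveryWeight < 0 || object@deliveryWeight > 1)
    msg <- c(msg, "'deliveryWeight' must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Probability density state of a population
#'
#' Probability mass per grid cell plus the mass currently held in
#' refractory queues. For a valid state the total over both is 1 up to
#' round-off at every simulation step.
#'
#' @slot mass numeric vector, one entry per grid cell (linear index order).
#' @slot refractory numeric matrix `queueLength x nThresholdCells` of
#'   queued mass (0 x 0 when the model has no threshold).
#' @slot time current simulation time in seconds.
#' @seealso [newDensityState()], [stepReset()], [applyMasterProcess()]
#' @export
setClass("DensityState",
  representation(
    mass = "numeric",
    refractory = "matrix",
    time = "numeric"
  )
)

setValidity("DensityState", function(object) {
  msg <- character(0)
  if (length(object@mass) && min(object@mass) < -1e-12)
    msg <- c(msg, "probability mass must be non-negative")
  if (length(object@refractory) && min(object@refractory) < -1e-12)
    msg <- c(msg, "refractory queue contents must be non-negative")
  if (length(msg)) msg else TRUE
})

#' A network of interacting populations
#'
#' Nodes are instances of algorithms (grid population density or constant
#' rate), wired by typed delayed connections. The object carries the full
#' runtime state (per-node density states and activities, per-connection
#' delay queues) so that [evolveNetworkStep()] is a pure function from one
#' network state to the next.
#'
#' @slot algorithms named list of algorithm definitions.
#' @slot nodes list of node specifications (name, algorithm, type).
#' @slot connections list of connection specifications.
#' @slot incoming list of external-input declarations (order defines the
#'   order of the per-step external input vector).
#' @slot outgoing list of output declarations (order defines the order of
#'   activities returned by [evolveNetworkStep()]).
#' @slot dt network time step, seconds.
#' @slot masterSteps Euler substeps per time step for the master equation.
#' @slot state internal runtime state list.
#' @slot step number of steps taken so far.
#' @seealso [validateNetwork()], [evolveNetworkStep()], [runSimulation()]
#' @export
setClass("PopulationNetwork",
  representation(
    algorithms = "list",
    nodes = "list",
    connections = "list",
    incoming = "list",
    outgoing = "list",
    dt = "numeric",
    masterSteps = "integer",
    state = "list",
    step = "integer"
  )
)

#' Parsed simulation configuration
#'
#' The in-memory form of a simulation XML document: algorithm definitions,
#' nodes, connections, external input/output declarations, the reporting
#' plan and the run parameters, after variable substitution.
#'
#' @slot weightType connection vocabulary: `"double"`,
#'   `"DelayedConnection"` or `"CustomConnectionParameters"`.
#' @slot algorithms named list of algorithm definitions.
#' @slot nodes,connections,incoming,outgoing network structure lists.
#' @slot reporting list with elements `rates`, `densities`, `display`.
#' @slot runParams list: `simulationName`, `tEnd`, `tStep`, `nameLog`,
#'   `masterSteps` (default 10 when the document omits it).
#' @slot variables named character vector of variable defaults (after
#'   override resolution).
#' @seealso [parseSimulationXML()], [writeSimulationXML()], [runSimulation()]
#' @export
setClass("SimulationConfig",
  representation(
    weightType = "character",
    algorithms = "list",
    nodes = "list",
    connections = "list",
    incoming = "list",
    outgoing = "list",
    reporting = "list",
    runParams = "list",
    variables = "character"
  )
)

## ---- show methods -------------------------------------------------------

#' @describeIn NeuronModel-class compact display.
#' @param object object to display.
#' @export
setMethod("show", "NeuronModel", function(object) {
  cat("NeuronModel \"", object@name, "\"\n", sep = "")
  cat("  timestep: ", object@timestep, " s  timescale: ", object@timescale,
      " s per model time unit\n", sep = "")
  if (is.finite(object@thresholdV)) {
    cat("  threshold: ", object@thresholdV, "  reset: ", object@resetV,
        "  reset shift (h): ", object@resetShiftH, "\n", sep = "")
    cat("  refractory period: ", object@refractoryPeriod, " s\n", sep = "")
  } else {
    cat("  no threshold-reset mechanic\n")
  }
  cat("  efficacy orientation: ", object@efficacyOrientation, "\n", sep = "")
  invisible(NULL)
})

#' @describeIn StateGrid-class compact display.
#' @param object object to display.
#' @export
setMethod("show", "StateGrid", function(object) {
  cat("StateGrid: ", object@nV, " x ", object@nH, " cells (",
      nCells(object), " total)\n", sep = "")
  cat("  v: [", object@vMin, ", ", object@vMax, "]  cell width ",
      cellWidth(object), "\n", sep = "")
  cat("  h: [", object@hMin, ", ", object@hMax, "]  cell height ",
      cellHeight(object), "\n", sep = "")
  invisible(NULL)
})

#' @describeIn TransitionMatrix-class compact display.
#' @param object object to display.
#' @export
setMethod("show", "TransitionMatrix", function(object) {
  cat("TransitionMatrix (", object@kind, ") on a ", object@nV, " x ",
      object@nH, " grid\n", sep = "")
  if (!is.na(object@dt))
    cat("  generating time step: ", object@dt, " s\n", sep = "")
  cat("  nonzero entries: ", length(object@matrix@x),
      " (", format(100 * length(object@matrix@x) /
                   prod(dim(object@matrix)), digits = 3),
      "% dense)\n", sep = "")
  invisible(NULL)
})

#' @describeIn DensityState-class compact display.
#' @param object object to display.
#' @export
setMethod("show", "DensityState", function(object) {
  cat("DensityState at t = ", object@time, " s\n", sep = "")
  cat("  in-grid mass: ", format(sum(object@mass), digits = 10),
      "  refractory mass: ", format(sum(object@refractory), digits = 10),
      "\n", sep = "")
  invisible(NULL)
})

#' @describeIn PopulationNetwork-class compact display.
#' @param object object to display.
#' @export
setMethod("show", "PopulationNetwork", function(object) {
  cat("PopulationNetwork: ", length(object@nodes), " nodes, ",
      length(object@connections), " connections\n", sep = "")
  cat("  dt = ", object@dt, " s, master substeps = ", object@masterSteps,
      ", steps taken = ", object@step, "\n", sep = "")
  for (nd in object@nodes)
    cat("  node ", nd$name, " [", nd$type, "] <- algorithm ", nd$algorithm,
        "\n", sep = "")
  invisible(NULL)
})

#' @describeIn SimulationConfig-class compact display.
#' @param object object to display.
#' @export
setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig \"", object@runParams$simulationName, "\"\n", sep = "")
  cat("  weight type: ", object@weightType, "\n", sep = "")
  cat("  ", length(object@algorithms), " algorithms, ",
      length(object@nodes), " nodes, ", length(object@connections),
      " connections\n", sep = "")
  cat("  t_end = ", object@runParams$tEnd, " s, t_step = ",
      object@runParams$tStep, " s, master_steps = ",
      object@runParams$masterSteps, "\n", sep = "")
  invisible(NULL)
})

## ---- simple accessors ---------------------------------------------------

#' @rdname cellWidth
#' @export
setMethod("cellWidth", "StateGrid", function(x) (x@vMax - x@vMin) / x@nV)

#' @rdname cellWidth
#' @export
setMethod("cellHeight", "StateGrid", function(x) (x@hMax - x@hMin) / x@nH)

#' @rdname cellWidth
#' @export
setMethod("nCells", "StateGrid", function(x) as.integer(x@nV) * as.integer(x@nH))

#' @rdname mass
#' @export
setMethod("mass", "DensityState", function(x) x@mass)

#' @rdname mass
#' @export
setMethod("totalMass", "DensityState",
          function(x) sum(x@mass) + sum(x@refractory))

#' @rdname mass
#' @export
setMethod("simTime", "DensityState", function(x) x@time)
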