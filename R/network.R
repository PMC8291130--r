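#' @include reset.R
NULL

#' Algorithm definitions for population nodes
#'
#' `gridAlgorithm` defines a population simulated with the grid population
#' density technique: a neuron model, its state grid, the pre-computed
#' deterministic transition matrix and the activity read-out. `rateAlgorithm`
#' defines a node emitting a constant activity (typically an external
#' Poisson input source).
#'
#' @param model a [NeuronModel-class].
#' @param grid a [StateGrid-class].
#' @param tmat a [TransitionMatrix-class] of kind `"deterministic"`
#'   generated for `grid` (resolution and dt are checked).
#' @param rateMethod `"rate"` (population firing rate, Hz) or `"avgv"`
#'   (mass-weighted average of the first state variable over in-grid
#'   mass).
#' @param startV,startH starting state: all probability mass is placed in
#'   the cell containing `(startV, startH)`. Defaults to
#'   `(model@resetV, 0)` clamped into the grid.
#' @param rate constant activity of a rate node, Hz.
#' @return an algorithm definition list for [validateNetwork()].
#' @export
gridAlgorithm <- function(model, grid, tmat, rateMethod = c("rate", "avgv"),
                          startV = NULL, startH = NULL) {
  rateMethod <- match.arg(rateMethod)
  stopifnot(methods::is(model, "NeuronModel"),
            methods::is(grid, "StateGrid"),
            methods::is(tmat, "TransitionMatrix"))
  if (tmat@nV != grid@nV || tmat@nH != grid@nH)
    stop("transition matrix resolution does not match the grid")
  if (!is.na(tmat@dt) && abs(tmat@dt - model@timestep) >
      1e-12 * model@timestep)
    stop(sprintf(
      "transition matrix was generated with dt = %g but the model timestep is %g",
      tmat@dt, model@timestep))
  if (is.null(startV))
    startV <- min(max(model@resetV, grid@vMin), grid@vMax)
  if (is.null(startH))
    startH <- min(max(0, grid@hMin), grid@hMax)
  list(type = "grid", model = model, grid = grid, tmat = tmat,
       rateMethod = rateMethod, startV = startV, startH = startH)
}

#' @rdname gridAlgorithm
#' @export
rateAlgorithm <- function(rate) {
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0)
    stop("'rate' must be a single non-negative number")
  list(type = "rate", rate = as.numeric(rate))
}

#' Effective Poisson input rate of a connection
#'
#' The number of incoming connections acts as a weight: each neuron in the
#' target population receives, on average, `numConnections` times the
#' source population's activity as its Poisson input rate.
#'
#' @param numConnections non-negative connection-count multiplier.
#' @param inActivity source activity in Hz.
#' @return effective rate in Hz.
#' @examples
#' effectiveInputRate(10, 10)  # 100 Hz
#' @export
effectiveInputRate <- function(numConnections, inActivity) {
  if (any(inActivity < 0))
    stop("rate-typed activity must be >= 0")
  numConnections * inActivity
}

## delay queue: slots m + 2 where m = floor(delay / dt); reading before
## the push interpolates the two oldest required samples, so delay 0 still
## implies a one-step transport lag (synchronous update).
.newDelayQueue <- function(delay, dt) {
  if (delay < 0) stop("connection delay must be >= 0")
  ratio <- delay / dt
  m <- as.integer(floor(ratio + 1e-12))
  alpha <- ratio - m
  if (alpha < 1e-12) alpha <- 0
  list(values = numeric(m + 2L), m = m, alpha = alpha)
}

.readDelayQueue <- function(q) {
  (1 - q$alpha) * q$values[q$m + 1L] + q$alpha * q$values[q$m + 2L]
}

.pushDelayQueue <- function(q, value) {
  q$values <- c(value, q$values[seq_len(length(q$values) - 1L)])
  q
}

#' Validate and instantiate a population network
#'
#' Checks the network structure (unique node names, existing connection
#' endpoints, efficacy signs compatible with the source node's type:
#' positive for `EXCITATORY`, negative for `INHIBITORY`, either for
#' `NEUTRAL`) and pre-builds one jump matrix per connection into a grid
#' node, using the target model's efficacy orientation. The returned
#' network carries its full runtime state; advance it with
#' [evolveNetworkStep()].
#'
#' @param algorithms named list of algorithm definitions
#'   ([gridAlgorithm()], [rateAlgorithm()]).
#' @param nodes list of node specs: `list(name =, algorithm =, type =)`
#'   with type one of `"EXCITATORY"`, `"INHIBITORY"`, `"NEUTRAL"`.
#' @param connections list of connection specs: `list(inNode =, outNode =,
#'   numConnections =, efficacy =, delay = 0)`.
#' @param incoming list of external-input declarations: `list(node =,
#'   efficacy =, numConnections = 1, delay = 0)`; their order defines the
#'   order of the external input vector passed to [evolveNetworkStep()].
#' @param outgoing list of output declarations `list(node =)`; their order
#'   defines the order of returned activities.
#' @param dt network time step in seconds.
#' @param masterSteps Euler substeps for the master equation (default 10).
#' @return a [PopulationNetwork-class], initialised at time 0.
#' @export
validateNetwork <- function(algorithms, nodes, connections = list(),
                            incoming = list(), outgoing = list(),
                            dt, masterSteps = 10L) {
  nodeNames <- vapply(nodes, function(n) n$name, character(1))
  if (anyDuplicated(nodeNames))
    stop("node names must be unique; duplicated: ",
         paste(unique(nodeNames[duplicated(nodeNames)]), collapse = ", "))
  types <- vapply(nodes, function(n) n$type, character(1))
  types[types == "EXCITATORY_DIRECT"] <- "EXCITATORY"
  types[types == "INHIBITORY_DIRECT"] <- "INHIBITORY"
  if (!all(types %in% c("EXCITATORY", "INHIBITORY", "NEUTRAL")))
    stop("node type must be EXCITATORY, INHIBITORY or NEUTRAL")
  for (k in seq_along(nodes)) {
    nodes[[k]]$type <- types[k]
    alg <- nodes[[k]]$algorithm
    if (!alg %in% names(algorithms))
      stop("node '", nodeNames[k], "' references unknown algorithm '",
           alg, "'")
  }
  names(nodes) <- nodeNames

  checkEndpoint <- function(nm, what) {
    if (!nm %in% nodeNames)
      stop(what, " references unknown node '", nm, "'")
  }
  checkSign <- function(type, efficacy, label) {
    if (type == "EXCITATORY" && efficacy < 0)
      stop("connection ", label,
           ": negative efficacy from an EXCITATORY node")
    if (type == "INHIBITORY" && efficacy > 0)
      stop("connection ", label,
           ": positive efficacy from an INHIBITORY node")
  }

  for (k in seq_along(connections)) {
    cn <- connections[[k]]
    checkEndpoint(cn$inNode, "connection")
    checkEndpoint(cn$outNode, "connection")
    if (is.null(cn$delay)) cn$delay <- 0
    if (cn$numConnections < 0)
      stop("numConnections must be >= 0")
    label <- paste0(cn$inNode, " -> ", cn$outNode)
    checkSign(nodes[[cn$inNode]]$type, cn$efficacy, label)
    tgtAlg <- algorithms[[nodes[[cn$outNode]]$algorithm]]
    cn$jump <- if (tgtAlg$type == "grid") {
      buildJumpMatrix(tgtAlg$grid, cn$efficacy,
                      tgtAlg$model@efficacyOrientation)
    } else NULL
    connections[[k]] <- cn
  }
  for (k in seq_along(incoming)) {
    ic <- incoming[[k]]
    checkEndpoint(ic$node, "incoming connection")
    if (is.null(ic$numConnections)) ic$numConnections <- 1
    if (is.null(ic$delay)) ic$delay <- 0
    tgtAlg <- algorithms[[nodes[[ic$node]]$algorithm]]
    ic$jump <- if (tgtAlg$type == "grid") {
      buildJumpMatrix(tgtAlg$grid, ic$efficacy,
                      tgtAlg$model@efficacyOrientation)
    } else NULL
    incoming[[k]] <- ic
  }
  for (og in outgoing) checkEndpoint(og$node, "outgoing connection")

  ## runtime state
  densities <- list()
  mappings <- list()
  activities <- stats::setNames(numeric(length(nodes)), nodeNames)
  for (nm in nodeNames) {
    alg <- algorithms[[nodes[[nm]]$algorithm]]
    if (alg$type == "grid") {
      mp <- buildResetMapping(alg$grid, alg$model, dt = dt)
      mappings[[nm]] <- mp
      densities[[nm]] <- newDensityState(
        alg$grid, start = c(alg$startV, alg$startH), mapping = mp)
      activities[nm] <- 0
    } else if (alg$type == "rate") {
      activities[nm] <- alg$rate
    } else stop("unknown algorithm type: ", alg$type)
  }
  queues <- lapply(connections, function(cn) .newDelayQueue(cn$delay, dt))
  inQueues <- lapply(incoming, function(ic) .newDelayQueue(ic$delay, dt))

  methods::new("PopulationNetwork",
    algorithms = algorithms, nodes = nodes, connections = connections,
    incoming = incoming, outgoing = outgoing,
    dt = as.numeric(dt), masterSteps = as.integer(masterSteps),
    state = list(densities = densities, mappings = mappings,
                 activities = activities, queues = queues,
                 inQueues = inQueues, fired = activities * 0,
                 conservationError = 0),
    step = 0L)
}

#' Advance a population network by one time step
#'
#' Synchronous update: every node reads last-step activities through the
#' connection delay queues, then all nodes advance. Per grid node the
#' within-step operator order is (1) deterministic transition matrix,
#' (2) threshold-reset redistribution with refractory queues,
#' (3) Poisson master process for all incident inputs combined, then the
#' activity read-out (fired mass / dt, or the average membrane potential
#' for `"avgv"` nodes, computed over in-grid mass only). Activities are
#' pushed into the delay queues afterwards, so a delay of 0 still implies
#' a one-step transport lag.
#'
#' @param network a [PopulationNetwork-class].
#' @param externalInputs numeric vector of external input rates (Hz), one
#'   per declared incoming connection, in declaration order.
#' @return the advanced network. The activities returned to the caller
#'   (in outgoing declaration order) are available via
#'   [outputActivities()]; per-node values via [nodeActivity()].
#' @export
evolveNetworkStep <- function(network, externalInputs = numeric(0)) {
  stopifnot(methods::is(network, "PopulationNetwork"))
  nIn <- length(network@incoming)
  if (length(externalInputs) != nIn)
    stop(sprintf("expected %d external input value(s), got %d",
                 nIn, length(externalInputs)))
  st <- network@state
  dt <- network@dt
  nodes <- network@nodes

  ## effective Poisson input per node, read through the delay queues
  perNode <- stats::setNames(vector("list", length(nodes)), names(nodes))
  for (k in seq_along(network@connections)) {
    cn <- network@connections[[k]]
    act <- .readDelayQueue(st$queues[[k]])
    lam <- effectiveInputRate(cn$numConnections, act)
    if (!is.null(cn$jump))
      perNode[[cn$outNode]] <- c(perNode[[cn$outNode]],
                                 list(list(rate = abs(lam),
                                           matrix = cn$jump)))
  }
  for (k in seq_along(network@incoming)) {
    ic <- network@incoming[[k]]
    lam <- if (ic$delay > 0) {
      effectiveInputRate(ic$numConnections,
                         .readDelayQueue(st$inQueues[[k]]))
    } else {
      effectiveInputRate(ic$numConnections, externalInputs[k])
    }
    if (!is.null(ic$jump))
      perNode[[ic$node]] <- c(perNode[[ic$node]],
                              list(list(rate = abs(lam),
                                        matrix = ic$jump)))
  }

  ## advance every node
  for (nm in names(nodes)) {
    alg <- network@algorithms[[nodes[[nm]]$algorithm]]
    if (alg$type != "grid") next
    ds <- st$densities[[nm]]
    mp <- st$mappings[[nm]]
    ## (1) deterministic flow
    ds@mass <- as.numeric(alg$tmat@matrix %*% ds@mass)
    ## (2) threshold-reset / refractory queues
    rr <- stepReset(ds, mp)
    ds <- rr$state
    ## (3) master process
    ds <- applyMasterProcess(ds, perNode[[nm]], dt,
                             masterSteps = network@masterSteps)
    st$fired[nm] <- rr$fired
    st$activities[nm] <- if (alg$rateMethod == "avgv") {
      inGrid <- sum(ds@mass)
      if (inGrid > 0) {
        sum(ds@mass * cellCenters(alg$grid)[, "v"]) / inGrid
      } else 0
    } else {
      firingRate(rr$fired, dt)
    }
    err <- abs(totalMass(ds) - 1)
    if (err > st$conservationError) st$conservationError <- err
    st$densities[[nm]] <- ds
  }

  ## push activities (and external samples) into the queues
  for (k in seq_along(network@connections)) {
    cn <- network@connections[[k]]
    st$queues[[k]] <- .pushDelayQueue(st$queues[[k]],
                                      st$activities[cn$inNode])
  }
  for (k in seq_along(network@incoming)) {
    if (network@incoming[[k]]$delay > 0)
      st$inQueues[[k]] <- .pushDelayQueue(st$inQueues[[k]],
                                          externalInputs[k])
  }

  network@state <- st
  network@step <- network@step + 1L
  network
}

#' Inspect network runtime state
#'
#' `outputActivities` returns the activities of the declared outgoing
#' nodes (in declaration order); `nodeActivity` a named node's current
#' activity; `nodeDensity` its [DensityState-class] (grid nodes only);
#' `conservationError` the worst absolute deviation of any node's total
#' probability mass (grid + refractory queues) from 1 seen so far.
#'
#' @param network a [PopulationNetwork-class].
#' @param name node name.
#' @export
outputActivities <- function(network) {
  vapply(network@outgoing,
         function(og) network@state$activities[[og$node]], numeric(1))
}

#' @rdname outputActivities
#' @export
nodeActivity <- function(network, name) {
  if (!name %in% names(network@nodes)) stop("unknown node: ", name)
  unname(network@state$activities[name])
}

#' @rdname outputActivities
#' @export
nodeDensity <- function(network, name) {
  if (!name %in% names(network@state$densities))
    stop("node '", name, "' is not a grid node")
  network@state$densities[[name]]
}

#' @rdname outputActivities
#' @export
conservationError <- function(network) {
  network@state$conservationError
}
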