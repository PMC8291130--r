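#' @include jump.R
NULL

#' Create a density state on a grid
#'
#' Initialises a [DensityState-class] with all probability mass
#' concentrated in a single cell (the cell containing `start`, or an
#' explicit `cell` index), with empty refractory queues sized for the
#' supplied reset mapping.
#'
#' @param grid a [StateGrid-class].
#' @param start numeric `c(v, h)` starting point; mass 1 is placed in the
#'   cell containing it.
#' @param cell alternatively, a linear cell index.
#' @param mapping optionally a [ResetMapping-class]; its queue geometry
#'   determines the refractory storage.
#' @param time initial time (seconds).
#' @return a [DensityState-class] with `totalMass(state) == 1`.
#' @export
newDensityState <- function(grid, start = NULL, cell = NULL,
                            mapping = NULL, time = 0) {
  m <- numeric(nCells(grid))
  if (is.null(cell)) {
    if (is.null(start))
      stop("supply either 'start' coordinates or a 'cell' index")
    cell <- cellOf(grid, start[1], start[2])
    if (is.na(cell))
      stop(sprintf("starting point (%g, %g) lies outside the grid",
                   start[1], start[2]))
  }
  cell <- as.integer(cell)
  if (cell < 1L || cell > nCells(grid)) stop("cell index out of range")
  m[cell] <- 1
  q <- if (is.null(mapping)) {
    matrix(numeric(0), nrow = 0, ncol = 0)
  } else {
    matrix(0, nrow = mapping@queueLength,
           ncol = length(mapping@thresholdCells))
  }
  methods::new("DensityState", mass = m, refractory = q,
               time = as.numeric(time))
}

#' Integrate the Poisson master equation over one time step
#'
#' Evolves the density under shot noise: each incoming connection `k`
#' delivers Poisson spike trains at rate \eqn{\lambda_k}, each spike
#' displacing neurons according to the jump matrix \eqn{M_k}. The change
#' in the density \eqn{\rho} obeys the master equation
#' \deqn{d\rho/dt = \sum_k \lambda_k (M_k - I)\,\rho,}
#' integrated here with `masterSteps` fixed forward-Euler substeps of
#' `dt / masterSteps`. All inputs are combined into a single generator per
#' step (their order is immaterial). Total mass is conserved exactly by
#' construction; if a substep drives any component negative beyond
#' round-off the integration has blown up and an error recommends raising
#' `masterSteps`. Negative components within `1e-12` are clamped to zero
#' and the mass renormalised.
#'
#' @param state a [DensityState-class].
#' @param inputs list of inputs, each `list(rate = <Hz>, matrix =
#'   <TransitionMatrix>)` (jump matrices from [buildJumpMatrix()]).
#' @param dt time step in seconds.
#' @param masterSteps number of Euler substeps (>= 1; default 10).
#' @return the evolved [DensityState-class] (time advanced by `dt`).
#' @examples
#' g <- buildGrid(c(0, 1, 0, 1), c(50, 1))
#' st <- newDensityState(g, cell = 10)
#' jm <- buildJumpMatrix(g, cellWidth(g), "v")  # jump of exactly one cell
#' out <- applyMasterProcess(st, list(list(rate = 1, matrix = jm)),
#'                           dt = 1, masterSteps = 1000)
#' # mass(out) ~ Poisson pmf with mean 1, offset from cell 10
#' @export
applyMasterProcess <- function(state, inputs, dt, masterSteps = 10L) {
  stopifnot(methods::is(state, "DensityState"))
  masterSteps <- as.integer(masterSteps)
  if (masterSteps < 1L) stop("'masterSteps' must be >= 1")
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be positive")
  rho <- state@mass
  if (!length(inputs)) {
    state@time <- state@time + dt
    return(state)
  }
  rates <- vapply(inputs, function(x) as.numeric(x$rate), numeric(1))
  if (any(rates < 0)) stop("input rates must be >= 0")
  mats <- lapply(inputs, function(x) {
    stopifnot(methods::is(x$matrix, "TransitionMatrix"))
    x$matrix@matrix
  })
  active <- which(rates > 0)
  if (!length(active)) {
    state@time <- state@time + dt
    return(state)
  }
  ## combined generator: sum_k rate_k * (M_k - I)
  Q <- rates[active[1]] * mats[[active[1]]]
  for (k in active[-1]) Q <- Q + rates[k] * mats[[k]]
  lamTot <- sum(rates[active])
  h <- dt / masterSteps
  tot0 <- sum(rho)
  for (s in seq_len(masterSteps)) {
    rho <- rho + h * (as.numeric(Q %*% rho) - lamTot * rho)
    mn <- min(rho)
    if (mn < -1e-12)
      stop(sprintf(
        "master-equation blow-up: mass component reached %.3g at substep %d; increase 'masterSteps' (currently %d) or reduce the time step",
        mn, s, masterSteps))
    if (mn < 0) {
      rho[rho < 0] <- 0
      sm <- sum(rho)
      if (sm > 0) rho <- rho * (tot0 / sm)
    }
  }
  state@mass <- rho
  state@time <- state@time + dt
  state
}
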