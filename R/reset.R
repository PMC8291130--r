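#' @include master.R
NULL

#' Build the threshold-to-reset cell mapping
#'
#' Identifies the threshold cells (all cells whose lower v-edge lies at or
#' above the lower edge of the column containing `thresholdV`) and maps
#' each to its reset cell: the cell in the column containing `resetV`, in
#' the row displaced by `round(resetShiftH / cellHeight)`. A model with
#' `thresholdV` at or beyond the grid's upper v-bound (or non-finite) has
#' no threshold cells, which disables the threshold-reset mechanic — mass
#' then never leaves the grid through the threshold.
#'
#' The refractory queue geometry (number of slots and the linear
#' interpolation weight of the final two places) is derived from the
#' model's refractory period and time step; see [ResetMapping-class].
#'
#' @param grid a [StateGrid-class].
#' @param model a [NeuronModel-class].
#' @param dt time step used for queue sizing (defaults to
#'   `model@timestep`).
#' @return a [ResetMapping-class].
#' @export
buildResetMapping <- function(grid, model, dt = model@timestep) {
  nV <- grid@nV; nH <- grid@nH
  cw <- cellWidth(grid); ch <- cellHeight(grid)
  thr <- integer(0); res <- integer(0)
  if (is.finite(model@thresholdV) && model@thresholdV < grid@vMax) {
    if (model@thresholdV < grid@vMin)
      stop("thresholdV lies below the grid's v range")
    iThr <- as.integer(floor((model@thresholdV - grid@vMin) / cw)) + 1L
    if (model@resetV < grid@vMin || model@resetV > grid@vMax)
      stop("resetV lies outside the grid's v range")
    iRes <- as.integer(floor((model@resetV - grid@vMin) / cw)) + 1L
    iRes <- min(iRes, nV)
    rowShift <- as.integer(round(model@resetShiftH / ch))
    jSrc <- rep(seq_len(nH), each = nV - iThr + 1L)
    iSrc <- rep(iThr:nV, times = nH)
    jDst <- jSrc + rowShift
    if (abs(rowShift) >= nH)
      stop(sprintf(
        "reset target row out of the grid for reset_shift_h = %g (row shift %d); enlarge the grid's h range",
        model@resetShiftH, rowShift))
    if (any(jDst < 1L) || any(jDst > nH)) {
      warning(sprintf(
        "reset_shift_h = %g pushes %d row(s) past the grid's h bounds; their reset targets are clamped at the edge rows",
        model@resetShiftH, sum(jDst < 1L | jDst > nH)))
      jDst <- pmin(pmax(jDst, 1L), nH)
    }
    thr <- cellIndex(grid, iSrc, jSrc)
    res <- cellIndex(grid, iRes, jDst)
  }
  r <- model@refractoryPeriod
  ratio <- r / dt
  qlen <- max(1L, as.integer(ceiling(ratio - 1e-12))) + 1L
  alpha <- ratio - floor(ratio + 1e-12)
  if (alpha < 1e-12) alpha <- 0
  w <- 1 - alpha
  agg <- if (length(thr)) {
    methods::as(Matrix::sparseMatrix(i = res, j = seq_along(res),
                                     x = rep(1, length(res)),
                                     dims = c(nCells(grid), length(res))),
                "CsparseMatrix")
  } else {
    methods::as(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                     x = numeric(0),
                                     dims = c(nCells(grid), 0L)),
                "CsparseMatrix")
  }
  methods::new("ResetMapping",
    thresholdCells = thr, resetCells = res,
    queueLength = qlen, deliveryWeight = w,
    refractoryPeriod = r, dt = dt, aggregator = agg)
}

#' Apply one step of threshold-reset and refractory-queue dynamics
#'
#' Per simulation step: (1) the probability mass currently in the
#' threshold cells is removed from the grid and pushed onto the head of
#' each cell's refractory queue — its total is the fired mass from which
#' the population firing rate derives; (2) every queue shifts one slot;
#' (3) the linear interpolation of the final two queue places determines
#' the mass delivered to the mapped reset cell this step
#' (`q[last] + w * q[last - 1]`), the remainder `(1 - w) * q[last - 1]`
#' moving to the final place for delivery next step. Global mass
#' (grid + queues) is conserved exactly.
#'
#' @param state a [DensityState-class] whose refractory storage matches
#'   `mapping`.
#' @param mapping a [ResetMapping-class].
#' @return `list(state = <DensityState>, fired = <probability mass>)`.
#' @seealso [buildResetMapping()], [firingRate()]
#' @export
stepReset <- function(state, mapping) {
  stopifnot(methods::is(state, "DensityState"),
            methods::is(mapping, "ResetMapping"))
  nThr <- length(mapping@thresholdCells)
  if (!nThr)
    return(list(state = state, fired = 0))
  Q <- state@refractory
  if (nrow(Q) != mapping@queueLength || ncol(Q) != nThr)
    stop("refractory storage does not match the mapping's queue geometry")
  L <- mapping@queueLength
  w <- mapping@deliveryWeight
  rho <- state@mass
  fired <- rho[mapping@thresholdCells]
  rho[mapping@thresholdCells] <- 0
  delivered <- Q[L, ] + w * Q[L - 1L, ]
  newQ <- Q
  newQ[L, ] <- (1 - w) * Q[L - 1L, ]
  if (L > 2L) newQ[2:(L - 1L), ] <- Q[1:(L - 2L), , drop = FALSE]
  newQ[1L, ] <- fired
  if (any(delivered != 0))
    rho <- rho + as.numeric(mapping@aggregator %*% delivered)
  state@mass <- rho
  state@refractory <- newQ
  list(state = state, fired = sum(fired))
}

#' Population firing rate from fired probability mass
#'
#' The total probability mass crossing threshold in one step, divided by
#' the time step, is the population's average firing rate in Hz.
#'
#' @param firedMass probability mass removed at threshold this step
#'   (in `[0, 1]`).
#' @param dt time step in seconds.
#' @return firing rate in Hz.
#' @examples
#' firingRate(0.01, 1e-3)  # 10 Hz
#' @export
firingRate <- function(firedMass, dt) {
  if (any(firedMass < 0) || any(firedMass > 1))
    stop("'firedMass' must lie in [0, 1]")
  if (dt <= 0) stop("'dt' must be positive")
  firedMass / dt
}
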