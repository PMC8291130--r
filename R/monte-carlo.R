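#' @include reporting.R
NULL

#' Direct Monte-Carlo simulation of a neuron ensemble
#'
#' Integrates `n` individual model neurons under Poisson spike input — the
#' finite-size ground truth that the population density technique
#' approximates. Per neuron and step: active neurons take one forward
#' Euler step of the vector field; a neuron crossing threshold records a
#' spike, is reset (first variable to `resetV`, second shifted by
#' `resetShiftH`) and is held — frozen and ignoring input — for the
#' refractory period; active neurons then receive `Poisson(rate * dt)`
#' spikes per input, each displacing the state by that input's efficacy.
#' The step structure (flow, threshold check, then jumps; refractory
#' re-entry after the same number of steps as the density solver's queue
#' delivery) mirrors the grid algorithm's operator order so that the two
#' methods are directly comparable.
#'
#' Event counts are drawn per step rather than via exponential waiting
#' times, which is valid for `rate * dt` well below 1; a warning is
#' emitted otherwise.
#'
#' @param model a [NeuronModel-class].
#' @param n number of neurons (>= 1).
#' @param inputs list of inputs, each `list(rate = <Hz>, efficacy =
#'   <jump>, orientation = "v"|"h")`. Defaults to the model's efficacy
#'   orientation when `orientation` is omitted.
#' @param tEnd simulated time in seconds.
#' @param dt time step in seconds.
#' @param seed RNG seed for reproducibility.
#' @param init initial state: numeric `c(v, h)` (all neurons start there)
#'   or an `n x 2` matrix.
#' @param binWidth spike-histogram bin width in seconds (default 1 ms).
#' @return a list: `spikes` (data.frame `time`, `count`, `rate` — per-bin
#'   spike counts and population rate in Hz), `states` (final `n x 2`
#'   state matrix), `refractory` (per-neuron steps remaining), `nSpikes`,
#'   and the call parameters `n`, `dt`, `binWidth`.
#' @examples
#' lif <- modelArchive("lif")
#' out <- simulateEnsemble(lif, n = 100, inputs = list(),
#'                         tEnd = 0.1, dt = 1e-3, seed = 1,
#'                         init = c(0, 0))
#' out$nSpikes  # 0: v = 0 is the equilibrium and there is no input
#' @export
simulateEnsemble <- function(model, n, inputs, tEnd, dt, seed = 1L,
                             init = NULL, binWidth = 1e-3) {
  stopifnot(methods::is(model, "NeuronModel"))
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be >= 1")
  if (dt <= 0) stop("'dt' must be positive")
  rates <- vapply(inputs, function(x) as.numeric(x$rate), numeric(1))
  if (any(rates < 0)) stop("input rates must be >= 0")
  if (any(rates * dt > 0.5))
    warning("rate * dt exceeds 0.5 for at least one input; per-step ",
            "Poisson counts become a coarse approximation — reduce dt")
  effs <- vapply(inputs, function(x) as.numeric(x$efficacy), numeric(1))
  orients <- vapply(inputs, function(x) {
    if (is.null(x$orientation)) model@efficacyOrientation else
      x$orientation
  }, character(1))

  if (is.null(init))
    init <- c(model@resetV, 0)
  if (is.matrix(init)) {
    if (nrow(init) != n || ncol(init) != 2)
      stop("'init' matrix must be n x 2")
    v <- init[, 1]; h <- init[, 2]
  } else {
    v <- rep(init[1], n); h <- rep(init[2], n)
  }

  set.seed(as.integer(seed))
  nSteps <- round(tEnd / dt)
  ## refractory re-entry lag matching the density solver's queue:
  ## delivery after max(1, ceiling(r / dt)) steps for integer multiples,
  ## stochastically rounded for fractional refractory periods.
  ratio <- model@refractoryPeriod / dt
  mFloor <- as.integer(floor(ratio + 1e-12))
  alpha <- ratio - mFloor
  if (alpha < 1e-12) alpha <- 0
  ## queue delivery lag: integer-multiple refractory periods deliver all
  ## mass max(1, r/dt) steps after the crossing; fractional ones split
  ## between lags mFloor + 1 and mFloor + 2 with weights (1-alpha, alpha)
  baseLag <- if (alpha == 0) max(1L, mFloor) else mFloor + 1L
  hasThreshold <- is.finite(model@thresholdV)

  refr <- integer(n)
  spikeStep <- integer(0)
  f <- model@vectorField
  hstep <- dt / model@timescale

  for (s in seq_len(nSteps)) {
    ## (0) refractory countdown; neurons reaching 0 now re-enter this
    ## step (they receive jumps but skip the flow, exactly as queued mass
    ## delivered at the reset stage joins the master process of the same
    ## iteration and only flows from the next one)
    held <- refr > 0L
    if (any(held)) refr[held] <- refr[held] - 1L
    reenter <- held & refr == 0L
    flowing <- refr == 0L & !reenter
    ## (1) deterministic flow
    if (any(flowing)) {
      d <- f(list(v[flowing], h[flowing]), 0)
      v[flowing] <- v[flowing] + hstep * d[[1]]
      h[flowing] <- h[flowing] + hstep * d[[2]]
      if (any(!is.finite(v)) || any(!is.finite(h))) {
        bad <- which(!is.finite(v) | !is.finite(h))[1]
        stop(sprintf("non-finite state for neuron %d at t = %g s",
                     bad, s * dt))
      }
    }
    ## (2) threshold-reset
    if (hasThreshold) {
      crossed <- flowing & v >= model@thresholdV
      nc <- sum(crossed)
      if (nc) {
        spikeStep <- c(spikeStep, rep.int(s, nc))
        v[crossed] <- model@resetV
        h[crossed] <- h[crossed] + model@resetShiftH
        lag <- rep.int(baseLag, nc)
        if (alpha > 0) {
          ## fractional refractory period: an alpha share re-enters one
          ## step later, matching the queue interpolation in expectation
          lag <- lag + as.integer(stats::runif(nc) < alpha)
        }
        refr[crossed] <- lag
      }
    }
    ## (3) Poisson jumps for all non-refractory neurons (including those
    ## re-entering this step)
    recv <- refr == 0L
    nAct <- sum(recv)
    if (nAct) {
      for (k in seq_along(inputs)) {
        if (rates[k] <= 0) next
        counts <- stats::rpois(nAct, rates[k] * dt)
        if (orients[k] == "v") {
          v[recv] <- v[recv] + counts * effs[k]
        } else {
          h[recv] <- h[recv] + counts * effs[k]
        }
      }
    }
  }

  nBins <- max(1L, as.integer(ceiling(tEnd / binWidth - 1e-9)))
  counts <- integer(nBins)
  if (length(spikeStep)) {
    bins <- pmin(nBins, as.integer(ceiling(spikeStep * dt / binWidth -
                                           1e-9)))
    tb <- tabulate(bins, nbins = nBins)
    counts <- tb
  }
  spikes <- data.frame(
    time = (seq_len(nBins) - 0.5) * binWidth,
    count = counts,
    rate = counts / (n * binWidth))
  list(spikes = spikes, states = cbind(v = v, h = h), refractory = refr,
       nSpikes = length(spikeStep), n = n, dt = dt, binWidth = binWidth)
}

#' Bin an ensemble onto a state grid
#'
#' Produces the empirical density: per-cell neuron counts divided by the
#' ensemble size. Neurons outside the grid are counted under the same
#' boundary policy as the density solver (pinned at the lower bounds,
#' wrapped from the upper bounds) so the histogram is directly comparable
#' with a [DensityState-class] mass vector and always sums to 1.
#'
#' @param states an `n x 2` matrix of neuron states (e.g.
#'   `simulateEnsemble(...)$states`).
#' @param grid a [StateGrid-class].
#' @return numeric vector of length `nCells(grid)` summing to 1.
#' @export
binToGrid <- function(states, grid) {
  if (!is.matrix(states) || ncol(states) != 2)
    stop("'states' must be an n x 2 matrix")
  cw <- cellWidth(grid); ch <- cellHeight(grid)
  i <- floor((states[, 1] - grid@vMin) / cw) + 1
  j <- floor((states[, 2] - grid@hMin) / ch) + 1
  bp <- .applyBoundaryPolicy(grid, as.integer(i), as.integer(j))
  cells <- cellIndex(grid, bp$i, bp$j)
  tabulate(cells, nbins = nCells(grid)) / nrow(states)
}
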