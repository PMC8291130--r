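#' @include AllClasses.R
NULL

#' Construct a point-neuron model
#'
#' Wraps a user-supplied vector field and threshold/reset parameters into a
#' [NeuronModel-class]. The vector field has the signature `f(y, t)` with
#' `y` a list of the two state variables (numeric vectors; the function
#' must vectorise over them) and `t` a placeholder argument that is
#' ignored. It returns `list(dV, dH)`, the derivatives in model time
#' units. For a 1D model, return `0 * y[[2]]` (or any inert expression)
#' for the second derivative.
#'
#' @param name identifier of the model.
#' @param vectorField function of `(y, t)`, see Details.
#' @param timestep default simulation time step in seconds.
#' @param timescale seconds per model time unit (1 for a model already
#'   written in seconds, `1e-3` for a millisecond-based model).
#' @param thresholdV spike threshold for the first variable; `Inf` for
#'   models without a threshold-reset mechanic.
#' @param resetV reset value of the first variable.
#' @param resetShiftH additive shift of the second variable on reset.
#' @param refractoryPeriod refractory hold time in seconds.
#' @param efficacyOrientation `"v"` or `"h"`: dimension in which an
#'   incoming spike displaces the state.
#' @param tolerance maximum allowed per-step displacement before a warning
#'   is emitted during transition-matrix generation (default `Inf`).
#' @return a validated [NeuronModel-class] object.
#' @examples
#' lif <- neuronModel("lif", function(y, t) list(-y[[1]], 0 * y[[2]]),
#'                    timestep = 1e-3, thresholdV = 1, resetV = 0)
#' eulerStep(lif, c(1, 0), dt = 0.1)   # c(0.9, 0)
#' @export
neuronModel <- function(name, vectorField, timestep,
                        timescale = 1,
                        thresholdV = Inf, resetV = -Inf,
                        resetShiftH = 0, refractoryPeriod = 0,
                        efficacyOrientation = "v",
                        tolerance = Inf) {
  methods::new("NeuronModel",
    name = as.character(name), vectorField = vectorField,
    timestep = as.numeric(timestep), timescale = as.numeric(timescale),
    thresholdV = as.numeric(thresholdV), resetV = as.numeric(resetV),
    resetShiftH = as.numeric(resetShiftH),
    refractoryPeriod = as.numeric(refractoryPeriod),
    efficacyOrientation = as.character(efficacyOrientation),
    tolerance = as.numeric(tolerance))
}

#' Advance points through the deterministic flow with forward Euler
#'
#' Applies `substeps` forward-Euler steps of `dt / substeps` each to one or
#' more state-space points: `y <- y + (dt / timescale / substeps) * f(y)`.
#' No threshold is applied here; this is the pure deterministic flow used
#' both to translate grid-cell vertices during transition-matrix
#' generation and to integrate individual neurons in the Monte-Carlo
#' reference simulator.
#'
#' @param model a [NeuronModel-class].
#' @param point numeric vector `c(v, h)` or an `n x 2` matrix of points.
#' @param dt time step in seconds (must be positive).
#' @param substeps number of Euler substeps (default 1; a single step is
#'   usually sufficient for the small time steps used on grids, but
#'   substepping is available for stiff fields).
#' @return object of the same shape as `point`, advanced by `dt`.
#' @examples
#' fhn <- modelArchive("fitzhugh_nagumo")
#' eulerStep(fhn, c(0, 0), dt = 0.01)  # c(0, 0.00056)
#' @export
eulerStep <- function(model, point, dt, substeps = 1L) {
  stopifnot(methods::is(model, "NeuronModel"))
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number")
  substeps <- as.integer(substeps)
  if (substeps < 1L) stop("'substeps' must be >= 1")
  vec <- is.matrix(point)
  if (vec) {
    v <- point[, 1]; h <- point[, 2]
  } else {
    if (length(point) != 2) stop("'point' must have two coordinates")
    v <- point[1]; h <- point[2]
  }
  hstep <- dt / model@timescale / substeps
  f <- model@vectorField
  for (k in seq_len(substeps)) {
    d <- f(list(v, h), 0)
    v <- v + hstep * d[[1]]
    h <- h + hstep * d[[2]]
  }
  if (any(!is.finite(v)) || any(!is.finite(h)))
    stop("vector field produced a non-finite state; ",
         "the model blows up at (or near) the supplied point(s)")
  if (vec) cbind(v, h, deparse.level = 0) else c(v, h)
}

#' Ready-made neuron models
#'
#' Returns one of the bundled point-neuron models with standard published
#' parameters as defaults:
#' \describe{
#'   \item{`lif`}{leaky integrate-and-fire, `F(v) = -v` (membrane time
#'     constant 1 in model units), threshold 1, reset 0. 1D: the second
#'     variable is inert.}
#'   \item{`qif`}{quadratic integrate-and-fire, `F(v) = v^2 + I` with the
#'     bifurcation parameter `I` (default -1: excitable regime with fixed
#'     points at \eqn{\pm 1}), threshold 10, reset -10. 1D.}
#'   \item{`cond2d`}{conductance-based leaky integrate-and-fire:
#'     \eqn{\tau dV/dt = -(V - E_l) - g_e V},
#'     \eqn{\tau_e dg_e/dt = -g_e}, with \eqn{E_l = -65} mV,
#'     \eqn{\tau = 20} ms, \eqn{\tau_e = 5} ms, threshold -55 mV, reset
#'     -65 mV. Spikes jump the conductance variable
#'     (`efficacyOrientation = "h"`).}
#'   \item{`fitzhugh_nagumo`}{FitzHugh-Nagumo:
#'     \eqn{dV/dt = V - V^3/3 - W}, \eqn{dW/dt = 0.08 (V + 0.7 - 0.8 W)};
#'     no threshold-reset mechanic (threshold `Inf`), arbitrary units.}
#'   \item{`izhikevich`}{Izhikevich simple model (regular-spiking
#'     parameters), millisecond time base:
#'     \eqn{dv/dt = 0.04 v^2 + 5 v + 140 - u + I},
#'     \eqn{du/dt = a (b v - u)} with `a = 0.02`, `b = 0.2`, `I = 0`,
#'     threshold 30 mV, reset -65 mV, reset shift `d = 8` in `u`.}
#'   \item{`adex`}{adaptive exponential integrate-and-fire (regular
#'     spiking), millisecond time base, V in mV, adaptation current w in
#'     pA: `C = 281` pF, `gL = 30` nS, `EL = -70.6` mV, `VT = -50.4` mV,
#'     `DeltaT = 2` mV, `tauW = 144` ms, `a = 4` nS; numerical cut-off
#'     threshold -40 mV, reset -70.6 mV, reset shift `b = 80.5` pA.}
#' }
#'
#' @param name one of `"lif"`, `"qif"`, `"cond2d"`, `"fitzhugh_nagumo"`,
#'   `"izhikevich"`, `"adex"`.
#' @param I constant input current for the `qif`, `izhikevich` and `adex`
#'   models (model units; default as listed above).
#' @return a [NeuronModel-class].
#' @examples
#' cond <- modelArchive("cond2d")
#' cond@thresholdV   # -55
#' @export
modelArchive <- function(name, I = NULL) {
  available <- c("lif", "qif", "cond2d", "fitzhugh_nagumo",
                 "izhikevich", "adex")
  if (missing(name) || !is.character(name) || length(name) != 1 ||
      !name %in% available)
    stop("unknown model", if (!missing(name)) paste0(" '", name, "'"),
         "; available models: ", paste(available, collapse = ", "))
  switch(name,
    lif = neuronModel("lif",
      function(y, t) list(-y[[1]], 0 * y[[2]]),
      timestep = 1e-3, timescale = 1,
      thresholdV = 1, resetV = 0, efficacyOrientation = "v"),
    qif = {
      Iq <- if (is.null(I)) -1 else I
      neuronModel("qif",
        function(y, t) list(y[[1]]^2 + Iq, 0 * y[[2]]),
        timestep = 1e-4, timescale = 1,
        thresholdV = 10, resetV = -10, efficacyOrientation = "v")
    },
    cond2d = neuronModel("cond2d",
      function(y, t) {
        tau <- 20e-3; tauE <- 5e-3; El <- -65
        list((-(y[[1]] - El) - y[[2]] * y[[1]]) / tau,
             -y[[2]] / tauE)
      },
      timestep = 1e-3, timescale = 1,
      thresholdV = -55, resetV = -65, efficacyOrientation = "h"),
    fitzhugh_nagumo = neuronModel("fitzhugh_nagumo",
      function(y, t)
        list(y[[1]] - y[[1]]^3 / 3 - y[[2]],
             0.08 * (y[[1]] + 0.7 - 0.8 * y[[2]])),
      timestep = 1e-2, timescale = 1,
      thresholdV = Inf, resetV = -Inf, efficacyOrientation = "v"),
    izhikevich = {
      Ii <- if (is.null(I)) 0 else I
      neuronModel("izhikevich",
        function(y, t)
          list(0.04 * y[[1]]^2 + 5 * y[[1]] + 140 - y[[2]] + Ii,
               0.02 * (0.2 * y[[1]] - y[[2]])),
        timestep = 1e-4, timescale = 1e-3,
        thresholdV = 30, resetV = -65, resetShiftH = 8,
        efficacyOrientation = "v")
    },
    adex = {
      Ia <- if (is.null(I)) 0 else I
      neuronModel("adex",
        function(y, t) {
          C <- 281; gL <- 30; EL <- -70.6; VT <- -50.4; DT <- 2
          tauW <- 144; a <- 4
          dv <- (-gL * (y[[1]] - EL) +
                 gL * DT * exp((y[[1]] - VT) / DT) - y[[2]] + Ia) / C
          dw <- (a * (y[[1]] - EL) - y[[2]]) / tauW
          list(dv, dw)
        },
        timestep = 1e-4, timescale = 1e-3,
        thresholdV = -40, resetV = -70.6, resetShiftH = 80.5,
        efficacyOrientation = "v")
    })
}
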