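---
title: "Methods: the grid population density technique in popdens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the grid population density technique in popdens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `popdens`, the
numerical choices behind it, and what its validation does and does not
establish. It states no empirical result beyond what the package's test
suite and `scripts/acceptance.R` themselves compute.

## The model

A population of identical point neurons with 1D or 2D state
$\vec v = (v, h)$ is represented by a probability density $\rho(\vec v,
t)$ instead of a cloud of individual states. Between spikes each neuron
follows the deterministic flow $d\vec v/dt = \vec F(\vec v)$; incoming
spikes arrive as Poisson processes and displace the state
instantaneously by the synaptic efficacy (a jump in $v$ for
delta-synapses, in $h$ for conductance-type models). The density then
obeys a transport equation with a shot-noise master-equation right-hand
side; threshold-reset models additionally remove flux at $v_{th}$ and
re-inject it at $v_{reset}$ after a refractory hold. The technique
assumes:

* neurons within a population are exchangeable (identical parameters,
  identical input statistics) — the density describes an effectively
  infinite population, so finite-size fluctuations are absent from its
  output by design;
* input spike trains are Poisson with slowly varying rates relative to
  the time step, and efficacies are state-independent constants per
  connection;
* vector fields are autonomous (`f(y, t)` receives `t` only as a
  placeholder).

1D models are embedded in 2D with an inert second variable; the
vertical axis of their grids carries no meaning.

## Discretisation and the three-step iteration

State space is truncated to a rectangle and split into $M \times N$
identical cells, each holding a uniform mass. Per time step, in this
fixed order:

1. **Deterministic transition matrix.** Each cell's four vertices are
   advanced by one forward-Euler step of the flow (a single step is
   adequate at the small steps used; `substeps` subdivides it for stiff
   fields). The transformed quadrilateral is fan-triangulated from its
   first vertex, and each triangle is recursively split at grid-line
   intersections until it lies within one (conceptually unbounded)
   lattice cell; absolute triangle areas are then summed per cell, which
   also handles non-convex or self-intersecting images. The fractions
   form one sparse stochastic row per source cell, computed
   independently of any processing order.
2. **Threshold-reset.** Threshold cells are all cells whose lower
   $v$-edge lies at or above the lower edge of the column containing
   $v_{th}$; their mass is removed each step (its total over the step,
   divided by $dt$, is the population rate) and pushed onto per-cell
   refractory queues. Each queue has $\max(1,\lceil r/dt\rceil) + 1$
   slots — the final slot is the "remainder" place: the mass delivered
   to the mapped reset cell per step is $q_{last} + w\,q_{last-1}$ with
   $w = 1 - (r/dt - \lfloor r/dt\rfloor)$, so an integer-multiple
   refractory period delivers each packet in one step and, e.g.,
   $r = 1.5\,dt$ splits packets 0.5/0.5 over two consecutive steps.
   Queued mass is outside state space: it receives no input and is
   excluded from average-membrane-potential read-outs, but counts
   toward conservation.
3. **Master equation.** All incident connections are combined into one
   generator $\sum_k \lambda_k (M_k - I)$ and integrated with
   `master_steps` fixed forward-Euler substeps (default 10). Each $M_k$
   is the two-cell split determined by the cell size and efficacy alone.

Delivered reset mass joins the master process of the same iteration and
re-enters the deterministic flow the following iteration; the bundled
Monte-Carlo simulator mirrors exactly this schedule so the two methods
are comparable step for step.

## Tunable parameters

| Parameter | Units | Default | Notes |
|---|---|---|---|
| grid bounds | model units | — | cover everywhere mass can reach; place $v_{th}$ and $v_{reset}$ on cell edges when possible (removes the half-cell threshold softening) |
| `resolution` | cells | — | 100×100–500×500 is typical; accuracy per dimension can be unbalanced |
| `timestep` | s | per model | also the network step; the matrix generator records it and refuses mismatched pairings |
| `timescale` | s per model time unit | 1 | e.g. `1e-3` for millisecond-based models; an Euler step advances by `(dt/timescale)·f(y)` |
| `master_steps` | — | 10 | raise to avoid blow-up for large `rate·dt`; negative mass beyond `1e-12` aborts with that advice |
| `refractoryPeriod` / `tau_refractive` | s | 0 | queue geometry derived as above |
| `num_connections`, `efficacy`, `delay` | —, model units, s | — | effective input rate = presynaptic activity × `num_connections` |

## Numerical choices

* **Boundary policy.** Mass transported below the lower grid bounds is
  pinned at the boundary cells; mass beyond the upper bounds wraps
  around to the lower bounds (both dimensions). Both paths log a
  warning because the resulting behaviour is wrong by construction —
  grids should be sized so they never trigger. The policy is applied at
  matrix-generation time so rows still sum to 1; rows are renormalised
  exactly after dropping fractions below `1e-12`.
* **Geometry tolerances.** Vertices within `1e-12` of a grid line (in
  units of the cell size) are snapped onto it; a line is only selected
  for splitting when it lies strictly inside a triangle's extent by a
  `1e-9`-cell margin, which terminates the recursion without slivers.
  Final triangles are binned by centroid; cells are half-open
  `[low, high)` with the grid's upper bound belonging to the last
  column/row, so binning is deterministic.
* **Reset mapping.** The reset column is the cell containing
  $v_{reset}$; `reset_shift_h` displaces the target row by
  `round(shift/cellHeight)`. Rows shifted past the grid edge are
  clamped at the edge row with a warning (a hard error would make any
  nonzero shift unusable, since threshold cells span every row); a
  shift of a full grid height or more is an error. Setting the
  threshold at the grid's upper $v$-bound (or `Inf`) disables the
  mechanic entirely.
* **Operator order.** Deterministic matrix → reset redistribution →
  master process, then the activity read-out. The update is synchronous
  across nodes: activities are read through per-connection delay
  queues, so even a zero delay implies a one-step transport lag.
* **Master integrator.** Fixed-step Euler with `master_steps` substeps,
  chosen for determinism and testability over an adaptive scheme; the
  test suite bounds its error directly against the analytic Poisson
  distribution (max per-cell deviation `< 1e-3` at `rate·t = 1` with
  1000 substeps). Components in `(-1e-12, 0)` are clamped to zero and
  the total renormalised; anything more negative is a hard error.
* **Units.** `timescale` is *seconds per model time unit* (the
  conversion applied to the time step), so vector fields are written in
  their natural units (e.g. mV/ms for the Izhikevich model with
  `timescale = 1e-3`).

## Validation: what it shows and what it does not

The Monte-Carlo reference (`simulateEnsemble`) integrates N individual
neurons with per-step Poisson event counts (valid for `rate·dt ≪ 1`;
warned beyond 0.5) and the same threshold, reset and refractory
schedule as the density solver. The acceptance checks compare, among
others, the stationary rate of a conductance-based population (800 Hz
drive, conductance jumps of 0.05, 2 ms refractory period) between the
grid solver on a threshold-aligned 210×100 grid at `dt = 0.1` ms and a
10,000-neuron ensemble over a 0.2 s stationary window — agreement
within 3 Monte-Carlo standard errors. This establishes that the
discretised transport + jump + reset machinery reproduces the ensemble
dynamics of the *same* idealised model; it does not validate the
Poisson-input idealisation itself, captures no finite-size or
correlation effects of real circuits, and inherits the usual grid
caveats: models whose firing rate hinges on sharp speed changes across
threshold (e.g. exponential integrate-and-fire) need much finer grids
than the defaults used here.

Problem sizes in the shipped tests were chosen to make each check sharp
at modest cost: 100×100–310×100 grids, 1000–8000 steps, ensembles of
2,000–10,000 neurons.

## Known limitations

* Only autonomous 1D/2D fields; no mesh-style characteristics-based
  discretisation, no state-dependent efficacies, no 3D grids.
* Time-varying inputs enter through the per-step external-input API
  (`evolveNetworkStep`), not through expression-valued rate functors;
  XML `RateFunctor` accepts constant expressions only.
* `.model` files store grid geometry and scalar parameters; the vector
  field itself is code and must be supplied when a configuration is
  instantiated (`buildNetworkFromConfig(models = ...)`).
* The upper-bound wrap-around is applied in both dimensions; whether
  that is preferable to pinning is untestable from within the method
  (either is wrong when reached) — grids should simply be large enough.
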