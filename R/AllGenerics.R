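#' Cell width of a state-space grid
#'
#' Accessors for the geometry of a [StateGrid-class]: the width of a cell in
#' the first (v) dimension, its height in the second (h) dimension, and the
#' total number of cells.
#'
#' @param x a `StateGrid` object.
#' @return `cellWidth` and `cellHeight` return a single numeric value;
#'   `nCells` returns an integer.
#' @examples
#' g <- buildGrid(c(-72, -54, -1, 1), c(100, 100))
#' cellWidth(g)   # 0.18
#' nCells(g)      # 10000
#' @export
setGeneric("cellWidth", function(x) standardGeneric("cellWidth"))

#' @rdname cellWidth
#' @export
setGeneric("cellHeight", function(x) standardGeneric("cellHeight"))

#' @rdname cellWidth
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' Probability mass of a density state
#'
#' `mass` returns the per-cell probability mass vector of a
#' [DensityState-class] (linear cell order, see [cellIndex]). The mass held
#' in refractory queues is not part of this vector; `totalMass` returns the
#' conserved total including queued refractory mass.
#'
#' @param x a `DensityState` object.
#' @return `mass`: numeric vector of length `nCells(grid)`; `totalMass`:
#'   a single numeric value (1 up to round-off for a valid state).
#' @export
setGeneric("mass", function(x) standardGeneric("mass"))

#' @rdname mass
#' @export
setGeneric("totalMass", function(x) standardGeneric("totalMass"))

#' @rdname mass
#' @export
setGeneric("simTime", function(x) standardGeneric("simTime"))
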