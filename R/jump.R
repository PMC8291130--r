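#' @include transition.R
NULL

#' Build the single-spike jump transition matrix
#'
#' A single incoming spike displaces every neuron's state by the synaptic
#' efficacy `h` along the jump orientation. Because all grid cells are
#' congruent, the resulting transition is identical for every cell and
#' involves at most two target cells: with cell size `s` in the jump
#' direction, the integer offset is `k = sign(h) * floor(|h| / s)` and the
#' fractional part `f = |h|/s - floor(|h|/s)` splits the mass `(1 - f)` to
#' the offset-`k` cell and `f` to the offset-`(k + sign(h))` cell. A zero
#' efficacy yields the identity. Shifts beyond the grid follow the
#' boundary policy (pinned below, wrapped above).
#'
#' @param grid a [StateGrid-class].
#' @param efficacy signed jump size, in units of the first variable
#'   (`orientation = "v"`) or the second (`orientation = "h"`).
#' @param orientation `"v"` or `"h"`.
#' @return a [TransitionMatrix-class] of kind `"jump"`.
#' @examples
#' g <- buildGrid(c(0, 1, 0, 1), c(10, 1))
#' jm <- buildJumpMatrix(g, efficacy = 0.05, orientation = "v")
#' # half a cell width: 0.5/0.5 split between offsets 0 and +1
#' Matrix::colSums(jm@matrix)  # all 1
#' @export
buildJumpMatrix <- function(grid, efficacy, orientation = c("v", "h")) {
  orientation <- match.arg(orientation)
  if (!is.numeric(efficacy) || length(efficacy) != 1 ||
      !is.finite(efficacy))
    stop("'efficacy' must be a single finite number")
  nV <- grid@nV; nH <- grid@nH; n <- nCells(grid)
  s <- if (orientation == "v") cellWidth(grid) else cellHeight(grid)
  sg <- sign(efficacy)
  f <- abs(efficacy) / s - floor(abs(efficacy) / s)
  k <- as.integer(sg * floor(abs(efficacy) / s))

  ij <- cellColRow(grid, seq_len(n))
  shift <- function(off) {
    if (orientation == "v") {
      bp <- .applyBoundaryPolicy(grid, ij[, "i"] + off, ij[, "j"])
    } else {
      bp <- .applyBoundaryPolicy(grid, ij[, "i"], ij[, "j"] + off)
    }
    cellIndex(grid, bp$i, bp$j)
  }

  if (efficacy == 0 || f == 0) {
    tgt <- shift(k)
    m <- Matrix::sparseMatrix(i = tgt, j = seq_len(n), x = rep(1, n),
                              dims = c(n, n))
  } else {
    t1 <- shift(k)
    t2 <- shift(k + as.integer(sg))
    m <- Matrix::sparseMatrix(
      i = c(t1, t2), j = c(seq_len(n), seq_len(n)),
      x = c(rep(1 - f, n), rep(f, n)), dims = c(n, n))
  }
  methods::new("TransitionMatrix", matrix = methods::as(m, "CsparseMatrix"),
               dt = NA_real_, kind = "jump", nV = nV, nH = nH)
}
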