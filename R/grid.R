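#' @include AllClasses.R
NULL

#' Build a rectangular state-space grid
#'
#' Discretises the rectangle `[vMin, vMax] x [hMin, hMax]` into
#' `nV * nH` identical axis-aligned cells. See [StateGrid-class] for the
#' indexing convention (half-open cells; linear index
#' `(j - 1) * nV + i`).
#'
#' @param bounds numeric vector `c(vMin, vMax, hMin, hMax)`.
#' @param resolution integer vector `c(nV, nH)` of column and row counts.
#' @return a [StateGrid-class].
#' @examples
#' g <- buildGrid(c(-72, -54, -1, 1), c(100, 100))
#' nCells(g)      # 10000
#' cellWidth(g)   # 0.18
#' @export
buildGrid <- function(bounds, resolution) {
  if (length(bounds) != 4 || !is.numeric(bounds) || any(!is.finite(bounds)))
    stop("'bounds' must be four finite numbers c(vMin, vMax, hMin, hMax)")
  if (length(resolution) != 2 || any(resolution < 1) ||
      any(resolution != round(resolution)))
    stop("'resolution' must be two positive integers c(nV, nH)")
  if (bounds[1] >= bounds[2] || bounds[3] >= bounds[4])
    stop("inverted bounds: need vMin < vMax and hMin < hMax")
  methods::new("StateGrid",
    vMin = bounds[1], vMax = bounds[2],
    hMin = bounds[3], hMax = bounds[4],
    nV = as.integer(resolution[1]), nH = as.integer(resolution[2]))
}

#' Cell indexing on a state grid
#'
#' `cellIndex` converts column/row pairs `(i, j)` (1-based) to linear cell
#' indices; `cellColRow` is the inverse; `cellOf` bins state-space points
#' into cells (half-open convention, points exactly on the upper bound
#' belong to the last column/row; points outside the grid give `NA`).
#' All are vectorised.
#'
#' @param grid a [StateGrid-class].
#' @param i,j column and row indices (1-based).
#' @param cell linear cell indices.
#' @param v,h point coordinates.
#' @return `cellIndex`/`cellOf`: integer linear indices; `cellColRow`: a
#'   two-column integer matrix with columns `i`, `j`.
#' @examples
#' g <- buildGrid(c(0, 1, 0, 1), c(10, 10))
#' cellIndex(g, 1, 2)          # 11
#' cellOf(g, 0.05, 0.15)       # 11
#' @export
cellIndex <- function(grid, i, j) {
  as.integer((j - 1L) * grid@nV + i)
}

#' @rdname cellIndex
#' @export
cellColRow <- function(grid, cell) {
  cell <- as.integer(cell)
  i <- ((cell - 1L) %% grid@nV) + 1L
  j <- ((cell - 1L) %/% grid@nV) + 1L
  cbind(i = i, j = j)
}

#' @rdname cellIndex
#' @export
cellOf <- function(grid, v, h) {
  cw <- cellWidth(grid); ch <- cellHeight(grid)
  i <- floor((v - grid@vMin) / cw) + 1
  j <- floor((h - grid@hMin) / ch) + 1
  i[v == grid@vMax] <- grid@nV
  j[h == grid@hMax] <- grid@nH
  bad <- i < 1 | i > grid@nV | j < 1 | j > grid@nH
  out <- cellIndex(grid, i, j)
  out[bad] <- NA_integer_
  out
}

#' Geometry of individual cells
#'
#' `cellVertices` returns the four corners of a cell in counter-clockwise
#' order starting from the lower-left corner; `cellCenters` returns the
#' center coordinates of all cells (rows in linear index order).
#'
#' @param grid a [StateGrid-class].
#' @param cell a single linear cell index.
#' @return `cellVertices`: a `4 x 2` numeric matrix; `cellCenters`: an
#'   `nCells x 2` matrix with columns `v`, `h`.
#' @export
cellVertices <- function(grid, cell) {
  ij <- cellColRow(grid, cell)
  cw <- cellWidth(grid); ch <- cellHeight(grid)
  x0 <- grid@vMin + (ij[1, "i"] - 1L) * cw
  y0 <- grid@hMin + (ij[1, "j"] - 1L) * ch
  matrix(c(x0,      y0,
           x0 + cw, y0,
           x0 + cw, y0 + ch,
           x0,      y0 + ch), ncol = 2, byrow = TRUE)
}

#' @rdname cellVertices
#' @export
cellCenters <- function(grid) {
  cw <- cellWidth(grid); ch <- cellHeight(grid)
  v <- grid@vMin + (seq_len(grid@nV) - 0.5) * cw
  h <- grid@hMin + (seq_len(grid@nH) - 0.5) * ch
  cbind(v = rep(v, times = grid@nH),
        h = rep(h, each = grid@nV))
}

## Map raw (possibly out-of-grid) column/row indices to in-grid indices
## under the boundary policy: below the lower bounds mass is pinned at the
## boundary cell, above the upper bounds it wraps around to the lower
## bounds (modular index). Both produce incorrect simulation behaviour by
## construction, so callers count and warn. Returns list(i, j, nPinned,
## nWrapped).
.applyBoundaryPolicy <- function(grid, i, j) {
  nPin <- sum(i < 1L) + sum(j < 1L)
  nWrap <- sum(i > grid@nV) + sum(j > grid@nH)
  i[i < 1L] <- 1L
  j[j < 1L] <- 1L
  i <- ((i - 1L) %% grid@nV) + 1L
  j <- ((j - 1L) %% grid@nH) + 1L
  list(i = i, j = j, nPinned = nPin, nWrapped = nWrap)
}
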