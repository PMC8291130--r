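#' @include grid.R neuron-models.R
NULL

## ---- internal geometry helpers ------------------------------------------

## Signed area of a triangle given as c(x1,y1,x2,y2,x3,y3).
.triArea <- function(t) {
  0.5 * ((t[3] - t[1]) * (t[6] - t[2]) - (t[5] - t[1]) * (t[4] - t[2]))
}

## Snap coordinates within `tol` of a grid line to that line exactly.
## Tie-breaking for the recursion: a vertex sitting (numerically) on a
## line must not generate a degenerate split.
.snapToLines <- function(x, origin, spacing, tol) {
  k <- round((x - origin) / spacing)
  g <- origin + k * spacing
  ifelse(abs(x - g) < tol, g, x)
}

## Clip a convex polygon (vectors px, py) against the half-plane
## coord <= c (side = -1) or coord >= c (side = +1) on axis 1 (x) or 2 (y).
## Intersection points are placed exactly on the line.
.clipPoly <- function(px, py, axis, cval, side) {
  n <- length(px)
  outx <- numeric(n + 4L); outy <- numeric(n + 4L); m <- 0L
  cur <- if (axis == 1L) px else py
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    a <- cur[k]; b <- cur[k2]
    ain <- if (side < 0L) a <= cval else a >= cval
    bin <- if (side < 0L) b <= cval else b >= cval
    if (ain) {
      m <- m + 1L; outx[m] <- px[k]; outy[m] <- py[k]
    }
    if (xor(ain, bin) && a != b) {
      tt <- (cval - a) / (b - a)
      ix <- px[k] + tt * (px[k2] - px[k])
      iy <- py[k] + tt * (py[k2] - py[k])
      if (axis == 1L) ix <- cval else iy <- cval
      m <- m + 1L; outx[m] <- ix; outy[m] <- iy
    }
  }
  list(x = outx[seq_len(m)], y = outy[seq_len(m)])
}

## Fan-triangulate a polygon into triangles c(x1,y1,...,x3,y3); drops
## polygons with fewer than 3 vertices.
.fanTriangles <- function(px, py) {
  n <- length(px)
  if (n < 3L) return(list())
  out <- vector("list", n - 2L)
  for (k in 2:(n - 1L))
    out[[k - 1L]] <- c(px[1], py[1], px[k], py[k], px[k + 1L], py[k + 1L])
  out
}

## Recursive triangulation of a transformed quadrilateral against the
## (conceptually unbounded) lattice of grid lines: the quad is split into
## two fan triangles, each triangle is recursively subdivided at
## intersections with grid lines until it lies within a single lattice
## cell, and absolute triangle areas are summed per cell. Non-convex /
## self-intersecting quads are handled by taking absolute areas per
## triangle. Returns list(i, j, area, total) with *raw* (possibly
## out-of-grid) column/row indices; the boundary policy is applied by the
## caller.
.triangulateOverlap <- function(quad, grid) {
  cw <- cellWidth(grid); ch <- cellHeight(grid)
  snapX <- 1e-12 * cw; snapY <- 1e-12 * ch
  strictX <- 1e-9 * cw; strictY <- 1e-9 * ch
  x0 <- grid@vMin; y0 <- grid@hMin

  qx <- .snapToLines(quad[, 1], x0, cw, snapX)
  qy <- .snapToLines(quad[, 2], y0, ch, snapY)

  stack <- list(
    c(qx[1], qy[1], qx[2], qy[2], qx[3], qy[3]),
    c(qx[1], qy[1], qx[3], qy[3], qx[4], qy[4])
  )
  total <- abs(.triArea(stack[[1]])) + abs(.triArea(stack[[2]]))
  if (total <= 0)
    return(list(i = integer(0), j = integer(0), area = numeric(0),
                total = 0))
  areaFloor <- 1e-14 * total

  resI <- integer(64L); resJ <- integer(64L); resA <- numeric(64L)
  nres <- 0L
  guard <- 0L

  while (length(stack)) {
    guard <- guard + 1L
    if (guard > 2e5L)
      stop("triangulation failed to terminate; degenerate geometry?")
    tri <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL

    a <- abs(.triArea(tri))
    if (a < areaFloor) next

    xs <- tri[c(1, 3, 5)]; ys <- tri[c(2, 4, 6)]

    ## first vertical grid line strictly inside the triangle's x-range
    minx <- min(xs); maxx <- max(xs)
    kx <- floor((minx + strictX - x0) / cw) + 1
    lx <- x0 + kx * cw
    if (lx < maxx - strictX) {
      left <- .clipPoly(xs, ys, 1L, lx, -1L)
      right <- .clipPoly(xs, ys, 1L, lx, +1L)
      stack <- c(stack, .fanTriangles(left$x, left$y),
                 .fanTriangles(right$x, right$y))
      next
    }

    ## then horizontal grid lines
    miny <- min(ys); maxy <- max(ys)
    ky <- floor((miny + strictY - y0) / ch) + 1
    ly <- y0 + ky * ch
    if (ly < maxy - strictY) {
      lo <- .clipPoly(xs, ys, 2L, ly, -1L)
      hi <- .clipPoly(xs, ys, 2L, ly, +1L)
      stack <- c(stack, .fanTriangles(lo$x, lo$y),
                 .fanTriangles(hi$x, hi$y))
      next
    }

    ## triangle lies within a single lattice cell: assign by centroid
    cx <- (xs[1] + xs[2] + xs[3]) / 3
    cy <- (ys[1] + ys[2] + ys[3]) / 3
    ci <- as.integer(floor((cx - x0) / cw)) + 1L
    cj <- as.integer(floor((cy - y0) / ch)) + 1L
    nres <- nres + 1L
    if (nres > length(resI)) {
      length(resI) <- 2L * length(resI)
      length(resJ) <- 2L * length(resJ)
      length(resA) <- 2L * length(resA)
    }
    resI[nres] <- ci; resJ[nres] <- cj; resA[nres] <- a
  }

  list(i = resI[seq_len(nres)], j = resJ[seq_len(nres)],
       area = resA[seq_len(nres)], total = total)
}

## ---- exported operations -------------------------------------------------

#' Translate a grid cell through one time step of the neuron dynamics
#'
#' Applies one forward-Euler step of the model's deterministic flow to the
#' four vertices of a grid cell. The returned quadrilateral is in general
#' no longer rectangular and may be non-convex; [overlapFractions()]
#' measures its area overlap with the untransformed grid.
#'
#' @param model a [NeuronModel-class].
#' @param grid a [StateGrid-class].
#' @param cell linear index of the cell to transform.
#' @param dt time step (defaults to `model@timestep`).
#' @param substeps Euler substeps (see [eulerStep()]).
#' @return a `4 x 2` matrix of translated vertices (same vertex order as
#'   [cellVertices()]).
#' @export
transformCell <- function(model, grid, cell, dt = model@timestep,
                          substeps = 1L) {
  if (cell < 1L || cell > nCells(grid))
    stop("cell index out of range")
  verts <- cellVertices(grid, cell)
  out <- tryCatch(eulerStep(model, verts, dt, substeps),
    error = function(e) {
      ij <- cellColRow(grid, cell)
      stop(sprintf(
        "model blow-up transforming cell %d (column %d, row %d, v in [%g, %g], h in [%g, %g]): %s",
        cell, ij[1, "i"], ij[1, "j"], verts[1, 1], verts[2, 1],
        verts[1, 2], verts[4, 2], conditionMessage(e)), call. = FALSE)
    })
  out
}

#' Area overlap of a transformed cell with the grid
#'
#' Implements the geometric overlap computation at the heart of the grid
#' population density technique: the quadrilateral is split into
#' triangles, each triangle is recursively subdivided at its intersections
#' with the grid lines until it lies within a single cell, and the
#' absolute triangle areas are summed per cell. Fractions are overlap
#' areas divided by the quadrilateral's total area. Mass falling outside
#' the grid is reassigned under the boundary policy (pinned at the lower
#' bounds, wrapped around from the upper bounds), so the returned
#' fractions always sum to 1.
#'
#' @param quad a `4 x 2` matrix of quadrilateral vertices in order (as
#'   returned by [transformCell()]).
#' @param grid a [StateGrid-class].
#' @param warnBoundary emit a warning when the boundary policy reassigned
#'   any mass (default `TRUE`).
#' @return a data.frame with columns `cell` (linear index) and `fraction`,
#'   sorted by cell.
#' @examples
#' g <- buildGrid(c(0, 1, 0, 1), c(4, 4))
#' q <- cellVertices(g, 1)
#' overlapFractions(q, g)                   # cell 1, fraction 1
#' q2 <- sweep(q, 2, c(cellWidth(g) / 2, 0), "+")
#' overlapFractions(q2, g)                  # cells 1 and 2, 0.5 each
#' @export
overlapFractions <- function(quad, grid, warnBoundary = TRUE) {
  if (!is.matrix(quad) || nrow(quad) != 4 || ncol(quad) != 2)
    stop("'quad' must be a 4 x 2 matrix of vertices")
  tri <- .triangulateOverlap(quad, grid)
  if (tri$total <= 0)
    stop("degenerate quadrilateral: (near-)zero area")
  bp <- .applyBoundaryPolicy(grid, tri$i, tri$j)
  if (warnBoundary && (bp$nPinned || bp$nWrapped))
    warning(sprintf(
      "mass transported outside the grid: %d piece(s) pinned at the lower bounds, %d wrapped from the upper bounds; results there are incorrect",
      bp$nPinned, bp$nWrapped))
  cells <- cellIndex(grid, bp$i, bp$j)
  agg <- rowsum(tri$area, cells)
  frac <- as.numeric(agg) / tri$total
  data.frame(cell = as.integer(rownames(agg)), fraction = frac)
}

#' Pre-compute the deterministic-dynamics transition matrix
#'
#' Builds the sparse stochastic matrix describing how probability mass is
#' transported between grid cells by one noise-free time step of the
#' neuron model: every cell is translated through the flow
#' ([transformCell()]) and its exact area overlaps with the untransformed
#' grid are measured ([overlapFractions()]). The result is independent of
#' the order in which source cells are processed. Mass leaving the grid is
#' reassigned under the boundary policy (pinned below, wrapped above) and
#' a single summary warning is emitted, since such transport produces
#' incorrect behaviour. Fractions below `1e-12` are dropped and each row
#' renormalised, so every source cell's proportions sum to 1 exactly.
#'
#' @param model a [NeuronModel-class].
#' @param grid a [StateGrid-class].
#' @param dt generating time step (defaults to `model@timestep`).
#' @param substeps Euler substeps per vertex translation (default 1).
#' @return a [TransitionMatrix-class] of kind `"deterministic"`.
#' @export
generateDeterministicMatrix <- function(model, grid, dt = model@timestep,
                                        substeps = 1L) {
  nV <- grid@nV; nH <- grid@nH; n <- nCells(grid)
  cw <- cellWidth(grid); ch <- cellHeight(grid)

  ## translate every grid vertex once, vectorised over the whole lattice
  vx <- grid@vMin + (0:nV) * cw
  vy <- grid@hMin + (0:nH) * ch
  px <- rep(vx, times = nH + 1L)
  py <- rep(vy, each = nV + 1L)
  moved <- eulerStep(model, cbind(px, py), dt, substeps)
  if (any(!is.finite(moved))) {
    bad <- which(!is.finite(moved[, 1]) | !is.finite(moved[, 2]))[1]
    stop(sprintf("model blow-up at grid vertex (v = %g, h = %g)",
                 px[bad], py[bad]))
  }
  disp <- sqrt((moved[, 1] - px)^2 + (moved[, 2] - py)^2)
  if (is.finite(model@tolerance) && max(disp) > model@tolerance)
    warning(sprintf(
      "maximum per-step displacement %.4g exceeds the model tolerance %.4g; consider a smaller time step",
      max(disp), model@tolerance))

  vert <- function(i, j) (j * (nV + 1L)) + i + 1L  # 0-based i in 0..nV

  srcAll <- vector("list", n)
  tgtAll <- vector("list", n)
  prpAll <- vector("list", n)
  nPinned <- 0L; nWrapped <- 0L

  for (j in seq_len(nH) - 1L) {
    base <- vert(0:(nV - 1L), j)
    for (ii in seq_len(nV)) {
      i <- ii - 1L
      idx <- c(vert(i, j), vert(i + 1L, j), vert(i + 1L, j + 1L),
               vert(i, j + 1L))
      quad <- moved[idx, , drop = FALSE]
      tri <- .triangulateOverlap(quad, grid)
      if (tri$total <= 0) {
        stop(sprintf(
          "degenerate transformed cell %d (column %d, row %d): zero area after translation",
          cellIndex(grid, ii, j + 1L), ii, j + 1L))
      }
      bp <- .applyBoundaryPolicy(grid, tri$i, tri$j)
      nPinned <- nPinned + bp$nPinned
      nWrapped <- nWrapped + bp$nWrapped
      cells <- (bp$j - 1L) * nV + bp$i
      agg <- rowsum(tri$area, cells)
      frac <- as.numeric(agg) / tri$total
      tgt <- as.integer(rownames(agg))
      keep <- frac >= 1e-12
      frac <- frac[keep]; tgt <- tgt[keep]
      frac <- frac / sum(frac)
      src <- cellIndex(grid, ii, j + 1L)
      srcAll[[src]] <- rep.int(src, length(tgt))
      tgtAll[[src]] <- tgt
      prpAll[[src]] <- frac
    }
  }

  if (nPinned || nWrapped)
    warning(sprintf(
      "boundary policy applied during matrix generation: %d piece(s) pinned at the lower bounds, %d wrapped from the upper bounds; mass reaching the grid edges will behave incorrectly",
      nPinned, nWrapped))

  m <- Matrix::sparseMatrix(
    i = unlist(tgtAll), j = unlist(srcAll), x = unlist(prpAll),
    dims = c(n, n))
  methods::new("TransitionMatrix", matrix = methods::as(m, "CsparseMatrix"),
               dt = dt, kind = "deterministic", nV = nV, nH = nH)
}
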