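#' @include sim-config.R
NULL

#' Write a rate trace record
#'
#' One line per recorded interval: time and activity, whitespace
#' separated. If the node's activity read-out is the average membrane
#' potential, that is what is recorded.
#'
#' @param times numeric vector of record times (seconds).
#' @param activities numeric vector of activities, parallel to `times`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRateRecord <- function(times, activities, path) {
  if (length(times) != length(activities))
    stop("'times' and 'activities' must have equal length")
  writeLines(paste(formatC(times, digits = 12, format = "g"),
                   formatC(activities, digits = 12, format = "g")),
             path)
  invisible(path)
}

#' @rdname writeRateRecord
#' @export
readRateRecord <- function(path) {
  if (!file.exists(path)) stop("rate file not found: ", path)
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  if (!length(lines))
    return(data.frame(time = numeric(0), activity = numeric(0)))
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  m <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
  data.frame(time = m[, 1], activity = m[, 2])
}

#' Density snapshot files
#'
#' A snapshot stores the per-cell probability mass of a grid node at one
#' time point as plain text: a header with the time and grid geometry
#' followed by one mass value per line in linear cell-index order. The
#' in-grid masses sum to at most 1; any deficit is mass held in the
#' node's refractory queues at that time. `readDensitySnapshot` restores
#' the exact in-memory values.
#'
#' @param state a [DensityState-class].
#' @param grid the [StateGrid-class] the state lives on.
#' @param path file path.
#' @return `writeDensitySnapshot` returns `path` invisibly;
#'   `readDensitySnapshot` returns a list with elements `time`, `grid`
#'   and `mass`.
#' @export
writeDensitySnapshot <- function(state, grid, path) {
  stopifnot(methods::is(state, "DensityState"),
            methods::is(grid, "StateGrid"))
  if (length(state@mass) != nCells(grid))
    stop("state and grid dimensions disagree")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# popdens density snapshot",
    paste("time", .fmt17(state@time)),
    paste("grid", grid@nV, grid@nH, .fmt17(grid@vMin), .fmt17(grid@vMax),
          .fmt17(grid@hMin), .fmt17(grid@hMax))
  ), con)
  writeLines(.fmt17(state@mass), con)
  invisible(path)
}

#' @rdname writeDensitySnapshot
#' @export
readDensitySnapshot <- function(path) {
  if (!file.exists(path)) stop("density snapshot not found: ", path)
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  lines <- lines[!startsWith(trimws(lines), "#")]
  kv <- strsplit(trimws(lines[1:2]), "[[:space:]]+")
  names(kv) <- vapply(kv, `[`, character(1), 1)
  if (!all(c("time", "grid") %in% names(kv)))
    stop("malformed density snapshot: ", path)
  g <- as.numeric(kv$grid[-1])
  grid <- buildGrid(c(g[3], g[4], g[5], g[6]), c(g[1], g[2]))
  m <- as.numeric(lines[-(1:2)])
  if (length(m) != nCells(grid))
    stop("density snapshot has ", length(m), " mass values but the grid ",
         "has ", nCells(grid), " cells")
  list(time = as.numeric(kv$time[2]), grid = grid, mass = m)
}

#' Marginal distributions of a density
#'
#' Sums the mass grid over rows and columns: the marginal over the first
#' variable (v) is the per-column sum, the marginal over the second
#' variable (h) the per-row sum. Each marginal sums exactly to the total
#' in-grid mass.
#'
#' @param state a [DensityState-class], or a numeric mass vector in
#'   linear cell order.
#' @param grid a [StateGrid-class].
#' @return a list of two data.frames, `v` (columns `v`, `mass`) and `h`
#'   (columns `h`, `mass`), coordinates at cell centers.
#' @export
marginalDensities <- function(state, grid) {
  m <- if (methods::is(state, "DensityState")) state@mass else
    as.numeric(state)
  if (length(m) != nCells(grid))
    stop("mass vector length does not match the grid")
  mg <- matrix(m, nrow = grid@nV, ncol = grid@nH)
  cw <- cellWidth(grid); ch <- cellHeight(grid)
  list(
    v = data.frame(v = grid@vMin + (seq_len(grid@nV) - 0.5) * cw,
                   mass = rowSums(mg)),
    h = data.frame(h = grid@hMin + (seq_len(grid@nH) - 0.5) * ch,
                   mass = colSums(mg)))
}

#' Render a density heat map
#'
#' Renders the per-cell probability mass as a heat map image, normalised
#' to the maximum density value (the brightest cell is the most likely
#' state). An all-zero density renders as a uniform image with a warning.
#'
#' @param state a [DensityState-class] or numeric mass vector.
#' @param grid a [StateGrid-class].
#' @param path output PNG path; `NULL` draws on the active device.
#' @param width,height image size in pixels.
#' @param main plot title.
#' @return the normalised `nV x nH` intensity matrix, invisibly.
#' @export
renderDensityHeatmap <- function(state, grid, path = NULL,
                                 width = 480, height = 480, main = "") {
  m <- if (methods::is(state, "DensityState")) state@mass else
    as.numeric(state)
  if (length(m) != nCells(grid))
    stop("mass vector length does not match the grid")
  mx <- max(m)
  z <- matrix(if (mx > 0) m / mx else {
    warning("all-zero density; rendering a uniform image")
    rep(0, length(m))
  }, nrow = grid@nV, ncol = grid@nH)
  if (!is.null(path)) {
    grDevices::png(path, width = width, height = height)
    on.exit(grDevices::dev.off())
  }
  cw <- cellWidth(grid); ch <- cellHeight(grid)
  graphics::image(
    x = grid@vMin + (seq_len(grid@nV) - 0.5) * cw,
    y = grid@hMin + (seq_len(grid@nH) - 0.5) * ch,
    z = z, zlim = c(0, 1), col = grDevices::hcl.colors(100, "inferno"),
    xlab = "v", ylab = "h", main = main, useRaster = TRUE)
  invisible(z)
}
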