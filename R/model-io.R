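#' @include transition.R
NULL

## Plain-text dialects.
##
## .model (version 1): "key value" pairs, one per line; '#' comments.
## Required keys: v_min v_max h_min h_max n_v n_h timestep timescale
## threshold_v reset_v reset_shift_h refractory_period
## efficacy_orientation. Optional: "reset <thresholdCell> <resetCell>"
## lines serialising a reset mapping (1-based linear indices).
##
## .tmat (version 1): header keys dt, kind, n_v, n_h followed by one line
## per nonzero entry "source target proportion" (1-based linear indices,
## proportions at 17 significant digits so round-trips are bit-exact).

.fmt17 <- function(x)
  ifelse(is.finite(x), sprintf("%.17g", x), as.character(x))

#' Write and read grid model files
#'
#' Serialises the grid geometry and the scalar model parameters (bounds,
#' resolution, time step, timescale, threshold/reset values, refractory
#' period, efficacy orientation) to a plain-text `.model` file, optionally
#' including a threshold-to-reset-cell mapping. The vector field itself is
#' code and is not serialised; `readModelFile` therefore returns the grid,
#' the parameter set and any stored mapping, which
#' [gridAlgorithm()] combines with a vector field supplied in code.
#'
#' @param grid a [StateGrid-class].
#' @param model a [NeuronModel-class].
#' @param path file path.
#' @param mapping optionally a [ResetMapping-class] to serialise.
#' @return `writeModelFile` returns `path` invisibly. `readModelFile`
#'   returns a list with elements `grid` ([StateGrid-class]), `params`
#'   (named list of the scalar parameters) and `mapping` (a two-column
#'   integer matrix of threshold/reset cell pairs, or `NULL`).
#' @seealso [writeTmat()], [readTmat()]
#' @export
writeModelFile <- function(grid, model, path, mapping = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# popdens model file",
    "format_version 1",
    paste("v_min", .fmt17(grid@vMin)),
    paste("v_max", .fmt17(grid@vMax)),
    paste("h_min", .fmt17(grid@hMin)),
    paste("h_max", .fmt17(grid@hMax)),
    paste("n_v", grid@nV),
    paste("n_h", grid@nH),
    paste("timestep", .fmt17(model@timestep)),
    paste("timescale", .fmt17(model@timescale)),
    paste("threshold_v", .fmt17(model@thresholdV)),
    paste("reset_v", .fmt17(model@resetV)),
    paste("reset_shift_h", .fmt17(model@resetShiftH)),
    paste("refractory_period", .fmt17(model@refractoryPeriod)),
    paste("efficacy_orientation", model@efficacyOrientation)
  ), con)
  if (!is.null(mapping)) {
    stopifnot(methods::is(mapping, "ResetMapping"))
    if (length(mapping@thresholdCells))
      writeLines(paste("reset", mapping@thresholdCells,
                       mapping@resetCells), con)
  }
  invisible(path)
}

#' @rdname writeModelFile
#' @export
readModelFile <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  lines <- readLines(path)
  kv <- list()
  resets <- list()
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (s == "" || startsWith(s, "#")) next
    parts <- strsplit(s, "[[:space:]]+")[[1]]
    if (parts[1] == "reset") {
      if (length(parts) != 3)
        stop(sprintf("%s:%d: malformed reset mapping line", path, ln))
      resets[[length(resets) + 1L]] <- as.integer(parts[2:3])
    } else {
      if (length(parts) != 2)
        stop(sprintf("%s:%d: expected 'key value'", path, ln))
      kv[[parts[1]]] <- parts[2]
    }
  }
  need <- c("v_min", "v_max", "h_min", "h_max", "n_v", "n_h", "timestep",
            "timescale", "threshold_v", "reset_v", "reset_shift_h",
            "refractory_period", "efficacy_orientation")
  missingKeys <- setdiff(need, names(kv))
  if (length(missingKeys))
    stop("model file ", path, " is missing key(s): ",
         paste(missingKeys, collapse = ", "))
  num <- function(k) as.numeric(kv[[k]])
  grid <- buildGrid(c(num("v_min"), num("v_max"), num("h_min"),
                      num("h_max")),
                    c(as.integer(kv[["n_v"]]), as.integer(kv[["n_h"]])))
  params <- list(
    timestep = num("timestep"), timescale = num("timescale"),
    thresholdV = num("threshold_v"), resetV = num("reset_v"),
    resetShiftH = num("reset_shift_h"),
    refractoryPeriod = num("refractory_period"),
    efficacyOrientation = kv[["efficacy_orientation"]])
  mapping <- NULL
  if (length(resets))
    mapping <- do.call(rbind, resets)
  if (!is.null(mapping))
    colnames(mapping) <- c("thresholdCell", "resetCell")
  list(grid = grid, params = params, mapping = mapping)
}

#' Write and read transition-matrix files
#'
#' Serialises a [TransitionMatrix-class] to the plain-text `.tmat` dialect
#' (one line per nonzero entry, `source target proportion`, proportions at
#' 17 significant digits so a write/read round trip reproduces the matrix
#' bit-exactly). `readTmat` validates the stochasticity invariant: every
#' source cell's proportions must sum to 1 within `1e-9`.
#'
#' @param tmat a [TransitionMatrix-class].
#' @param path file path.
#' @param expectedDt if given, `readTmat` signals an error when the file's
#'   generating time step differs (guards against pairing a `.model` file
#'   with a `.tmat` generated at a different dt).
#' @return `writeTmat` returns `path` invisibly; `readTmat` returns a
#'   [TransitionMatrix-class].
#' @export
writeTmat <- function(tmat, path) {
  stopifnot(methods::is(tmat, "TransitionMatrix"))
  m <- methods::as(tmat@matrix, "TsparseMatrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# popdens transition matrix",
    "format_version 1",
    paste("dt", .fmt17(tmat@dt)),
    paste("kind", tmat@kind),
    paste("n_v", tmat@nV),
    paste("n_h", tmat@nH)
  ), con)
  ## m@j is the source (column), m@i the target (row), both 0-based
  writeLines(paste(m@j + 1L, m@i + 1L, .fmt17(m@x)), con)
  invisible(path)
}

#' @rdname writeTmat
#' @export
readTmat <- function(path, expectedDt = NULL) {
  if (!file.exists(path)) stop("tmat file not found: ", path)
  lines <- readLines(path)
  kv <- list()
  entryStart <- NA_integer_
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (s == "" || startsWith(s, "#")) next
    parts <- strsplit(s, "[[:space:]]+")[[1]]
    if (parts[1] %in% c("format_version", "dt", "kind", "n_v", "n_h")) {
      kv[[parts[1]]] <- parts[2]
    } else {
      entryStart <- ln
      break
    }
  }
  need <- c("dt", "kind", "n_v", "n_h")
  missingKeys <- setdiff(need, names(kv))
  if (length(missingKeys))
    stop("tmat file ", path, " is missing header key(s): ",
         paste(missingKeys, collapse = ", "))
  dt <- as.numeric(kv[["dt"]])
  if (!is.null(expectedDt) && !is.na(dt) &&
      abs(dt - expectedDt) > 1e-15 * max(1, abs(expectedDt)))
    stop(sprintf(
      "tmat file %s was generated with dt = %g but dt = %g was expected",
      path, dt, expectedDt))
  nV <- as.integer(kv[["n_v"]]); nH <- as.integer(kv[["n_h"]])
  n <- nV * nH
  src <- integer(0); tgt <- integer(0); prp <- numeric(0)
  if (!is.na(entryStart)) {
    body <- lines[entryStart:length(lines)]
    body <- body[trimws(body) != "" & !startsWith(trimws(body), "#")]
    if (length(body)) {
      fields <- strsplit(trimws(body), "[[:space:]]+")
      bad <- which(lengths(fields) != 3)
      if (length(bad))
        stop(sprintf("%s:%d: expected 'source target proportion'",
                     path, entryStart + bad[1] - 1L))
      fm <- matrix(unlist(fields), ncol = 3, byrow = TRUE)
      src <- as.integer(fm[, 1]); tgt <- as.integer(fm[, 2])
      prp <- as.numeric(fm[, 3])
      if (any(is.na(src)) || any(is.na(tgt)) || any(is.na(prp)))
        stop("tmat file ", path, ": non-numeric entry")
      if (any(src < 1L) || any(src > n) || any(tgt < 1L) || any(tgt > n))
        stop("tmat file ", path, ": cell index out of range")
    }
  }
  m <- Matrix::sparseMatrix(i = tgt, j = src, x = prp, dims = c(n, n))
  rs <- Matrix::colSums(m)
  worst <- which.max(abs(rs - 1))
  if (length(rs) && abs(rs[worst] - 1) > 1e-9)
    stop(sprintf(
      "tmat file %s violates mass conservation: source cell %d proportions sum to %.12g",
      path, worst, rs[worst]))
  methods::new("TransitionMatrix", matrix = methods::as(m, "CsparseMatrix"),
               dt = dt, kind = kv[["kind"]], nV = nV, nH = nH)
}
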