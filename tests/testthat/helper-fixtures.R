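# Shared fixtures, built in code and memoised so expensive transition
# matrices are generated once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# a field-free model: the flow is the identity
zeroFieldModel <- function(dt = 1e-3) {
  neuronModel("zero", function(y, t) list(0 * y[[1]], 0 * y[[2]]),
              timestep = dt)
}

# uniform translation field: c units of v per second, nothing in h
driftModel <- function(c, dt = 1e-3) {
  neuronModel("drift", function(y, t) list(rep(c, length(y[[1]])),
                                           0 * y[[2]]),
              timestep = dt)
}

# quick-start E-I conductance network: generates cond.model / cond.tmat
# next to a copy of the packaged cond.xml in a temp dir, returns the dir
condQuickStartDir <- function() {
  fixture("condDir", function() {
    dir <- file.path(tempdir(), "cond-quickstart")
    dir.create(dir, showWarnings = FALSE)
    m <- modelArchive("cond2d")
    m@timestep <- 1e-3
    m@refractoryPeriod <- 2e-3
    g <- buildGrid(c(-72, -54, -0.2, 1), c(100, 100))
    tm <- suppressWarnings(generateDeterministicMatrix(m, g))
    writeModelFile(g, m, file.path(dir, "cond.model"),
                   mapping = buildResetMapping(g, m))
    writeTmat(tm, file.path(dir, "cond.tmat"))
    file.copy(system.file("extdata", "cond.xml", package = "popdens"),
              file.path(dir, "cond.xml"), overwrite = TRUE)
    dir
  })
}

condModels <- function() {
  list(COND = modelArchive("cond2d"))
}

# Monte-Carlo area oracle: fraction of uniformly sampled quad points per
# cell; independent of the triangulation path
mcOverlapOracle <- function(quad, grid, n = 10000L) {
  A <- quad[1, ]; B <- quad[2, ]; C <- quad[3, ]; D <- quad[4, ]
  a1 <- abs((B[1] - A[1]) * (C[2] - A[2]) -
            (C[1] - A[1]) * (B[2] - A[2])) / 2
  a2 <- abs((C[1] - A[1]) * (D[2] - A[2]) -
            (D[1] - A[1]) * (C[2] - A[2])) / 2
  m1 <- round(n * a1 / (a1 + a2)); m2 <- n - m1
  sampleTri <- function(P, Q, R, m) {
    r1 <- sqrt(stats::runif(m)); r2 <- stats::runif(m)
    cbind((1 - r1) * P[1] + r1 * (1 - r2) * Q[1] + r1 * r2 * R[1],
          (1 - r1) * P[2] + r1 * (1 - r2) * Q[2] + r1 * r2 * R[2])
  }
  pts <- rbind(sampleTri(A, B, C, m1), sampleTri(A, C, D, m2))
  counts <- binToGrid(pts, grid)
  counts
}
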