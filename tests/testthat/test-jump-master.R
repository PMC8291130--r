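test_that("jump matrices implement the two-cell split formula", {
  g <- buildGrid(c(0, 1, 0, 1), c(20, 10))

  # zero efficacy: identity
  jm0 <- buildJumpMatrix(g, 0, "v")
  expect_equal(as.numeric(Matrix::diag(jm0@matrix)), rep(1, nCells(g)))

  # exactly one cell: clean single-target shift
  jm1 <- buildJumpMatrix(g, cellWidth(g), "v")
  src <- cellIndex(g, 5L, 3L)
  expect_equal(jm1@matrix[cellIndex(g, 6L, 3L), src], 1)

  # half a cell: 0.5 / 0.5 between offsets 0 and +1
  jmh <- buildJumpMatrix(g, cellWidth(g) / 2, "v")
  expect_equal(jmh@matrix[src, src], 0.5)
  expect_equal(jmh@matrix[cellIndex(g, 6L, 3L), src], 0.5)

  # h-orientation moves rows instead of columns
  jmv <- buildJumpMatrix(g, 1.5 * cellHeight(g), "h")
  expect_equal(jmv@matrix[cellIndex(g, 5L, 4L), src], 0.5)
  expect_equal(jmv@matrix[cellIndex(g, 5L, 5L), src], 0.5)
})

test_that("jump split matches a Monte-Carlo binning oracle", {
  set.seed(5)
  g <- buildGrid(c(0, 1, 0, 1), c(50, 1))
  h <- 0.033  # 1.65 cells: offset 1 with fraction 0.65
  jm <- buildJumpMatrix(g, h, "v")
  # uniform points in cell 10, shifted by h, binned
  n <- 200000
  pts <- cbind(stats::runif(n, 0.18, 0.20) + h, stats::runif(n, 0, 1))
  emp <- binToGrid(pts, g)
  expect_equal(jm@matrix[11, 10], 0.35, tolerance = 1e-12)
  expect_equal(emp[11], 0.35, tolerance = 0.01)
  expect_equal(jm@matrix[12, 10], 0.65, tolerance = 1e-12)
  expect_equal(emp[12], 0.65, tolerance = 0.01)
})

test_that("every jump row has at most two targets for arbitrary efficacy", {
  set.seed(9)
  for (trial in 1:25) {
    nV <- sample(3:40, 1); nH <- sample(1:10, 1)
    g <- buildGrid(c(sort(stats::runif(2, -10, 10)),
                     sort(stats::runif(2, -5, 5))), c(nV, nH))
    ori <- sample(c("v", "h"), 1)
    s <- if (ori == "v") cellWidth(g) else cellHeight(g)
    h <- stats::runif(1, -4, 4) * s
    jm <- buildJumpMatrix(g, h, ori)
    perSource <- diff(jm@matrix@p)
    expect_true(all(perSource <= 2L))
    expect_true(all(abs(Matrix::colSums(jm@matrix) - 1) < 1e-12))
  }
})

test_that("the master process is inert without input", {
  g <- buildGrid(c(0, 1, 0, 1), c(30, 1))
  st <- newDensityState(g, cell = 7L)
  out <- applyMasterProcess(st, list(), dt = 1e-3)
  expect_identical(mass(out), mass(st))
  jm <- buildJumpMatrix(g, cellWidth(g), "v")
  out2 <- applyMasterProcess(st, list(list(rate = 0, matrix = jm)),
                             dt = 1e-3)
  expect_identical(mass(out2), mass(st))
  expect_equal(simTime(out2), 1e-3)
})

test_that("a one-cell jump chain reproduces the analytic Poisson law", {
  g <- buildGrid(c(0, 1, 0, 1), c(60, 1))
  st <- newDensityState(g, cell = 5L)
  jm <- buildJumpMatrix(g, cellWidth(g), "v")
  out <- applyMasterProcess(st, list(list(rate = 1, matrix = jm)),
                            dt = 1, masterSteps = 1000L)
  k <- 0:40
  expect_lt(max(abs(mass(out)[5L + k] - stats::dpois(k, 1))), 1e-3)
  expect_equal(sum(mass(out)), 1, tolerance = 1e-9)
})

test_that("opposite equal inputs preserve the mean and grow the variance", {
  g <- buildGrid(c(0, 1, 0, 1), c(400, 1))
  s <- cellWidth(g)
  st <- newDensityState(g, cell = 200L)
  up <- buildJumpMatrix(g, 3.5 * s, "v")
  down <- buildJumpMatrix(g, -3.5 * s, "v")
  cen <- cellCenters(g)[, "v"]
  inputs <- list(list(rate = 50, matrix = up),
                 list(rate = 50, matrix = down))
  m0 <- sum(mass(st) * cen); v0 <- sum(mass(st) * cen^2) - m0^2
  for (k in 1:50)
    st <- applyMasterProcess(st, inputs, dt = 1e-3, masterSteps = 20L)
  m1 <- sum(mass(st) * cen); v1 <- sum(mass(st) * cen^2) - m1^2
  expect_equal(m1, m0, tolerance = 1e-10)
  expect_gt(v1, v0)
})

test_that("the mean/variance growth law holds to discretisation accuracy", {
  g <- buildGrid(c(0, 1, 0, 1), c(500, 1))
  s <- cellWidth(g)
  h <- 10.5 * s; nu <- 100
  jm <- buildJumpMatrix(g, h, "v")
  st <- newDensityState(g, start = c(0.2 + s / 2, 0.5))
  cen <- cellCenters(g)[, "v"]
  stat <- function(m) {
    mu <- sum(m * cen); c(mu, sum(m * cen^2) - mu^2)
  }
  s0 <- stat(mass(st))
  tT <- 0.1
  for (k in 1:100)
    st <- applyMasterProcess(st, list(list(rate = nu, matrix = jm)),
                             dt = 1e-3, masterSteps = 100L)
  s1 <- stat(mass(st))
  expect_equal((s1[1] - s0[1]) / tT, nu * h, tolerance = 0.02)
  expect_equal((s1[2] - s0[2]) / tT, nu * h^2, tolerance = 0.02)
})

test_that("joint application equals integration of the summed generator", {
  g <- buildGrid(c(0, 1, 0, 1), c(80, 1))
  j1 <- buildJumpMatrix(g, 2.3 * cellWidth(g), "v")
  j2 <- buildJumpMatrix(g, -1.1 * cellWidth(g), "v")
  st <- newDensityState(g, cell = 40L)
  out <- applyMasterProcess(st, list(list(rate = 30, matrix = j1),
                                     list(rate = 20, matrix = j2)),
                            dt = 1e-3, masterSteps = 10L)
  # manual Euler on the summed generator
  rho <- mass(st)
  Q <- 30 * j1@matrix + 20 * j2@matrix
  hh <- 1e-3 / 10
  for (k in 1:10) rho <- rho + hh * (as.numeric(Q %*% rho) - 50 * rho)
  expect_equal(mass(out), rho, tolerance = 1e-14)
})

test_that("grid refinement reduces the variance error of the shot noise", {
  # for a jump that is not an integer number of cells, the two-cell split
  # adds spurious variance s^2 f(1-f) per event plus s^2/12 from the
  # initial cell; both shrink when the cell size s is halved
  h <- 0.025; nu <- 20; tT <- 0.1
  excessFor <- function(nV) {
    g <- buildGrid(c(0, 1, 0, 1), c(nV, 1))
    st <- newDensityState(g, cell = round(nV / 5))
    jm <- buildJumpMatrix(g, h, "v")
    for (k in 1:100)
      st <- applyMasterProcess(st, list(list(rate = nu, matrix = jm)),
                               dt = tT / 100, masterSteps = 50L)
    cen <- cellCenters(g)[, "v"]
    mu <- sum(mass(st) * cen)
    vv <- sum(mass(st) * cen^2) - mu^2
    abs(vv - nu * tT * h^2)
  }
  expect_lt(excessFor(96), excessFor(48))
})

test_that("master blow-up is caught with actionable advice", {
  g <- buildGrid(c(0, 1, 0, 1), c(30, 1))
  st <- newDensityState(g, cell = 2L)
  jm <- buildJumpMatrix(g, cellWidth(g), "v")
  # absurdly large rate with one Euler substep drives mass negative
  expect_error(
    applyMasterProcess(st, list(list(rate = 5000, matrix = jm)),
                       dt = 1e-3, masterSteps = 1L),
    "masterSteps")
})
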