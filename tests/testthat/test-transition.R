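test_that("transformCell follows the flow", {
  g <- buildGrid(c(0, 1, 0, 1), c(10, 10))

  # identity flow: quadrilateral equals the cell
  z <- zeroFieldModel()
  expect_equal(transformCell(z, g, 23L), cellVertices(g, 23L))

  # uniform translation by exactly one column
  d <- driftModel(c = cellWidth(g) / 1e-3, dt = 1e-3)
  moved <- transformCell(d, g, 1L)
  expect_equal(moved, sweep(cellVertices(g, 1L), 2, c(cellWidth(g), 0),
                            "+"))

  # conductance model: the (E_l, 0) corner is a fixed point, other
  # vertices move toward it
  cond <- modelArchive("cond2d")
  gc <- buildGrid(c(-65, -55, 0, 1), c(10, 10))
  q <- transformCell(cond, gc, 1L)
  expect_equal(q[1, ], c(-65, 0))          # fixed corner
  expect_true(all(q[3, 2] < cellVertices(gc, 1L)[3, 2]))  # g_e decays
})

test_that("overlapFractions handles the exactly-aligned cases", {
  g <- buildGrid(c(0, 1, 0, 1), c(4, 4))
  q <- cellVertices(g, 6L)
  of <- overlapFractions(q, g)
  expect_equal(of$cell, 6L)
  expect_equal(of$fraction, 1)

  # half-cell shift in v: 0.5 / 0.5
  q2 <- sweep(q, 2, c(cellWidth(g) / 2, 0), "+")
  of2 <- overlapFractions(q2, g)
  expect_equal(of2$cell, c(6L, 7L))
  expect_equal(of2$fraction, c(0.5, 0.5))

  # diagonal half-cell shift: four cells at 0.25
  q3 <- sweep(q, 2, c(cellWidth(g) / 2, cellHeight(g) / 2), "+")
  of3 <- overlapFractions(q3, g)
  expect_equal(of3$cell, c(6L, 7L, 10L, 11L))
  expect_equal(of3$fraction, rep(0.25, 4))
})

test_that("overlapFractions matches a Monte-Carlo area oracle", {
  set.seed(41)
  g <- buildGrid(c(0, 1, 0, 1), c(8, 8))
  n <- 20000L
  for (trial in 1:30) {
    # random rotated/sheared/translated square, kept inside the grid
    th <- stats::runif(1, 0, 2 * pi)
    sc <- stats::runif(1, 0.05, 0.3)
    sh <- stats::runif(1, -0.4, 0.4)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    S <- matrix(c(1, 0, sh, 1), 2, 2)
    base <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
    quad <- sc * base %*% S %*% t(R)
    ctr <- stats::runif(2, 0.35, 0.65)
    quad <- sweep(quad, 2, ctr - colMeans(quad), "+")
    of <- overlapFractions(quad, g, warnBoundary = FALSE)
    emp <- mcOverlapOracle(quad, g, n)
    full <- numeric(nCells(g))
    full[of$cell] <- of$fraction
    se <- sqrt(pmax(full * (1 - full), 1e-6) / n)
    expect_true(all(abs(full - emp) <= 3.5 * se),
                info = sprintf("trial %d: worst |diff|/se = %.2f", trial,
                               max(abs(full - emp) / se)))
  }
})

test_that("degenerate quadrilaterals are reported", {
  g <- buildGrid(c(0, 1, 0, 1), c(4, 4))
  q <- matrix(c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1), 4, 2,
              byrow = TRUE)
  expect_error(overlapFractions(q, g), "degenerate")
})

test_that("zero field yields the identity matrix", {
  g <- buildGrid(c(0, 1, 0, 1), c(12, 9))
  tm <- generateDeterministicMatrix(zeroFieldModel(), g)
  expect_equal(as.numeric(Matrix::diag(tm@matrix)),
               rep(1, nCells(g)))
  expect_equal(length(tm@matrix@x), nCells(g))
})

test_that("uniform one-column translation yields a permutation matrix", {
  g <- buildGrid(c(0, 1, 0, 1), c(10, 4))
  d <- driftModel(c = cellWidth(g) / 1e-3, dt = 1e-3)
  expect_warning(tm <- generateDeterministicMatrix(d, g), "wrapped")
  m <- tm@matrix
  expect_true(all(abs(Matrix::colSums(m) - 1) < 1e-12))
  # interior columns shift one to the right; last column wraps to first
  for (j in 1:4) {
    for (i in 1:9)
      expect_equal(m[cellIndex(g, i + 1L, j), cellIndex(g, i, j)], 1)
    expect_equal(m[cellIndex(g, 1L, j), cellIndex(g, 10L, j)], 1)
  }
})

test_that("downward drift pins mass at the lower boundary", {
  g <- buildGrid(c(0, 1, 0, 1), c(5, 1))
  d <- driftModel(c = -cellWidth(g) / 1e-3, dt = 1e-3)
  expect_warning(tm <- generateDeterministicMatrix(d, g), "pinned")
  # the first column keeps its mass (pinned), all rows sum to 1
  expect_equal(tm@matrix[1, 1], 1)
  expect_true(all(abs(Matrix::colSums(tm@matrix) - 1) < 1e-12))
})

test_that("generated matrices are stochastic for a real model", {
  cond <- modelArchive("cond2d")
  g <- buildGrid(c(-72, -54, -0.2, 1), c(40, 40))
  tm <- suppressWarnings(generateDeterministicMatrix(cond, g))
  cs <- Matrix::colSums(tm@matrix)
  expect_true(all(abs(cs - 1) <= 1e-9))
  expect_true(all(tm@matrix@x >= 0))
  # sparse: mass only reaches nearby cells for a small time step
  expect_lt(length(tm@matrix@x), 12 * nCells(g))
})

test_that("matrix generation is independent of source-cell order", {
  cond <- modelArchive("cond2d")
  g <- buildGrid(c(-72, -54, -0.2, 1), c(15, 15))
  tm <- suppressWarnings(generateDeterministicMatrix(cond, g))
  # assemble the same matrix from per-cell calls in shuffled order
  set.seed(11)
  order <- sample(nCells(g))
  tri <- lapply(order, function(cell) {
    q <- transformCell(cond, g, cell)
    of <- suppressWarnings(overlapFractions(q, g, warnBoundary = FALSE))
    keep <- of$fraction >= 1e-12
    data.frame(src = cell, tgt = of$cell[keep],
               p = of$fraction[keep] / sum(of$fraction[keep]))
  })
  tri <- do.call(rbind, tri)
  m2 <- Matrix::sparseMatrix(i = tri$tgt, j = tri$src, x = tri$p,
                             dims = dim(tm@matrix))
  expect_equal(max(abs(tm@matrix - m2)), 0)
})

test_that("the matrix approaches identity as dt shrinks", {
  cond <- modelArchive("cond2d")
  g <- buildGrid(c(-72, -54, -0.2, 1), c(20, 20))
  selfMass <- vapply(1e-3 / 2^(0:5), function(dt) {
    tm <- suppressWarnings(generateDeterministicMatrix(cond, g, dt = dt))
    mean(Matrix::diag(tm@matrix))
  }, numeric(1))
  expect_true(all(diff(selfMass) > 0))
  expect_gt(selfMass[6], 0.85)
})

test_that("per-step displacement beyond the model tolerance warns", {
  fast <- driftModel(c = 100, dt = 1e-3)
  fast@tolerance <- 0.01
  g <- buildGrid(c(0, 1, 0, 1), c(10, 10))
  w <- capture_warnings(generateDeterministicMatrix(fast, g))
  expect_true(any(grepl("tolerance", w)))
})
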