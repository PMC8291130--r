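smallLifAlgorithm <- function(dt = 1e-3) {
  fixture("lifAlg", function() {
    m <- modelArchive("lif")
    m@timestep <- dt
    g <- buildGrid(c(-0.5, 1.02, -1, 1), c(76, 1))
    tm <- suppressWarnings(generateDeterministicMatrix(m, g))
    gridAlgorithm(m, g, tm, startV = 0.5, startH = 0)
  })
}

test_that("efficacy signs are validated against node types", {
  alg <- smallLifAlgorithm()
  nodes <- list(list(name = "A", algorithm = "LIF", type = "EXCITATORY"),
                list(name = "B", algorithm = "LIF", type = "INHIBITORY"),
                list(name = "C", algorithm = "LIF", type = "NEUTRAL"))
  mk <- function(from, eff)
    list(list(inNode = from, outNode = "A", numConnections = 1,
              efficacy = eff, delay = 0))
  base <- list(algorithms = list(LIF = alg), nodes = nodes, dt = 1e-3)

  # inhibitory node with negative efficacy: accepted
  expect_s4_class(validateNetwork(list(LIF = alg), nodes, mk("B", -0.05),
                                  dt = 1e-3), "PopulationNetwork")
  # excitatory node with negative efficacy: rejected, naming the link
  expect_error(validateNetwork(list(LIF = alg), nodes, mk("A", -0.1),
                               dt = 1e-3), "A -> A")
  # neutral: either sign
  expect_s4_class(validateNetwork(list(LIF = alg), nodes, mk("C", -0.3),
                                  dt = 1e-3), "PopulationNetwork")
  expect_s4_class(validateNetwork(list(LIF = alg), nodes, mk("C", 0.3),
                                  dt = 1e-3), "PopulationNetwork")
  # unknown endpoint
  expect_error(validateNetwork(list(LIF = alg), nodes, mk("Z", 0.1),
                               dt = 1e-3), "unknown node")
  # duplicate names
  expect_error(validateNetwork(list(LIF = alg),
                               c(nodes, nodes[1]), list(), dt = 1e-3),
               "unique")
})

test_that("effectiveInputRate multiplies activity by the connection count", {
  expect_equal(effectiveInputRate(10, 10), 100)
  expect_equal(effectiveInputRate(0, 50), 0)
  expect_equal(effectiveInputRate(2.5, 25), 62.5)
  expect_error(effectiveInputRate(1, -5), ">= 0")
})

test_that("a quiescent grid node reports zero activity at step 1", {
  alg <- smallLifAlgorithm()
  net <- validateNetwork(list(LIF = alg),
                         list(list(name = "P", algorithm = "LIF",
                                   type = "EXCITATORY")),
                         dt = 1e-3)
  net <- evolveNetworkStep(net)
  expect_equal(nodeActivity(net, "P"), 0)
  expect_equal(conservationError(net), 0, tolerance = 1e-12)
})

test_that("external input arity is enforced", {
  alg <- smallLifAlgorithm()
  net <- validateNetwork(
    list(LIF = alg),
    list(list(name = "P", algorithm = "LIF", type = "EXCITATORY")),
    incoming = list(list(node = "P", efficacy = 0.01)),
    dt = 1e-3)
  expect_error(evolveNetworkStep(net), "expected 1")
  expect_error(evolveNetworkStep(net, c(1, 2)), "expected 1")
  expect_s4_class(evolveNetworkStep(net, 100), "PopulationNetwork")
})

test_that("a delayed impulse arrives per the scalar queue oracle", {
  # two rate-driven observations: drive node B from node A through a
  # 1 ms delayed connection at dt = 1 ms; A's step-n output must first
  # influence B at step n + 2 (one queue slot + synchronous update)
  alg <- smallLifAlgorithm()
  net <- validateNetwork(
    algorithms = list(LIF = alg, SRC = rateAlgorithm(50)),
    nodes = list(list(name = "A", algorithm = "SRC", type = "EXCITATORY"),
                 list(name = "B", algorithm = "LIF",
                      type = "EXCITATORY")),
    connections = list(list(inNode = "A", outNode = "B",
                            numConnections = 1, efficacy = 0.05,
                            delay = 1e-3)),
    dt = 1e-3)
  # watch the mass leave B's starting cell: it only moves once input
  # (there is no drift at the cell around v = 0.5? there is, LIF decays)
  # -- instead watch the effective input via the density spread in h:
  # jumps are in v for LIF, so track total mass below the start cell
  startCell <- cellOf(alg$grid, 0.5, 0)
  massAt <- function(nw) mass(nodeDensity(nw, "B"))[startCell]
  m0 <- massAt(net)
  net1 <- evolveNetworkStep(net)
  net2 <- evolveNetworkStep(net1)
  net3 <- evolveNetworkStep(net2)
  # build the same network with no connection: pure drift reference
  ref <- validateNetwork(
    algorithms = list(LIF = alg, SRC = rateAlgorithm(50)),
    nodes = list(list(name = "A", algorithm = "SRC", type = "EXCITATORY"),
                 list(name = "B", algorithm = "LIF",
                      type = "EXCITATORY")),
    dt = 1e-3)
  ref1 <- evolveNetworkStep(ref)
  ref2 <- evolveNetworkStep(ref1)
  ref3 <- evolveNetworkStep(ref2)
  # steps 1 and 2: identical to drift-only (input not yet arrived)
  expect_equal(mass(nodeDensity(net1, "B")), mass(nodeDensity(ref1, "B")))
  expect_equal(mass(nodeDensity(net2, "B")), mass(nodeDensity(ref2, "B")))
  # step 3: the delayed input has arrived and the densities differ
  expect_gt(max(abs(mass(nodeDensity(net3, "B")) -
                    mass(nodeDensity(ref3, "B")))), 0)
})

test_that("runs are deterministic and bit-identical", {
  alg <- smallLifAlgorithm()
  build <- function() validateNetwork(
    algorithms = list(LIF = alg, SRC = rateAlgorithm(80)),
    nodes = list(list(name = "A", algorithm = "SRC",
                      type = "EXCITATORY"),
                 list(name = "B", algorithm = "LIF",
                      type = "EXCITATORY")),
    connections = list(list(inNode = "A", outNode = "B",
                            numConnections = 1, efficacy = 0.05,
                            delay = 0)),
    dt = 1e-3)
  run <- function() {
    net <- build()
    for (s in 1:50) net <- evolveNetworkStep(net)
    mass(nodeDensity(net, "B"))
  }
  expect_identical(run(), run())
})

test_that("a LIF population with zero input settles at its equilibrium", {
  alg <- smallLifAlgorithm()
  net <- validateNetwork(list(LIF = alg),
                         list(list(name = "P", algorithm = "LIF",
                                   type = "EXCITATORY")),
                         dt = 1e-3)
  # the LIF time constant is 1 s, so run several seconds of decay
  acts <- numeric(5000)
  for (s in 1:5000) {
    net <- evolveNetworkStep(net)
    acts[s] <- nodeActivity(net, "P")
  }
  expect_true(all(acts == 0))
  g <- alg$grid
  eq <- cellOf(g, 0, 0)
  dens <- mass(nodeDensity(net, "P"))
  # mass accumulates in (a neighbourhood of) the v = 0 equilibrium cell
  ij <- cellColRow(g, eq)
  nbhd <- cellIndex(g, ij[, "i"] + (-2:2), rep(ij[, "j"], 5))
  expect_gt(sum(dens[nbhd]), 0.95)
  expect_equal(conservationError(net), 0, tolerance = 1e-9)
})

test_that("AvgV activity is the mass-weighted mean membrane potential", {
  m <- modelArchive("lif")
  g <- buildGrid(c(-0.5, 1.02, -1, 1), c(76, 1))
  tm <- suppressWarnings(generateDeterministicMatrix(m, g))
  alg <- gridAlgorithm(m, g, tm, rateMethod = "avgv", startV = 0.5,
                       startH = 0)
  net <- validateNetwork(list(LIF = alg),
                         list(list(name = "P", algorithm = "LIF",
                                   type = "NEUTRAL")),
                         dt = 1e-3)
  net <- evolveNetworkStep(net)
  ds <- nodeDensity(net, "P")
  expected <- sum(mass(ds) * cellCenters(g)[, "v"]) / sum(mass(ds))
  expect_equal(nodeActivity(net, "P"), expected)
  # the potential decays toward 0 from the starting cell's center (0.51)
  expect_lt(nodeActivity(net, "P"), 0.51)
  expect_gt(nodeActivity(net, "P"), 0.45)
})
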