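condXml <- function() system.file("extdata", "cond.xml",
                                  package = "popdens")

test_that("the quick-start document parses to the expected structure", {
  cfg <- parseSimulationXML(condXml())
  expect_s4_class(cfg, "SimulationConfig")
  expect_identical(cfg@weightType, "CustomConnectionParameters")
  # two conductance populations and two input nodes
  expect_length(cfg@nodes, 4)
  nms <- vapply(cfg@nodes, function(n) n$name, character(1))
  expect_setequal(nms, c("E", "I", "Input_E", "Input_I"))
  expect_length(cfg@connections, 6)
  expect_length(cfg@outgoing, 2)
  # variable default used for t_end
  expect_equal(cfg@runParams$tEnd, 0.2)
  # master_steps omitted: defaults to 10
  expect_identical(cfg@runParams$masterSteps, 10L)
})

test_that("variable overrides take precedence over defaults", {
  cfg <- parseSimulationXML(condXml(), overrides = list(TIME_END = "1.0"))
  expect_equal(cfg@runParams$tEnd, 1.0)
  expect_error(parseSimulationXML(condXml(),
                                  overrides = list(NOPE = "1")),
               "undeclared")
})

test_that("override precedence holds for randomised variable maps", {
  tmpl <- '<Simulation>
    <WeightType>double</WeightType>
    <Algorithms>
      <Algorithm type="RateAlgorithm" name="S"><rate>RATE_A</rate></Algorithm>
    </Algorithms>
    <Nodes><Node algorithm="S" name="n" type="EXCITATORY"/></Nodes>
    <Connections/>
    <SimulationRunParameter>
      <SimulationName>v</SimulationName>
      <t_end>T_END</t_end><t_step>0.001</t_step>
      <name_log>v.log</name_log>
    </SimulationRunParameter>
    <Variable Name="RATE_A">5</Variable>
    <Variable Name="T_END">0.5</Variable>
  </Simulation>'
  set.seed(3)
  for (trial in 1:10) {
    ov <- list()
    if (stats::runif(1) < 0.5)
      ov$RATE_A <- as.character(round(stats::runif(1, 1, 99), 3))
    if (stats::runif(1) < 0.5)
      ov$T_END <- as.character(round(stats::runif(1, 0.1, 2), 3))
    cfg <- parseSimulationXML(tmpl, overrides = ov)
    expect_equal(cfg@algorithms$S$rate,
                 as.numeric(if (is.null(ov$RATE_A)) "5" else ov$RATE_A))
    expect_equal(cfg@runParams$tEnd,
                 as.numeric(if (is.null(ov$T_END)) "0.5" else ov$T_END))
  }
})

test_that("weight-type compatibility is enforced", {
  bad <- '<Simulation>
    <WeightType>DelayedConnection</WeightType>
    <Algorithms>
      <Algorithm type="GridAlgorithm" name="G" modelfile="x.model" tmatfile="x.tmat"/>
    </Algorithms>
    <Nodes><Node algorithm="G" name="n" type="NEUTRAL"/></Nodes>
    <Connections/>
    <SimulationRunParameter>
      <SimulationName>x</SimulationName>
      <t_end>0.1</t_end><t_step>0.001</t_step><name_log>x.log</name_log>
    </SimulationRunParameter>
  </Simulation>'
  expect_error(parseSimulationXML(bad), "incompatible with WeightType")
})

test_that("unsupported and unknown algorithm types are rejected explicitly", {
  mk <- function(type) sprintf('<Simulation>
    <WeightType>DelayedConnection</WeightType>
    <Algorithms><Algorithm type="%s" name="X" modelfile="a.model"/></Algorithms>
    <Nodes><Node algorithm="X" name="n" type="NEUTRAL"/></Nodes>
    <Connections/>
    <SimulationRunParameter>
      <SimulationName>x</SimulationName>
      <t_end>0.1</t_end><t_step>0.001</t_step><name_log>x.log</name_log>
    </SimulationRunParameter>
  </Simulation>', type)
  expect_error(parseSimulationXML(mk("MeshAlgorithm")), "unsupported")
  expect_error(parseSimulationXML(mk("OUAlgorithm")), "unsupported")
  expect_error(parseSimulationXML(mk("WilsonCowanAlgorithm")),
               "unsupported")
  expect_error(parseSimulationXML(mk("GridJumpAlgorithm")), "unsupported")
  expect_error(parseSimulationXML(mk("MadeUpAlgorithm")), "unknown type")
})

test_that("duplicate variables and non-numeric substitutions error", {
  dup <- '<Simulation>
    <WeightType>double</WeightType>
    <Algorithms><Algorithm type="RateAlgorithm" name="S"><rate>1</rate></Algorithm></Algorithms>
    <Nodes><Node algorithm="S" name="n" type="NEUTRAL"/></Nodes>
    <Connections/>
    <SimulationRunParameter>
      <SimulationName>x</SimulationName>
      <t_end>0.1</t_end><t_step>0.001</t_step><name_log>x.log</name_log>
    </SimulationRunParameter>
    <Variable Name="A">1</Variable><Variable Name="A">2</Variable>
  </Simulation>'
  expect_error(parseSimulationXML(dup), "duplicate Variable")

  expect_error(
    parseSimulationXML(condXml(), overrides = list(TIME_END = "soon")),
    "non-numerical")
})

test_that("RateFunctor accepts only constant expressions", {
  mk <- function(expr) sprintf('<Simulation>
    <WeightType>double</WeightType>
    <Algorithms><Algorithm type="RateFunctor" name="F"><expression>%s</expression></Algorithm></Algorithms>
    <Nodes><Node algorithm="F" name="n" type="NEUTRAL"/></Nodes>
    <Connections/>
    <SimulationRunParameter>
      <SimulationName>x</SimulationName>
      <t_end>0.1</t_end><t_step>0.001</t_step><name_log>x.log</name_log>
    </SimulationRunParameter>
  </Simulation>', expr)
  cfg <- parseSimulationXML(mk("42.5"))
  expect_equal(cfg@algorithms$F$rate, 42.5)
  expect_error(parseSimulationXML(mk("100*t/0.1")), "constant")
})

test_that("rate reporting intervals below the time step are rejected", {
  bad <- '<Simulation>
    <WeightType>double</WeightType>
    <Algorithms><Algorithm type="RateAlgorithm" name="S"><rate>1</rate></Algorithm></Algorithms>
    <Nodes><Node algorithm="S" name="n" type="NEUTRAL"/></Nodes>
    <Connections/>
    <Reporting><Rate node="n" t_interval="0.0001"/></Reporting>
    <SimulationRunParameter>
      <SimulationName>x</SimulationName>
      <t_end>0.1</t_end><t_step>0.001</t_step><name_log>x.log</name_log>
    </SimulationRunParameter>
  </Simulation>'
  expect_error(parseSimulationXML(bad), "t_interval")
})

test_that("serialising and re-parsing a configuration round-trips", {
  cfg <- parseSimulationXML(condXml())
  path <- withr::local_tempfile(fileext = ".xml")
  writeSimulationXML(cfg, path)
  cfg2 <- parseSimulationXML(path)
  expect_equal(cfg2@weightType, cfg@weightType)
  expect_equal(cfg2@algorithms, cfg@algorithms)
  expect_equal(cfg2@nodes, cfg@nodes)
  # extra custom attributes are preserved only as parsed metadata, so
  # compare the semantic connection fields
  strip <- function(cs) lapply(cs, function(x) x[c("inNode", "outNode",
                                                   "numConnections",
                                                   "efficacy", "delay")])
  expect_equal(strip(cfg2@connections), strip(cfg@connections))
  expect_equal(cfg2@incoming, cfg@incoming)
  expect_equal(cfg2@outgoing, cfg@outgoing)
  expect_equal(cfg2@reporting, cfg@reporting)
  expect_equal(cfg2@runParams, cfg@runParams)
})

test_that("extra custom connection attributes are parsed and preserved", {
  xml <- '<Simulation>
    <WeightType>CustomConnectionParameters</WeightType>
    <Algorithms><Algorithm type="RateAlgorithm" name="S"><rate>1</rate></Algorithm></Algorithms>
    <Nodes>
      <Node algorithm="S" name="a" type="EXCITATORY"/>
      <Node algorithm="S" name="b" type="NEUTRAL"/>
    </Nodes>
    <Connections>
      <Connection In="a" Out="b" num_connections="2" efficacy="0.1" delay="0" stationary="-65"/>
    </Connections>
    <SimulationRunParameter>
      <SimulationName>x</SimulationName>
      <t_end>0.1</t_end><t_step>0.001</t_step><name_log>x.log</name_log>
    </SimulationRunParameter>
  </Simulation>'
  cfg <- parseSimulationXML(xml)
  expect_equal(cfg@connections[[1]]$extra$stationary, "-65")
})
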