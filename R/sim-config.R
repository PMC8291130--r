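#' @include network.R model-io.R
NULL

.SUPPORTED_ALGOS <- c("RateAlgorithm", "RateFunctor", "GridAlgorithm",
                      "GridAlgorithmGroup")
.REJECTED_ALGOS <- c("MeshAlgorithm", "MeshAlgorithmCustom",
                     "MeshAlgorithmGroup", "OUAlgorithm",
                     "WilsonCowanAlgorithm", "GridJumpAlgorithm")

## weight-type compatibility (GridAlgorithm requires the custom-parameter
## connection vocabulary; rate sources work with any weight type)
.algoWeightOk <- function(type, weightType) {
  switch(type,
    RateAlgorithm = TRUE,
    RateFunctor = TRUE,
    GridAlgorithm = ,
    GridAlgorithmGroup = weightType == "CustomConnectionParameters",
    FALSE)
}

.asNum <- function(x, what) {
  out <- suppressWarnings(as.numeric(x))
  if (length(out) != 1 || is.na(out))
    stop("non-numerical value '", x, "' for ", what)
  out
}

## substitute variable names in a string: a value equal to a variable name
## is replaced by the variable's (string) value.
.substVars <- function(x, vars) {
  if (is.null(x) || !length(vars)) return(x)
  hit <- match(x, names(vars))
  ifelse(is.na(hit), x, unname(vars[hit]))
}

#' Parse a simulation XML document
#'
#' Reads the XML simulation dialect into a [SimulationConfig-class]. The
#' document root is `<Simulation>` with sections `<Algorithms>`,
#' `<Nodes>`, `<Connections>` (also holding `<IncomingConnection>` /
#' `<OutgoingConnection>` declarations), `<Reporting>` and
#' `<SimulationRunParameter>`, plus any number of `<Variable>`
#' definitions. Every attribute or element value equal to a variable name
#' is replaced by the override supplied here or, failing that, the
#' variable's default; values are type-checked only after substitution.
#'
#' Supported algorithm types are `RateAlgorithm`, `RateFunctor` (constant
#' expressions only) and `GridAlgorithm` (`GridAlgorithmGroup` is accepted
#' as an alias). Mesh, Ornstein-Uhlenbeck, Wilson-Cowan and jump-file
#' algorithm types are recognised and rejected explicitly. `GridAlgorithm`
#' requires `<WeightType>CustomConnectionParameters</WeightType>`;
#' connection compatibility with the declared weight type is enforced.
#'
#' @param document path to an XML file, or a string containing XML.
#' @param overrides named list/character of variable overrides (values are
#'   strings, as variables are untyped text until substitution).
#' @return a [SimulationConfig-class].
#' @examples
#' xml <- system.file("extdata", "cond.xml", package = "popdens")
#' cfg <- parseSimulationXML(xml)
#' cfg@runParams$tEnd
#' @export
parseSimulationXML <- function(document, overrides = list()) {
  doc <- xml2::read_xml(document)
  if (xml2::xml_name(doc) != "Simulation")
    stop("root element must be <Simulation>")

  ## variables: defaults from the document, then overrides
  varNodes <- xml2::xml_find_all(doc, "./Variable")
  vars <- character(0)
  for (vn in varNodes) {
    nm <- xml2::xml_attr(vn, "Name")
    if (is.na(nm)) nm <- xml2::xml_attr(vn, "name")
    if (is.na(nm)) stop("<Variable> without a Name attribute")
    if (nm %in% names(vars))
      stop("duplicate Variable name '", nm, "'")
    vars[nm] <- trimws(xml2::xml_text(vn))
  }
  if (length(overrides)) {
    ov <- vapply(overrides, as.character, character(1))
    unknown <- setdiff(names(ov), names(vars))
    if (length(unknown))
      stop("override(s) for undeclared Variable(s): ",
           paste(unknown, collapse = ", "))
    vars[names(ov)] <- ov
  }

  attrS <- function(node, name, default = NA_character_) {
    x <- xml2::xml_attr(node, name)
    if (is.na(x)) return(default)
    .substVars(x, vars)
  }
  textS <- function(node) .substVars(trimws(xml2::xml_text(node)), vars)
  childS <- function(node, name) {
    ch <- xml2::xml_find_first(node, paste0("./", name))
    if (inherits(ch, "xml_missing")) return(NA_character_)
    textS(ch)
  }

  wtNode <- xml2::xml_find_first(doc, "./WeightType")
  weightType <- if (inherits(wtNode, "xml_missing")) {
    "CustomConnectionParameters"
  } else textS(wtNode)
  if (!weightType %in% c("double", "DelayedConnection",
                         "CustomConnectionParameters"))
    stop("unknown WeightType '", weightType, "'")

  ## algorithms
  algorithms <- list()
  for (an in xml2::xml_find_all(doc, "./Algorithms/Algorithm")) {
    type <- attrS(an, "type")
    name <- attrS(an, "name")
    if (is.na(type) || is.na(name))
      stop("<Algorithm> requires 'type' and 'name' attributes")
    if (type %in% .REJECTED_ALGOS)
      stop("algorithm '", name, "': type ", type,
           " is unsupported in this implementation")
    if (!type %in% .SUPPORTED_ALGOS)
      stop("algorithm '", name, "': unknown type ", type)
    if (!.algoWeightOk(type, weightType))
      stop("algorithm '", name, "' of type ", type,
           " is incompatible with WeightType ", weightType)
    def <- switch(type,
      RateAlgorithm = {
        r <- childS(an, "rate")
        if (is.na(r)) stop("RateAlgorithm '", name, "' needs a <rate>")
        list(kind = "rate", rate = .asNum(r, paste0("rate of '", name, "'")))
      },
      RateFunctor = {
        expr <- childS(an, "expression")
        if (is.na(expr)) expr <- textS(an)
        r <- suppressWarnings(as.numeric(expr))
        if (is.na(r))
          stop("RateFunctor '", name, "' supports only constant ",
               "expressions; got '", expr, "'")
        list(kind = "rate", rate = r)
      },
      {
        ## GridAlgorithm / GridAlgorithmGroup
        mf <- attrS(an, "modelfile")
        tf <- attrS(an, "tmatfile")
        if (is.na(mf) || is.na(tf))
          stop("GridAlgorithm '", name,
               "' requires 'modelfile' and 'tmatfile' attributes")
        tr <- attrS(an, "tau_refractive", "0")
        rm <- attrS(an, "ratemethod", "")
        sv <- attrS(an, "start_v")
        sw <- attrS(an, "start_w")
        list(kind = "grid", modelfile = mf, tmatfile = tf,
             tauRefractive = .asNum(tr, paste0("tau_refractive of '",
                                               name, "'")),
             rateMethod = if (identical(rm, "AvgV")) "avgv" else "rate",
             startV = if (is.na(sv)) NULL else
               .asNum(sv, paste0("start_v of '", name, "'")),
             startH = if (is.na(sw)) NULL else
               .asNum(sw, paste0("start_w of '", name, "'")))
      })
    if (name %in% names(algorithms))
      stop("duplicate algorithm name '", name, "'")
    algorithms[[name]] <- def
  }

  ## nodes
  nodes <- list()
  for (nn in xml2::xml_find_all(doc, "./Nodes/Node")) {
    nm <- attrS(nn, "name")
    alg <- attrS(nn, "algorithm")
    tp <- attrS(nn, "type", "NEUTRAL")
    if (is.na(nm) || is.na(alg))
      stop("<Node> requires 'name' and 'algorithm' attributes")
    if (!alg %in% names(algorithms))
      stop("node '", nm, "' references undeclared algorithm '", alg, "'")
    nodes[[length(nodes) + 1L]] <- list(name = nm, algorithm = alg,
                                        type = tp)
  }

  ## connections (format depends on the weight type)
  connections <- list()
  incoming <- list()
  outgoing <- list()
  for (cn in xml2::xml_find_all(doc, "./Connections/*")) {
    tag <- xml2::xml_name(cn)
    if (tag == "Connection") {
      inN <- attrS(cn, "In"); outN <- attrS(cn, "Out")
      if (is.na(inN) || is.na(outN))
        stop("<Connection> requires 'In' and 'Out' attributes")
      spec <- switch(weightType,
        CustomConnectionParameters = {
          ncs <- attrS(cn, "num_connections")
          eff <- attrS(cn, "efficacy")
          dly <- attrS(cn, "delay", "0")
          if (is.na(ncs) || is.na(eff))
            stop("connection ", inN, " -> ", outN,
                 ": num_connections and efficacy attributes required")
          extra <- xml2::xml_attrs(cn)
          extra <- extra[!names(extra) %in%
                           c("In", "Out", "num_connections", "efficacy",
                             "delay")]
          list(numConnections = .asNum(ncs, "num_connections"),
               efficacy = .asNum(eff, "efficacy"),
               delay = .asNum(dly, "delay"),
               extra = as.list(.substVars(extra, vars)))
        },
        DelayedConnection = {
          parts <- strsplit(textS(cn), "[[:space:]]+")[[1]]
          parts <- parts[parts != ""]
          if (length(parts) != 3)
            stop("connection ", inN, " -> ", outN,
                 ": DelayedConnection needs three values ",
                 "(num_connections efficacy delay)")
          list(numConnections = .asNum(parts[1], "num_connections"),
               efficacy = .asNum(parts[2], "efficacy"),
               delay = .asNum(parts[3], "delay"), extra = list())
        },
        double = {
          w <- textS(cn)
          list(numConnections = .asNum(w, "connection weight"),
               efficacy = 0, delay = 0, extra = list())
        })
      spec$inNode <- inN; spec$outNode <- outN
      connections[[length(connections) + 1L]] <- spec
    } else if (tag == "IncomingConnection") {
      nd <- attrS(cn, "Node")
      if (is.na(nd)) nd <- attrS(cn, "node")
      if (is.na(nd)) stop("<IncomingConnection> requires a Node attribute")
      ncs <- attrS(cn, "num_connections", "1")
      eff <- attrS(cn, "efficacy", "0")
      dly <- attrS(cn, "delay", "0")
      incoming[[length(incoming) + 1L]] <-
        list(node = nd, numConnections = .asNum(ncs, "num_connections"),
             efficacy = .asNum(eff, "efficacy"),
             delay = .asNum(dly, "delay"))
    } else if (tag == "OutgoingConnection") {
      nd <- attrS(cn, "Node")
      if (is.na(nd)) nd <- attrS(cn, "node")
      if (is.na(nd)) stop("<OutgoingConnection> requires a Node attribute")
      outgoing[[length(outgoing) + 1L]] <- list(node = nd)
    } else {
      stop("unknown element <", tag, "> in <Connections>")
    }
  }

  ## reporting
  rates <- list(); densities <- list(); display <- character(0)
  rep <- xml2::xml_find_first(doc, "./Reporting")
  if (!inherits(rep, "xml_missing")) {
    for (rn in xml2::xml_find_all(rep, "./Rate")) {
      rates[[length(rates) + 1L]] <- list(
        node = attrS(rn, "node"),
        tInterval = .asNum(attrS(rn, "t_interval"), "Rate t_interval"))
    }
    for (dn in xml2::xml_find_all(rep, "./Density")) {
      densities[[length(densities) + 1L]] <- list(
        node = attrS(dn, "node"),
        tStart = .asNum(attrS(dn, "t_start"), "Density t_start"),
        tEnd = .asNum(attrS(dn, "t_end"), "Density t_end"),
        tInterval = .asNum(attrS(dn, "t_interval"), "Density t_interval"))
    }
    for (dn in xml2::xml_find_all(rep, "./Display"))
      display <- c(display, attrS(dn, "node"))
  }

  ## run parameters
  rp <- xml2::xml_find_first(doc, "./SimulationRunParameter")
  if (inherits(rp, "xml_missing"))
    stop("missing <SimulationRunParameter> section")
  ms <- childS(rp, "master_steps")
  runParams <- list(
    simulationName = {
      x <- childS(rp, "SimulationName"); if (is.na(x)) "simulation" else x
    },
    tEnd = .asNum(childS(rp, "t_end"), "t_end"),
    tStep = .asNum(childS(rp, "t_step"), "t_step"),
    nameLog = {
      x <- childS(rp, "name_log"); if (is.na(x)) "simulation.log" else x
    },
    masterSteps = if (is.na(ms)) 10L else
      as.integer(.asNum(ms, "master_steps")))
  if (runParams$tStep <= 0) stop("t_step must be positive")
  if (runParams$tEnd < 0) stop("t_end must be >= 0")
  for (r in rates)
    if (r$tInterval < runParams$tStep)
      stop("Rate t_interval must be >= the simulation time step")

  cfg <- methods::new("SimulationConfig",
    weightType = weightType, algorithms = algorithms, nodes = nodes,
    connections = connections, incoming = incoming, outgoing = outgoing,
    reporting = list(rates = rates, densities = densities,
                     display = display),
    runParams = runParams, variables = vars)
  ## structural validation against node/algorithm references
  nodeNames <- vapply(nodes, function(n) n$name, character(1))
  for (cn in connections) {
    if (!cn$inNode %in% nodeNames)
      stop("connection references unknown node '", cn$inNode, "'")
    if (!cn$outNode %in% nodeNames)
      stop("connection references unknown node '", cn$outNode, "'")
  }
  for (d in densities) {
    if (!d$node %in% nodeNames)
      stop("Density record references unknown node '", d$node, "'")
    if (algorithms[[nodes[[match(d$node, nodeNames)]]$algorithm]]$kind !=
        "grid")
      stop("density can only be recorded from grid-algorithm nodes; '",
           d$node, "' is a rate node")
  }
  cfg
}

#' Serialise a simulation configuration back to XML
#'
#' Writes a [SimulationConfig-class] in the same XML vocabulary that
#' [parseSimulationXML()] reads (values already substituted). Parsing the
#' result yields an equal configuration.
#'
#' @param config a [SimulationConfig-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSimulationXML <- function(config, path) {
  num <- function(x) formatC(x, digits = 17, format = "g")
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  ln <- c("<Simulation>",
          paste0("<WeightType>", config@weightType, "</WeightType>"),
          "<Algorithms>")
  for (nm in names(config@algorithms)) {
    a <- config@algorithms[[nm]]
    if (a$kind == "rate") {
      ln <- c(ln, paste0("<Algorithm type=\"RateAlgorithm\" name=\"",
                         esc(nm), "\"><rate>", num(a$rate),
                         "</rate></Algorithm>"))
    } else {
      attrs <- paste0(" modelfile=\"", esc(a$modelfile),
                      "\" tmatfile=\"", esc(a$tmatfile),
                      "\" tau_refractive=\"", num(a$tauRefractive), "\"")
      if (identical(a$rateMethod, "avgv"))
        attrs <- paste0(attrs, " ratemethod=\"AvgV\"")
      if (!is.null(a$startV))
        attrs <- paste0(attrs, " start_v=\"", num(a$startV), "\"")
      if (!is.null(a$startH))
        attrs <- paste0(attrs, " start_w=\"", num(a$startH), "\"")
      ln <- c(ln, paste0("<Algorithm type=\"GridAlgorithm\" name=\"",
                         esc(nm), "\"", attrs, "/>"))
    }
  }
  ln <- c(ln, "</Algorithms>", "<Nodes>")
  for (nd in config@nodes)
    ln <- c(ln, paste0("<Node algorithm=\"", esc(nd$algorithm),
                       "\" name=\"", esc(nd$name), "\" type=\"", nd$type,
                       "\"/>"))
  ln <- c(ln, "</Nodes>", "<Connections>")
  for (cn in config@connections) {
    if (config@weightType == "CustomConnectionParameters") {
      ln <- c(ln, paste0("<Connection In=\"", esc(cn$inNode),
                         "\" Out=\"", esc(cn$outNode),
                         "\" num_connections=\"", num(cn$numConnections),
                         "\" efficacy=\"", num(cn$efficacy),
                         "\" delay=\"", num(cn$delay), "\"/>"))
    } else if (config@weightType == "DelayedConnection") {
      ln <- c(ln, paste0("<Connection In=\"", esc(cn$inNode),
                         "\" Out=\"", esc(cn$outNode), "\">",
                         num(cn$numConnections), " ", num(cn$efficacy),
                         " ", num(cn$delay), "</Connection>"))
    } else {
      ln <- c(ln, paste0("<Connection In=\"", esc(cn$inNode),
                         "\" Out=\"", esc(cn$outNode), "\">",
                         num(cn$numConnections), "</Connection>"))
    }
  }
  for (ic in config@incoming)
    ln <- c(ln, paste0("<IncomingConnection Node=\"", esc(ic$node),
                       "\" num_connections=\"", num(ic$numConnections),
                       "\" efficacy=\"", num(ic$efficacy),
                       "\" delay=\"", num(ic$delay), "\"/>"))
  for (og in config@outgoing)
    ln <- c(ln, paste0("<OutgoingConnection Node=\"", esc(og$node),
                       "\"/>"))
  ln <- c(ln, "</Connections>", "<Reporting>")
  for (r in config@reporting$rates)
    ln <- c(ln, paste0("<Rate node=\"", esc(r$node), "\" t_interval=\"",
                       num(r$tInterval), "\"/>"))
  for (d in config@reporting$densities)
    ln <- c(ln, paste0("<Density node=\"", esc(d$node), "\" t_start=\"",
                       num(d$tStart), "\" t_end=\"", num(d$tEnd),
                       "\" t_interval=\"", num(d$tInterval), "\"/>"))
  for (d in config@reporting$display)
    ln <- c(ln, paste0("<Display node=\"", esc(d), "\"/>"))
  rp <- config@runParams
  ln <- c(ln, "</Reporting>", "<SimulationRunParameter>",
          paste0("<SimulationName>", esc(rp$simulationName),
                 "</SimulationName>"),
          paste0("<t_end>", num(rp$tEnd), "</t_end>"),
          paste0("<t_step>", num(rp$tStep), "</t_step>"),
          paste0("<name_log>", esc(rp$nameLog), "</name_log>"),
          paste0("<master_steps>", rp$masterSteps, "</master_steps>"),
          "</SimulationRunParameter>", "</Simulation>")
  writeLines(ln, path)
  invisible(path)
}

#' Instantiate a network from a parsed configuration
#'
#' Resolves the configuration's algorithm definitions into runtime
#' objects — grid algorithms load their `.model`/`.tmat` files (paths
#' resolved against `basedir`) and combine them with the matching archive
#' or user-supplied vector field — and builds the validated
#' [PopulationNetwork-class].
#'
#' @param config a [SimulationConfig-class].
#' @param basedir directory against which model/tmat file references are
#'   resolved (default: the working directory).
#' @param models named list mapping a grid algorithm name to the
#'   [NeuronModel-class] providing its vector field. A model file stores
#'   only parameters; the field itself is code.
#' @return a [PopulationNetwork-class].
#' @export
buildNetworkFromConfig <- function(config, basedir = ".", models = list()) {
  algs <- list()
  for (nm in names(config@algorithms)) {
    a <- config@algorithms[[nm]]
    if (a$kind == "rate") {
      algs[[nm]] <- rateAlgorithm(a$rate)
    } else {
      mf <- file.path(basedir, a$modelfile)
      tf <- file.path(basedir, a$tmatfile)
      info <- readModelFile(mf)
      if (!nm %in% names(models))
        stop("grid algorithm '", nm, "': supply its vector field through ",
             "the 'models' argument (model files store parameters only)")
      base <- models[[nm]]
      model <- neuronModel(
        name = base@name, vectorField = base@vectorField,
        timestep = info$params$timestep, timescale = info$params$timescale,
        thresholdV = info$params$thresholdV, resetV = info$params$resetV,
        resetShiftH = info$params$resetShiftH,
        refractoryPeriod = a$tauRefractive,
        efficacyOrientation = info$params$efficacyOrientation)
      tmat <- readTmat(tf, expectedDt = info$params$timestep)
      algs[[nm]] <- gridAlgorithm(model, info$grid, tmat,
                                  rateMethod = a$rateMethod,
                                  startV = a$startV, startH = a$startH)
    }
  }
  validateNetwork(
    algorithms = algs, nodes = config@nodes,
    connections = config@connections, incoming = config@incoming,
    outgoing = config@outgoing, dt = config@runParams$tStep,
    masterSteps = config@runParams$masterSteps)
}

#' Run a configured simulation
#'
#' Executes `round(tEnd / tStep)` synchronous network steps, recording
#' rate traces and density snapshots according to the configuration's
#' reporting plan. The run is fully deterministic: identical
#' configurations produce identical results.
#'
#' @param config a [SimulationConfig-class].
#' @param basedir directory for resolving model/tmat references.
#' @param models named list of [NeuronModel-class] vector-field providers
#'   for grid algorithms (see [buildNetworkFromConfig()]).
#' @param outDir if non-`NULL`, rate and density records are also written
#'   as files under this directory.
#' @param externalInputFun optional `function(step, time)` returning the
#'   external input vector for each step (defaults to zeros).
#' @param network optionally a pre-built [PopulationNetwork-class]
#'   (skips [buildNetworkFromConfig()]).
#' @return a list with elements `rates` (data.frame `time`, `node`,
#'   `activity`), `densities` (named list of [DensityState-class]
#'   snapshots, names `"<node>@<time>"`), `network` (final state), `log`
#'   (character vector) and `conservationError`.
#' @export
runSimulation <- function(config, basedir = ".", models = list(),
                          outDir = NULL, externalInputFun = NULL,
                          network = NULL) {
  rp <- config@runParams
  if (is.null(network))
    network <- buildNetworkFromConfig(config, basedir, models)
  nSteps <- round(rp$tEnd / rp$tStep)
  dt <- rp$tStep
  log <- sprintf("simulation '%s': %d steps of %g s", rp$simulationName,
                 nSteps, dt)

  rateRecs <- config@reporting$rates
  densRecs <- config@reporting$densities
  recTimes <- lapply(rateRecs, function(r) numeric(0))
  recVals <- lapply(rateRecs, function(r) numeric(0))
  densities <- list()

  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)

  recordEvery <- vapply(rateRecs, function(r)
    max(1L, as.integer(round(r$tInterval / dt))), integer(1))
  densEvery <- vapply(densRecs, function(d)
    max(1L, as.integer(round(d$tInterval / dt))), integer(1))

  ## step-0 records (initial state)
  for (k in seq_along(densRecs)) {
    d <- densRecs[[k]]
    if (d$tStart <= 0 && d$tEnd >= 0) {
      ds <- nodeDensity(network, d$node)
      densities[[paste0(d$node, "@0")]] <- ds
      if (!is.null(outDir)) {
        alg <- network@algorithms[[network@nodes[[d$node]]$algorithm]]
        writeDensitySnapshot(ds, alg$grid,
          file.path(outDir, sprintf("%s_0.density", d$node)))
      }
    }
  }
  for (k in seq_along(rateRecs)) {
    recTimes[[k]] <- c(recTimes[[k]], 0)
    recVals[[k]] <- c(recVals[[k]],
                      nodeActivity(network, rateRecs[[k]]$node))
  }

  for (s in seq_len(nSteps)) {
    tNow <- s * dt
    ext <- if (is.null(externalInputFun)) {
      numeric(length(network@incoming))
    } else {
      externalInputFun(s, tNow)
    }
    network <- evolveNetworkStep(network, ext)
    for (k in seq_along(rateRecs)) {
      if (s %% recordEvery[k] == 0L) {
        recTimes[[k]] <- c(recTimes[[k]], tNow)
        recVals[[k]] <- c(recVals[[k]],
                          nodeActivity(network, rateRecs[[k]]$node))
      }
    }
    for (k in seq_along(densRecs)) {
      d <- densRecs[[k]]
      if (tNow >= d$tStart - 1e-12 && tNow <= d$tEnd + 1e-12 &&
          s %% densEvery[k] == 0L) {
        ds <- nodeDensity(network, d$node)
        densities[[sprintf("%s@%g", d$node, tNow)]] <- ds
        if (!is.null(outDir)) {
          alg <- network@algorithms[[network@nodes[[d$node]]$algorithm]]
          writeDensitySnapshot(ds, alg$grid,
            file.path(outDir, sprintf("%s_%g.density", d$node, tNow)))
        }
      }
    }
  }

  rates <- if (length(rateRecs)) {
    do.call(rbind, lapply(seq_along(rateRecs), function(k)
      data.frame(time = recTimes[[k]], node = rateRecs[[k]]$node,
                 activity = recVals[[k]])))
  } else data.frame(time = numeric(0), node = character(0),
                    activity = numeric(0))

  if (!is.null(outDir)) {
    for (k in seq_along(rateRecs))
      writeRateRecord(recTimes[[k]], recVals[[k]],
        file.path(outDir, paste0(rateRecs[[k]]$node, ".rate")))
    writeLines(log, file.path(outDir, rp$nameLog))
  }

  list(rates = rates, densities = densities, network = network,
       log = log, conservationError = conservationError(network))
}
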