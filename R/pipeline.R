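#' Full-run configuration
#'
#' Bundles every module's parameter block plus lattice geometry, scenario
#' and seed.  `scenario` "NORMAL" (alias "D0": irradiation of normal tissue
#' with no tumor) or one of the tumor stages "D12".."D20", which are
#' reached by growing the tumor to the corresponding volume-fraction
#' milestone.
#'
#' @slot dims,voxelSize lattice geometry.
#' @slot scenario one of NORMAL, D0, D12, D14, D16, D18, D20.
#' @slot seed RNG seed (mandatory: every stochastic stage draws from R's
#'   stream).
#' @slot vessel,vegf,ham,tumor,oxygen,beams,doseResponse,thresholds module
#'   parameter blocks.
#' @slot remodelMcs,preEquilMcs,postMcs stage iteration budgets.
#' @slot postDt seconds represented by one post-irradiation step (the slow
#'   oxygenation decline after MRT runs over tens of minutes, so the post
#'   phase uses a coarser time step than the Potts-coupled stages).
#' @slot irradiationTime label (minutes) of the irradiation time point.
#' @slot normalDensity,normalCellVolume normal-tissue seeding.
#' @export
setClass("RunConfig",
  representation(dims = "integer", voxelSize = "numeric",
                 scenario = "character", seed = "integer",
                 vessel = "VesselNetworkParams", vegf = "VEGFParams",
                 ham = "HamiltonianParams", tumor = "TumorGrowthParams",
                 oxygen = "OxygenParams", beams = "BeamSpec",
                 doseResponse = "DoseResponseTable",
                 thresholds = "OutcomeThresholds",
                 remodelMcs = "integer", preEquilMcs = "integer",
                 postMcs = "integer", postDt = "numeric",
                 irradiationTime = "numeric",
                 normalDensity = "numeric", normalCellVolume = "numeric"))

setValidity("RunConfig", function(object) {
  if (!object@scenario %in% c("NORMAL", "D0", "D12", "D14", "D16", "D18",
                              "D20"))
    return("unknown scenario")
  TRUE
})

#' @describeIn RunConfig-class constructor.  `scale = "desk"` configures a
#'   64^3 lattice with compressed iteration budgets; `"tiny"` a 48^3
#'   lattice for smoke runs; `"full"` the 117^3 (0.7 mm at 6 um) lattice.
#' @param scenario,seed see slots.
#' @param scale one of "desk", "tiny", "full".
#' @param ... slot overrides.
#' @export
simulationConfig <- function(scenario = "NORMAL", seed = 1L,
                             scale = c("desk", "tiny", "full"), ...) {
  scale <- match.arg(scale)
  dims <- switch(scale, desk = rep(64L, 3), tiny = rep(48L, 3),
                 full = rep(117L, 3))
  budgets <- switch(scale,
                    desk = c(remodel = 60L, pre = 350L, post = 400L),
                    tiny = c(remodel = 40L, pre = 300L, post = 300L),
                    full = c(remodel = 250L, pre = 900L, post = 900L))
  growthRate <- switch(scale, full = 6.75, 67.5) # compressed stage clock
  args <- list(dims = dims, voxelSize = 6, scenario = scenario,
               seed = as.integer(seed), vessel = vesselNetworkParams(),
               vegf = vegfParams(),
               ham = remodelingParams(),
               tumor = tumorGrowthParams(maxGrowthRate = growthRate),
               oxygen = oxygenParams(
                 secondsPerMcs = if (scale == "full") 1 else 2),
               beams = beamSpec(),
               doseResponse = defaultDoseResponse(),
               thresholds = outcomeThresholds(),
               remodelMcs = unname(budgets["remodel"]),
               preEquilMcs = unname(budgets["pre"]),
               postMcs = unname(budgets["post"]), postDt = 5,
               irradiationTime = 30, normalDensity = 127870,
               normalCellVolume = 1944)
  over <- list(...)
  args[names(over)] <- over
  do.call(new, c("RunConfig", args))
}

# body-cell outcome fractions relative to a fixed initial population
.outcomeFractions <- function(lattice, nInitial, nRadiationDead) {
  cells <- lattice@cells
  body <- cells[cells$type %in% c("NORMAL", "TUMOR"), , drop = FALSE]
  nec <- sum(body$alive & body$oxygenState == "NECROTIC")
  hyp <- sum(body$alive & body$oxygenState == "HYPOXIC")
  nor <- sum(body$alive & body$oxygenState == "NORMOXIC")
  c(normoxic = nor / nInitial, hypoxic = hyp / nInitial,
    necrotic = nec / nInitial, radiationDead = nRadiationDead / nInitial,
    totalDead = (nec + nRadiationDead) / nInitial)
}

#' Run a full scenario (vasculature to outcome metrics)
#'
#' Stages, in order: synthetic vasculature (generate, cluster, remodel);
#' normal-tissue seeding; tumor growth to the scenario stage (tumor
#' scenarios only); donor/acceptor placement; oxygen pre-equilibration;
#' MRT irradiation (parametric dose, stochastic vascular deaths, beam-path
#' ablation); post-irradiation oxygen evolution with per-MCS oxygenation
#' classification; outcome metrics.
#'
#' @param config a [simulationConfig()].
#' @param outDir optional directory for the metrics CSV, reports and
#'   manifest.
#' @return list with `series` (the outcome time series), `metrics`
#'   (scalar summary), `lattice`, `reports` (vascular-death and ablation
#'   tables) and `manifest`.
#' @export
runScenario <- function(config, outDir = NULL) {
  validObject(config)
  set.seed(config@seed)
  thr <- config@thresholds
  oxy <- config@oxygen

  lattice <- generateCapillaryNetwork(config@vessel, config@dims,
                                      config@voxelSize)
  lattice <- clusterVascularCells(lattice)
  lattice <- remodelVasculature(lattice, config@vegf, config@ham,
                                nMcs = config@remodelMcs)
  lattice <- seedNormalTissue(lattice, config@normalDensity,
                              config@normalCellVolume)

  scenario <- config@scenario
  if (!scenario %in% c("NORMAL", "D0")) {
    lattice <- seedTumor(lattice, config@tumor)
    stageFrac <- config@tumor@stageFractions[scenario]
    if (is.na(stageFrac)) stop("no stage fraction for ", scenario)
    gr <- growToStage(lattice, config@tumor, oxy,
                      stages = c(stageFrac), maxMcs = 5000L)
    lattice <- gr$lattice
  }
  lattice <- placeDonorsAcceptors(lattice, oxy)

  refUniformity <- uniformityStatistic(lattice)

  eq <- equilibrateOxygen(lattice, oxy, maxMcs = config@preEquilMcs)
  vasc <- eq$vascular
  cellField <- eq$cellular
  cl <- classifyCells(lattice, cellField, thr)
  lattice <- cl$lattice

  body0 <- sum(lattice@cells$type %in% c("NORMAL", "TUMOR") &
                 lattice@cells$alive)
  vascFracPre <- vascularFraction(lattice)
  preMean <- mean(cellField@grid)
  preSD <- sd(as.vector(cellField@grid))
  preUnperfused <- unperfusedFraction(lattice, vasc, thr)

  series <- data.frame(mcs = 0L, phase = "pre", meanPO2 = preMean,
                       sdPO2 = preSD,
                       t(.outcomeFractions(lattice, body0, 0L)),
                       unperfused = preUnperfused)

  # irradiation
  dose <- buildParametricDose(config@beams, config@dims, config@voxelSize)
  md <- meanDosePerCell(dose, lattice)
  vd <- applyVascularDeaths(lattice, md, config@doseResponse)
  lattice <- vd$lattice
  ab <- ablateBeamPathCells(lattice, config@beams)
  lattice <- ab$lattice
  nRadDead <- sum(ab$report$removed)

  for (mcs in seq_len(config@postMcs)) {
    st <- stepOxygen(lattice, vasc, cellField, oxy, dt = config@postDt)
    vasc <- st$vascular
    cellField <- st$cellular
    cl <- classifyCells(lattice, cellField, thr)
    lattice <- cl$lattice
    if (mcs %% 10L == 0L || mcs == config@postMcs)
      series <- rbind(series, data.frame(
        mcs = mcs, phase = "post", meanPO2 = mean(cellField@grid),
        sdPO2 = sd(as.vector(cellField@grid)),
        t(.outcomeFractions(lattice, body0, nRadDead)),
        unperfused = unperfusedFraction(lattice, vasc, thr)))
  }

  postMean <- mean(cellField@grid)
  metrics <- list(
    scenario = scenario, seed = config@seed,
    vascularFractionPre = vascFracPre,
    vascularFractionPost = vascularFraction(lattice),
    uniformitySD = refUniformity$sd,
    equilibrationMcs = eq$mcs, equilibrationConverged = eq$converged,
    meanPO2Pre = preMean, meanPO2Post = postMean,
    depletion = (preMean - postMean) / preMean,
    unperfusedPre = preUnperfused,
    unperfusedPost = unperfusedFraction(lattice, vasc, thr),
    vascularDeathFraction = mean(vd$report$died),
    ablatedFraction = mean(ab$report$removed),
    fractions = .outcomeFractions(lattice, body0, nRadDead))
  manifest <- list(package = "mrtvasc",
                   version = as.character(utils::packageVersion("mrtvasc")),
                   scenario = scenario, seed = config@seed,
                   dims = config@dims, voxelSize = config@voxelSize,
                   stages = c(remodelMcs = config@remodelMcs,
                              preEquilMcs = config@preEquilMcs,
                              postMcs = config@postMcs),
                   outputs = character(0))
  out <- list(series = series, metrics = metrics, lattice = lattice,
              vascularField = vasc, cellularField = cellField,
              reports = list(vascularDeaths = vd$report,
                             ablation = ab$report),
              manifest = manifest)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(series = file.path(outDir, "outcome_series.csv"),
               deaths = file.path(outDir, "vascular_deaths.csv"),
               ablation = file.path(outDir, "ablation.csv"),
               manifest = file.path(outDir, "manifest.json"))
    write.csv(series, paths["series"], row.names = FALSE)
    write.csv(vd$report, paths["deaths"], row.names = FALSE)
    write.csv(ab$report, paths["ablation"], row.names = FALSE)
    out$manifest$outputs <- unname(paths)
    jsonlite::write_json(out$manifest, paths["manifest"],
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @rdname runScenario
#' @export
runFull <- runScenario

#' Write the single-capillary demonstration trajectory to CSV
#'
#' @param out CSV path; rows are MCS, columns `mcs` plus one column per
#'   capillary cell.
#' @param ... passed to [runCapillaryDemo()].
#' @return the demo result, invisibly.
#' @export
runDemoCapillary <- function(out, ...) {
  demo <- runCapillaryDemo(...)
  df <- data.frame(mcs = demo$time, demo$trajectory)
  names(df) <- c("mcs", sprintf("cell_%02d", seq_len(ncol(demo$trajectory))))
  write.csv(df, out, row.names = FALSE)
  invisible(demo)
}
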