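#' Synthetic capillary-network generation parameters
#'
#' Defaults emulate the mouse-brain cortical angioarchitecture the model is
#' built for: about 14.8% of the lattice volume occupied by capillaries with
#' a minimum diameter of 6 micrometres, spanning the simulation cube.
#'
#' @slot targetVolumeFraction vascular volume fraction to achieve (0-0.5).
#' @slot minCapillaryDiameter micrometres; must be >= the voxel size.
#' @slot nSeedPaths number of face-to-face seed paths laid before the
#'   fraction top-up loop.
#' @slot tortuosity >= 1; expected path length relative to the straight
#'   crossing.
#' @slot branchingRate expected number of branches spawned per seed path.
#' @export
setClass("VesselNetworkParams",
  representation(targetVolumeFraction = "numeric",
                 minCapillaryDiameter = "numeric", nSeedPaths = "integer",
                 tortuosity = "numeric", branchingRate = "numeric"))

setValidity("VesselNetworkParams", function(object) {
  msg <- character()
  if (object@targetVolumeFraction < 0 || object@targetVolumeFraction >= 0.5)
    msg <- c(msg, "targetVolumeFraction must lie in [0, 0.5)")
  if (object@tortuosity < 1) msg <- c(msg, "tortuosity must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn VesselNetworkParams-class constructor with defaults.
#' @param targetVolumeFraction,minCapillaryDiameter,nSeedPaths,tortuosity,branchingRate
#'   see slots.
#' @export
vesselNetworkParams <- function(targetVolumeFraction = 0.148,
                                minCapillaryDiameter = 6,
                                nSeedPaths = 6L, tortuosity = 1.1,
                                branchingRate = 1) {
  new("VesselNetworkParams",
      targetVolumeFraction = targetVolumeFraction,
      minCapillaryDiameter = minCapillaryDiameter,
      nSeedPaths = as.integer(nSeedPaths), tortuosity = tortuosity,
      branchingRate = branchingRate)
}

#' Autocrine VEGF-like chemoattractant parameters
#'
#' Vascular cells secrete the attractant into their own voxels; it diffuses
#' tissue-wide and decays.  Defaults: diffusion 10 micrometre^2/s, decay
#' 0.65 per hour.
#'
#' @slot diffusionCoefficient micrometre^2/s.
#' @slot decayConstant per hour.
#' @slot secretionRate concentration units per MCS added to each secreting
#'   voxel.
#' @export
setClass("VEGFParams",
  representation(diffusionCoefficient = "numeric", decayConstant = "numeric",
                 secretionRate = "numeric"))

setValidity("VEGFParams", function(object) {
  if (object@diffusionCoefficient < 0 || object@decayConstant < 0 ||
      object@secretionRate < 0)
    "all VEGF parameters must be >= 0" else TRUE
})

#' @describeIn VEGFParams-class constructor with defaults.
#' @param diffusionCoefficient,decayConstant,secretionRate see slots.
#' @export
vegfParams <- function(diffusionCoefficient = 10, decayConstant = 0.65,
                       secretionRate = 1) {
  new("VEGFParams", diffusionCoefficient = diffusionCoefficient,
      decayConstant = decayConstant, secretionRate = secretionRate)
}

#' Avascular tumor growth parameters
#'
#' Tumor cells start at 3375 micrometre^3, grow at a Michaelis-Menten rate
#' in their mean cellular pO2, and divide on reaching twice the initial
#' volume.
#'
#' @slot initialCellVolume micrometre^3.
#' @slot divisionVolume micrometre^3 (twice the initial volume).
#' @slot maxGrowthRate micrometre^3 per MCS at oxygen saturation.
#' @slot growthKm Michaelis-Menten half-saturation, mmHg.
#' @slot stageFractions tumor volume fractions (of the lattice) at which the
#'   staged snapshots D12..D20 are taken.
#' @slot mcsPerDay nominal MCS-per-day mapping for time labeling.
#' @export
setClass("TumorGrowthParams",
  representation(initialCellVolume = "numeric", divisionVolume = "numeric",
                 maxGrowthRate = "numeric", growthKm = "numeric",
                 stageFractions = "numeric", mcsPerDay = "numeric"))

setValidity("TumorGrowthParams", function(object) {
  msg <- character()
  if (!isTRUE(all.equal(object@divisionVolume,
                        2 * object@initialCellVolume)))
    msg <- c(msg, "divisionVolume must equal 2 * initialCellVolume")
  if (object@maxGrowthRate < 0 || object@growthKm < 0)
    msg <- c(msg, "rates must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn TumorGrowthParams-class constructor with defaults.  The stage
#'   fractions are the tumor volume fractions observed at days 12-20 of
#'   growth; staging by geometry rather than wall-clock lets scaled-down runs
#'   reach the same morphological stages.
#' @param initialCellVolume,divisionVolume,maxGrowthRate,growthKm,stageFractions,mcsPerDay
#'   see slots.
#' @export
tumorGrowthParams <- function(initialCellVolume = 3375,
                              divisionVolume = 6750,
                              maxGrowthRate = 6.75, growthKm = 5,
                              stageFractions = c(D12 = 0.055, D14 = 0.135,
                                                 D16 = 0.276, D18 = 0.465,
                                                 D20 = 0.565),
                              mcsPerDay = 500) {
  new("TumorGrowthParams", initialCellVolume = initialCellVolume,
      divisionVolume = divisionVolume, maxGrowthRate = maxGrowthRate,
      growthKm = growthKm, stageFractions = stageFractions,
      mcsPerDay = mcsPerDay)
}

#' Oxygen transport parameters
#'
#' Donor boundaries clamp vascular pO2 at arterial level (90 mmHg),
#' acceptors at 0.  Cellular pO2 diffuses at 2000 micrometre^2/s through
#' bulk tissue; each cell consumes oxygen at a Michaelis-Menten rate with a
#' maximum of 0.6 mmHg/s (tumor cells ten-fold higher).
#'
#' @slot donorPO2,acceptorPO2 clamped boundary values, mmHg.
#' @slot tissueDiffusion,vascularDiffusion micrometre^2/s.
#' @slot maxUptakePerCell mmHg/s for normal cells.
#' @slot tumorUptakeMultiplier dimensionless (>= 1).
#' @slot uptakeKm Michaelis-Menten half-saturation of uptake, mmHg.
#' @slot secondsPerMcs physical seconds represented by one MCS.
#' @export
setClass("OxygenParams",
  representation(donorPO2 = "numeric", acceptorPO2 = "numeric",
                 tissueDiffusion = "numeric", vascularDiffusion = "numeric",
                 maxUptakePerCell = "numeric",
                 tumorUptakeMultiplier = "numeric", uptakeKm = "numeric",
                 secondsPerMcs = "numeric"))

setValidity("OxygenParams", function(object) {
  msg <- character()
  vals <- c(object@donorPO2, object@acceptorPO2, object@tissueDiffusion,
            object@vascularDiffusion, object@maxUptakePerCell,
            object@uptakeKm, object@secondsPerMcs)
  if (any(vals < 0)) msg <- c(msg, "all oxygen parameters must be >= 0")
  if (object@tumorUptakeMultiplier < 1)
    msg <- c(msg, "tumorUptakeMultiplier must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn OxygenParams-class constructor with defaults.
#' @param donorPO2,acceptorPO2,tissueDiffusion,vascularDiffusion,maxUptakePerCell,tumorUptakeMultiplier,uptakeKm,secondsPerMcs
#'   see slots.
#' @export
oxygenParams <- function(donorPO2 = 90, acceptorPO2 = 0,
                         tissueDiffusion = 2000, vascularDiffusion = 4000,
                         maxUptakePerCell = 0.6, tumorUptakeMultiplier = 10,
                         uptakeKm = 1, secondsPerMcs = 1) {
  new("OxygenParams", donorPO2 = donorPO2, acceptorPO2 = acceptorPO2,
      tissueDiffusion = tissueDiffusion,
      vascularDiffusion = vascularDiffusion,
      maxUptakePerCell = maxUptakePerCell,
      tumorUptakeMultiplier = tumorUptakeMultiplier, uptakeKm = uptakeKm,
      secondsPerMcs = secondsPerMcs)
}

#' Oxygenation outcome thresholds
#'
#' Cells below 5 mmHg are hypoxic (reversible), below 1 mmHg necrotic
#' (absorbing).  A surviving vascular cell whose vascular pO2 falls below
#' `unperfusedPO2` counts as unperfused.
#'
#' @slot hypoxiaPO2,necrosisPO2,unperfusedPO2 mmHg.
#' @export
setClass("OutcomeThresholds",
  representation(hypoxiaPO2 = "numeric", necrosisPO2 = "numeric",
                 unperfusedPO2 = "numeric"))

setValidity("OutcomeThresholds", function(object) {
  if (object@necrosisPO2 >= object@hypoxiaPO2)
    "necrosisPO2 must be below hypoxiaPO2" else TRUE
})

#' @describeIn OutcomeThresholds-class constructor with defaults.
#' @param hypoxiaPO2,necrosisPO2,unperfusedPO2 see slots.
#' @export
outcomeThresholds <- function(hypoxiaPO2 = 5, necrosisPO2 = 1,
                              unperfusedPO2 = 1) {
  new("OutcomeThresholds", hypoxiaPO2 = hypoxiaPO2,
      necrosisPO2 = necrosisPO2, unperfusedPO2 = unperfusedPO2)
}
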