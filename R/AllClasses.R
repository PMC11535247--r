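#' VoxelLattice: voxel-to-cell map with a cell registry
#'
#' The central container of the package.  `grid` is a 3-D integer array
#' mapping each voxel to a cell identifier (0 = medium).  The registry
#' `cells` holds one row per biological cell with its type, target volume
#' (voxels), target major-axis length (voxels; vascular cells only),
#' oxygenation state and cached shape statistics.  Donor/acceptor perfusion
#' boundaries live in `boundary` as a virtual clamped layer outside the
#' lattice (they occupy no grid voxels).
#'
#' Voxel indices exposed in the API are 0-based linear indices in
#' column-major (x fastest) order, matching the compiled kernel.
#'
#' @slot grid integer 3-D array of cell identifiers, 0 = medium.
#' @slot voxelSize voxel edge length in micrometres (default 6).
#' @slot periodic logical length-3, per-axis periodicity of the lattice.
#' @slot cells data.frame registry: id, type, targetVolume (voxels),
#'   targetAxis (voxels), oxygenState, alive, volume, axisLength, cx, cy, cz
#'   (centroids in voxel coordinates).
#' @slot boundary list with data.frames `donor` and `acceptor` (columns id,
#'   voxel, value): lattice-face vascular voxels that exchange with a clamped
#'   ghost neighbor.
#' @export
setClass("VoxelLattice",
  representation(grid = "array", voxelSize = "numeric", periodic = "logical",
                 cells = "data.frame", boundary = "list"),
  prototype(voxelSize = 6, periodic = c(FALSE, FALSE, FALSE),
            boundary = list()))

setValidity("VoxelLattice", function(object) {
  msg <- character()
  if (length(dim(object@grid)) != 3L)
    msg <- c(msg, "grid must be a 3-D array")
  if (!is.integer(object@grid))
    msg <- c(msg, "grid must be integer")
  if (length(object@periodic) != 3L)
    msg <- c(msg, "periodic must have length 3")
  if (length(object@voxelSize) != 1L || object@voxelSize <= 0)
    msg <- c(msg, "voxelSize must be a positive scalar")
  cells <- object@cells
  if (nrow(cells)) {
    if (anyDuplicated(cells$id)) msg <- c(msg, "duplicate cell ids")
    if (any(cells$id <= 0)) msg <- c(msg, "cell ids must be positive")
    if (!all(cells$type %in% .TYPE_NAMES))
      msg <- c(msg, "unknown cell types in registry")
  }
  ids <- unique(object@grid[object@grid > 0L])
  if (length(ids) && !all(ids %in% cells$id))
    msg <- c(msg, "grid contains identifiers absent from the registry")
  if (length(msg)) msg else TRUE
})

#' Potts (GGH) Hamiltonian parameters
#'
#' Contact energies `J` are indexed by the six cell types (medium, vascular,
#' normal, tumor, donor, acceptor).  The energy change of a voxel copy is
#' \deqn{\Delta H = \Delta J + \lambda_{vol}\Delta(v - V_t)^2 +
#'   \lambda_{len}\Delta(\ell - L_t)^2 - \mu\,(f(src) - f(tgt))}
#' with the elongation term restricted to cells carrying a target major-axis
#' length and the chemotaxis term active only when a field is supplied.
#'
#' @slot J symmetric 6x6 numeric matrix of type-pair contact energies.
#' @slot lambdaVolume volume-constraint stiffness (>= 0).
#' @slot lambdaLength elongation-constraint stiffness (>= 0).
#' @slot chemotaxisMu chemotaxis strength (sign: positive favors copies whose
#'   source voxel sits higher in the field than the target voxel).
#' @slot temperature Metropolis temperature (>= 0; 0 accepts only
#'   non-positive energy changes).
#' @slot neighborhood "moore" (26) or "vonneumann" (6) for both adhesion and
#'   copy-attempt neighborhoods.
#' @slot frozenTypes cell types excluded from copy attempts.
#' @slot connectivity reject retractions that would split a cell within the
#'   26-voxel shell of the lost voxel (local connectivity constraint; keeps
#'   cells contiguous).
#' @export
setClass("HamiltonianParams",
  representation(J = "matrix", lambdaVolume = "numeric",
                 lambdaLength = "numeric", chemotaxisMu = "numeric",
                 temperature = "numeric", neighborhood = "character",
                 frozenTypes = "character", connectivity = "logical"))

setValidity("HamiltonianParams", function(object) {
  msg <- character()
  if (!all(dim(object@J) == c(6L, 6L))) msg <- c(msg, "J must be 6x6")
  else if (!isTRUE(all.equal(object@J, t(object@J))))
    msg <- c(msg, "J must be symmetric")
  if (object@lambdaVolume < 0 || object@lambdaLength < 0 ||
      object@temperature < 0)
    msg <- c(msg, "lambdaVolume, lambdaLength, temperature must be >= 0")
  if (!object@neighborhood %in% c("moore", "vonneumann"))
    msg <- c(msg, "neighborhood must be 'moore' or 'vonneumann'")
  if (length(msg)) msg else TRUE
})

#' Scalar concentration field on the lattice geometry
#'
#' @slot name one of "VASCULAR_PO2", "CELLULAR_PO2", "VEGF".
#' @slot grid numeric 3-D array of concentrations (mmHg or a.u.).
#' @slot diffusionByType named numeric, cell type -> diffusion coefficient
#'   (micrometre^2/s); types absent from the map do not conduct the field.
#' @slot decay first-order decay constant (1/s).
#' @slot boundary "periodic" or "clamped_cells" (donor/acceptor ghosts).
#' @export
setClass("ChemField",
  representation(name = "character", grid = "array",
                 diffusionByType = "numeric", decay = "numeric",
                 boundary = "character"))

setValidity("ChemField", function(object) {
  msg <- character()
  if (!object@name %in% c("VASCULAR_PO2", "CELLULAR_PO2", "VEGF"))
    msg <- c(msg, "unknown field name")
  if (length(dim(object@grid)) != 3L) msg <- c(msg, "grid must be 3-D")
  if (any(object@grid < 0)) msg <- c(msg, "concentrations must be >= 0")
  if (object@decay < 0) msg <- c(msg, "decay must be >= 0")
  if (!object@boundary %in% c("periodic", "clamped_cells"))
    msg <- c(msg, "boundary must be 'periodic' or 'clamped_cells'")
  if (length(msg)) msg else TRUE
})

#' Per-voxel absorbed dose on the lattice geometry
#' @slot grid numeric 3-D array, Gy.
#' @slot voxelSize voxel edge length, micrometres.
#' @export
setClass("DoseGrid",
  representation(grid = "array", voxelSize = "numeric"))

setValidity("DoseGrid", function(object) {
  msg <- character()
  if (length(dim(object@grid)) != 3L) msg <- c(msg, "grid must be 3-D")
  if (any(object@grid < 0)) msg <- c(msg, "doses must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Microbeam array geometry and dose normalization
#'
#' Defaults describe three planar 50-micrometre microbeams at 200
#' micrometre center-to-center spacing, normalized to a 350 Gy peak and a
#' 6 Gy valley at mid-spacing.
#'
#' @slot nBeams number of planar microbeams.
#' @slot fwhm lateral full width at half maximum of one beamlet, micrometres.
#' @slot ctc center-to-center spacing, micrometres.
#' @slot beamLength beam extent along its long axis, micrometres.
#' @slot peakDose,valleyDose normalization doses, Gy.
#' @slot penumbraSigma Gaussian penumbra width, micrometres.
#' @slot lateralAxis axis (1, 2 or 3) across which the peak/valley profile
#'   runs.
#' @slot depthInWater scoring depth metadata, millimetres.
#' @export
setClass("BeamSpec",
  representation(nBeams = "integer", fwhm = "numeric", ctc = "numeric",
                 beamLength = "numeric", peakDose = "numeric",
                 valleyDose = "numeric", penumbraSigma = "numeric",
                 lateralAxis = "integer", depthInWater = "numeric"))

setValidity("BeamSpec", function(object) {
  msg <- character()
  if (object@ctc <= object@fwhm) msg <- c(msg, "ctc must exceed fwhm")
  if (object@peakDose <= object@valleyDose || object@valleyDose < 0)
    msg <- c(msg, "need peakDose > valleyDose >= 0")
  if (!object@lateralAxis %in% 1:3) msg <- c(msg, "lateralAxis must be 1..3")
  if (object@penumbraSigma * 2 * sqrt(2 * log(2)) >= object@fwhm)
    msg <- c(msg, "penumbraSigma too large for the requested fwhm")
  if (length(msg)) msg else TRUE
})

#' Endothelial apoptosis dose-response table
#'
#' (dose, death probability) support points with linear interpolation inside
#' the measured range and linear extrapolation through the two highest
#' points beyond it, clamped to [0, 1].
#'
#' @slot dose strictly increasing doses starting at 0, Gy.
#' @slot probability non-decreasing death probabilities in [0, 1].
#' @slot maxMeasuredDose upper end of the measured range, Gy.
#' @export
setClass("DoseResponseTable",
  representation(dose = "numeric", probability = "numeric",
                 maxMeasuredDose = "numeric"))

setValidity("DoseResponseTable", function(object) {
  msg <- character()
  if (length(object@dose) != length(object@probability) ||
      length(object@dose) < 2L)
    msg <- c(msg, "need >= 2 (dose, probability) points")
  else {
    if (object@dose[1] != 0) msg <- c(msg, "doses must start at 0")
    if (any(diff(object@dose) <= 0))
      msg <- c(msg, "doses must be strictly increasing")
    if (any(object@probability < 0) || any(object@probability > 1))
      msg <- c(msg, "probabilities must lie in [0, 1]")
    if (any(diff(object@probability) < 0))
      msg <- c(msg, "probabilities must be non-decreasing")
  }
  if (length(msg)) msg else TRUE
})
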