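#' Construct Potts Hamiltonian parameters
#'
#' Default contact energies favor cohesion of like cell types, with medium
#' contact moderately penalized; they are calibration values exposed for
#' configuration, as is usual for GGH models, and are documented in the
#' methods vignette.
#'
#' @param J symmetric 6x6 contact-energy matrix ordered as
#'   (MEDIUM, VASCULAR, NORMAL, TUMOR, DONOR, ACCEPTOR).
#' @param lambdaVolume,lambdaLength,chemotaxisMu,temperature,neighborhood,frozenTypes,connectivity
#'   see [HamiltonianParams-class].
#' @return a [HamiltonianParams-class] object.
#' @export
hamiltonianParams <- function(J = NULL, lambdaVolume = 2,
                              lambdaLength = 0.5, chemotaxisMu = 0,
                              temperature = 10,
                              neighborhood = c("moore", "vonneumann"),
                              frozenTypes = c("DONOR", "ACCEPTOR"),
                              connectivity = TRUE) {
  if (is.null(J)) {
    J <- matrix(0, 6, 6, dimnames = list(.TYPE_NAMES, .TYPE_NAMES))
    set <- function(a, b, v) {
      J[a, b] <<- v
      J[b, a] <<- v
    }
    set("MEDIUM", "MEDIUM", 0)
    set("VASCULAR", "MEDIUM", 8)
    set("VASCULAR", "VASCULAR", 4)
    set("VASCULAR", "NORMAL", 10)
    set("VASCULAR", "TUMOR", 12)
    set("NORMAL", "MEDIUM", 8)
    set("NORMAL", "NORMAL", 6)
    set("NORMAL", "TUMOR", 9)
    set("TUMOR", "MEDIUM", 12)
    set("TUMOR", "TUMOR", 4)
    # boundary devices are frozen; mirror vascular contact energies
    for (tt in c("DONOR", "ACCEPTOR")) {
      J[tt, ] <- J["VASCULAR", ]
      J[, tt] <- J[, "VASCULAR"]
    }
    J["DONOR", "ACCEPTOR"] <- J["ACCEPTOR", "DONOR"] <- J["VASCULAR",
                                                          "VASCULAR"]
    J["DONOR", "DONOR"] <- J["ACCEPTOR", "ACCEPTOR"] <- J["VASCULAR",
                                                          "VASCULAR"]
  }
  new("HamiltonianParams", J = J, lambdaVolume = lambdaVolume,
      lambdaLength = lambdaLength, chemotaxisMu = chemotaxisMu,
      temperature = temperature,
      neighborhood = match.arg(neighborhood), frozenTypes = frozenTypes,
      connectivity = connectivity)
}

# assemble the per-identifier vectors the compiled kernel expects
.kernelArgs <- function(lattice, params, field = NULL) {
  cells <- lattice@cells
  maxId <- if (nrow(cells)) max(cells$id) else 0L
  typeVec <- integer(maxId + 1L)
  tv <- numeric(maxId + 1L)
  ta <- numeric(maxId + 1L)
  fr <- logical(maxId + 1L)
  if (nrow(cells)) {
    typeVec[cells$id + 1L] <- typeCode(cells$type)
    tv[cells$id + 1L] <- cells$targetVolume
    ta[cells$id + 1L] <- ifelse(is.na(cells$targetAxis), 0,
                                cells$targetAxis)
    fr[cells$id + 1L] <- cells$type %in% params@frozenTypes | !cells$alive
  }
  f <- if (is.null(field)) numeric(0)
       else if (is(field, "ChemField")) as.vector(field@grid)
       else as.vector(field)
  list(grid = as.vector(lattice@grid), dims = dim(lattice@grid),
       periodic = lattice@periodic, type = typeVec, targetVol = tv,
       targetAxis = ta, frozen = fr, J = params@J,
       lambdaVol = params@lambdaVolume, lambdaLen = params@lambdaLength,
       mu = params@chemotaxisMu, temperature = params@temperature,
       nbhd = if (params@neighborhood == "moore") 26L else 6L, field = f,
       connectivity = params@connectivity)
}

.checkAdjacent <- function(lattice, source, target, params) {
  n <- length(lattice@grid)
  if (source < 0 || source >= n || target < 0 || target >= n)
    stop("voxel index out of range")
  d <- dim(lattice@grid)
  a <- voxelCoords(lattice, source)[1, ]
  b <- voxelCoords(lattice, target)[1, ]
  delta <- abs(a - b)
  wrap <- lattice@periodic & (delta == d - 1L)
  delta[wrap] <- 1L
  maxd <- if (params@neighborhood == "moore") 1L else NA
  ok <- if (params@neighborhood == "moore") all(delta <= 1L)
        else sum(delta) == 1L
  if (!ok || all(delta == 0L)) stop("voxels are not lattice-adjacent")
  invisible(TRUE)
}

#' Incremental energy change of a voxel copy
#'
#' Energy change of re-labeling `target` with the cell occupying `source`,
#' combining adhesion, volume-constraint, elongation-constraint and
#' chemotaxis terms.  The incremental value equals the difference of full
#' Hamiltonian recomputations (chemotaxis excepted, which is a work term on
#' the move rather than a state energy).
#'
#' @param lattice a VoxelLattice.
#' @param source,target 0-based linear voxel indices; must be
#'   lattice-adjacent under the configured neighborhood.
#' @param params a [HamiltonianParams-class].
#' @param field optional chemotaxis [ChemField-class] (or bare array).
#' @return scalar energy change.
#' @export
deltaHamiltonian <- function(lattice, source, target, params,
                             field = NULL) {
  .checkAdjacent(lattice, source, target, params)
  a <- .kernelArgs(lattice, params, field)
  cpm_delta_h(a$grid, a$dims, a$periodic, a$type, a$targetVol, a$targetAxis,
              a$frozen, a$J, a$lambdaVol, a$lambdaLen, a$mu, a$temperature,
              a$nbhd, a$field, source, target)
}

#' Metropolis voxel-copy attempt
#'
#' Accepts the copy with probability `min(1, exp(-dH/T))`; at `T = 0` all
#' non-positive energy changes are accepted and all positive ones rejected.
#' Uses R's RNG stream, so results are reproducible under `set.seed()`.
#'
#' @inheritParams deltaHamiltonian
#' @return list with `accepted`, `deltaH` and the updated `lattice`.
#' @export
attemptCopy <- function(lattice, source, target, params, field = NULL) {
  .checkAdjacent(lattice, source, target, params)
  a <- .kernelArgs(lattice, params, field)
  res <- cpm_attempt_copy(a$grid, a$dims, a$periodic, a$type, a$targetVol,
                          a$targetAxis, a$frozen, a$J, a$lambdaVol,
                          a$lambdaLen, a$mu, a$temperature, a$nbhd, a$field,
                          a$connectivity, source, target)
  if (res$accepted) {
    lattice@grid <- array(res$grid, dim(lattice@grid))
    lattice <- syncRegistry(lattice)
  }
  list(accepted = res$accepted, deltaH = res$deltaH, lattice = lattice)
}

#' Run Monte-Carlo steps of the Potts dynamics
#'
#' One MCS performs as many random voxel-copy attempts as there are lattice
#' voxels.  Donor/acceptor boundary devices (and any configured frozen
#' types) never take part.  Cells shrunk to zero voxels are removed from
#' the registry.
#'
#' @inheritParams deltaHamiltonian
#' @param nSteps number of Monte-Carlo steps.
#' @return the updated VoxelLattice (attribute `mcsStats` carries attempt
#'   and acceptance counts).
#' @export
runMCS <- function(lattice, params, nSteps, field = NULL) {
  nSteps <- as.integer(nSteps)
  if (nSteps <= 0L) return(lattice)
  a <- .kernelArgs(lattice, params, field)
  res <- cpm_run_mcs(a$grid, a$dims, a$periodic, a$type, a$targetVol,
                     a$targetAxis, a$frozen, a$J, a$lambdaVol, a$lambdaLen,
                     a$mu, a$temperature, a$nbhd, a$field, a$connectivity,
                     nSteps)
  lattice@grid <- array(res$grid, dim(lattice@grid))
  lattice <- syncRegistry(lattice, drop = TRUE)
  attr(lattice, "mcsStats") <- list(attempts = res$attempts,
                                    accepted = res$accepted)
  lattice
}
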