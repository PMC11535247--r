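#' Construct a concentration field on a lattice geometry
#'
#' @param name "VASCULAR_PO2", "CELLULAR_PO2" or "VEGF".
#' @param lattice the VoxelLattice supplying the geometry.
#' @param diffusionByType named numeric map, cell type -> diffusion
#'   coefficient (micrometre^2/s); omitted types do not conduct the field.
#' @param decay first-order decay constant, 1/s.
#' @param boundary "periodic" or "clamped_cells".
#' @param init initial concentration (scalar or array).
#' @return a [ChemField-class].
#' @export
newChemField <- function(name, lattice, diffusionByType, decay = 0,
                         boundary = c("periodic", "clamped_cells"),
                         init = 0) {
  g <- array(0, dim(lattice@grid))
  g[] <- init
  new("ChemField", name = name, grid = g,
      diffusionByType = diffusionByType, decay = decay,
      boundary = match.arg(boundary))
}

# 0-based linear indices of voxels belonging to live vascular cells
.vascularVoxels <- function(lattice) {
  cells <- lattice@cells
  ids <- cells$id[cells$type == "VASCULAR" & cells$alive]
  if (!length(ids)) return(integer(0))
  which(lattice@grid %in% ids) - 1L
}

#' Attach donor/acceptor perfusion boundaries
#'
#' For every vascular voxel touching the three low lattice faces a donor
#' cell is appended just outside the lattice (a virtual clamped ghost at the
#' arterial pO2); the three opposite faces receive acceptor cells clamped at
#' the drainage value.  Donors and acceptors are registered as immobile
#' boundary devices and never take part in Potts dynamics.
#'
#' @param lattice a VoxelLattice with vascular cells.
#' @param params an [oxygenParams()].
#' @return the lattice with its `boundary` slot and registry extended.
#' @export
placeDonorsAcceptors <- function(lattice, params = oxygenParams()) {
  d <- dim(lattice@grid)
  vox0 <- .vascularVoxels(lattice)
  if (!length(vox0)) stop("no vascular voxels on the lattice")
  xyz <- voxelCoords(lattice, vox0)
  donorVox <- vox0[xyz[, 1] == 0L | xyz[, 2] == 0L | xyz[, 3] == 0L]
  accVox <- vox0[xyz[, 1] == d[1] - 1L | xyz[, 2] == d[2] - 1L |
                   xyz[, 3] == d[3] - 1L]
  if (!length(donorVox))
    stop("no vascular voxel touches a donor face: network not spanning")
  if (!length(accVox))
    stop("no vascular voxel touches an acceptor face: network not spanning")
  cells <- lattice@cells[!lattice@cells$type %in% c("DONOR", "ACCEPTOR"), ,
                         drop = FALSE]
  lattice@cells <- cells
  nextId <- if (nrow(cells)) max(cells$id) + 1L else 1L
  dIds <- nextId + seq_along(donorVox) - 1L
  aIds <- nextId + length(donorVox) + seq_along(accVox) - 1L
  mk <- function(ids, type) {
    data.frame(id = as.integer(ids), type = type, targetVolume = 1,
               targetAxis = 0, oxygenState = "NORMOXIC", alive = TRUE,
               volume = 1, axisLength = NA_real_, cx = NA_real_,
               cy = NA_real_, cz = NA_real_, stringsAsFactors = FALSE)
  }
  lattice@cells <- rbind(cells, mk(dIds, "DONOR"), mk(aIds, "ACCEPTOR"))
  lattice@boundary <- list(
    donor = data.frame(id = dIds, voxel = donorVox,
                       value = params@donorPO2),
    acceptor = data.frame(id = aIds, voxel = accVox,
                          value = params@acceptorPO2))
  lattice
}

#' Step the vascular pO2 field
#'
#' Explicit diffusion restricted to faces between two vascular voxels, with
#' clamped donor/acceptor ghost exchange on the lattice faces, followed by
#' subtraction of the per-voxel leak (the cellular pO2 increase attributable
#' to vascular sourcing, as returned by [stepCellularField()]) and clamping
#' at zero.  Stability is maintained by automatic sub-stepping.
#'
#' @param vasc the vascular [ChemField-class].
#' @param lattice the VoxelLattice (with perfusion boundaries attached).
#' @param params an [oxygenParams()].
#' @param dt step duration, seconds.
#' @param leak numeric vector of per-voxel concentration decreases aligned
#'   with `leakIdx` (both from [stepCellularField()]); optional.
#' @param leakIdx 0-based voxel indices the leak refers to.
#' @return the updated vascular field (zero outside vascular voxels).
#' @export
stepVascularField <- function(vasc, lattice, params, dt, leak = NULL,
                              leakIdx = NULL) {
  d <- dim(lattice@grid)
  vox0 <- .vascularVoxels(lattice)
  cond <- logical(length(lattice@grid))
  cond[vox0 + 1L] <- TRUE
  bd <- lattice@boundary
  donorVox <- if (length(bd)) bd$donor$voxel[cond[bd$donor$voxel + 1L]]
              else integer(0)
  accVox <- if (length(bd)) bd$acceptor$voxel[cond[bd$acceptor$voxel + 1L]]
            else integer(0)
  conc <- diffuse_vascular_cpp(as.vector(vasc@grid), d, cond,
                               params@vascularDiffusion,
                               lattice@voxelSize, dt, donorVox,
                               params@donorPO2, accVox, params@acceptorPO2)
  if (!is.null(leak) && length(leak)) {
    conc[leakIdx + 1L] <- conc[leakIdx + 1L] - leak
    conc[conc < 0] <- 0
  }
  conc[!cond] <- 0
  vasc@grid <- array(conc, d)
  vasc
}

# per-voxel uptake rates (mmHg/s) from the registry and the current field.
# The per-cell maximum (0.6 mmHg/s; tumor ten-fold) is the cell's total
# consumption, distributed over its voxels -- the reading consistent with
# the tens-of-minutes oxygenation timescales of the model.
.uptakeRates <- function(lattice, cellGrid, params) {
  cells <- lattice@cells
  maxId <- if (nrow(cells)) max(cells$id) else 0L
  if (!maxId) return(numeric(0))
  umax <- numeric(maxId)
  consumer <- cells$type %in% c("NORMAL", "TUMOR") & cells$alive &
    cells$oxygenState != "NECROTIC"
  umax[cells$id[consumer & cells$type == "NORMAL"]] <-
    params@maxUptakePerCell
  umax[cells$id[consumer & cells$type == "TUMOR"]] <-
    params@maxUptakePerCell * params@tumorUptakeMultiplier
  if (all(umax == 0)) return(numeric(0))
  cm <- cell_field_means(as.vector(lattice@grid), as.vector(cellGrid),
                         maxId)
  means <- cm$mean
  means[is.na(means) | means < 0] <- 0
  nvox <- pmax(cm$count, 1)
  rateById <- umax * means / (means + params@uptakeKm) / nvox
  rate <- numeric(length(lattice@grid))
  occ <- lattice@grid > 0L
  rate[occ] <- rateById[lattice@grid[occ]]
  rate
}

#' Step the cellular pO2 field
#'
#' Sources the field at vascular voxels from the vascular pO2, diffuses it
#' tissue-wide with periodic wrap on all axes, and applies per-cell
#' Michaelis-Menten uptake uniformly over each consuming cell's voxels
#' (clamped at zero).  The returned leak is the decrease of cellular pO2 in
#' vascular voxels between sourcing and end of step, which
#' [stepVascularField()] debits from the vascular field.
#'
#' @param cellField the cellular [ChemField-class].
#' @param vasc the vascular [ChemField-class] supplying source values.
#' @param lattice the VoxelLattice.
#' @param params an [oxygenParams()].
#' @param dt step duration, seconds.
#' @param clampLeak when TRUE (default) only a positive leak -- a drop of
#'   cellular pO2 at vascular voxels -- is reported, so the tissue never
#'   re-oxygenates a vessel; FALSE reports the signed exchange
#'   (bidirectional coupling, used to initialize equilibria).
#' @return list with `field` (updated cellular field), `leak` and `leakIdx`
#'   (0-based vascular voxel indices the leak aligns with).
#' @export
stepCellularField <- function(cellField, vasc, lattice, params, dt,
                              clampLeak = TRUE) {
  d <- dim(lattice@grid)
  vox0 <- .vascularVoxels(lattice)
  uptake <- .uptakeRates(lattice, cellField@grid, params)
  res <- step_cellular_cpp(as.vector(cellField@grid), d, rep(TRUE, 3L),
                           params@tissueDiffusion, lattice@voxelSize, dt,
                           uptake, cellField@decay, vox0,
                           as.vector(vasc@grid)[vox0 + 1L])
  cellField@grid <- array(res$conc, d)
  # by default only the drop due to diffusion into the tissue is debited
  # from the vascular field: tissue never re-oxygenates a vessel, so
  # severed segments drain monotonically
  leak <- if (clampLeak) pmax(res$leak, 0) else res$leak
  list(field = cellField, leak = leak, leakIdx = vox0)
}

#' One coupled oxygen step (cellular then vascular)
#'
#' @inheritParams stepCellularField
#' @return list with updated `vascular` and `cellular` fields.
#' @export
stepOxygen <- function(lattice, vasc, cellField, params,
                       dt = params@secondsPerMcs, clampLeak = TRUE) {
  res <- stepCellularField(cellField, vasc, lattice, params, dt,
                           clampLeak = clampLeak)
  vasc <- stepVascularField(vasc, lattice, params, dt, leak = res$leak,
                            leakIdx = res$leakIdx)
  list(vascular = vasc, cellular = res$field)
}

#' Initialize and equilibrate the coupled oxygen system
#'
#' Vascular pO2 starts at the donor (arterial) value inside the vasculature;
#' the cellular field starts at zero and the coupled system is stepped until
#' the relative change of the mean cellular pO2 per MCS falls below `tol`.
#'
#' @param lattice a VoxelLattice with perfusion boundaries attached.
#' @param params an [oxygenParams()].
#' @param tol relative-change convergence tolerance per MCS.
#' @param maxMcs iteration cap.
#' @param vasc,cellField optional pre-initialized fields to continue from.
#' @return list with `vascular`, `cellular`, `mcs` (steps used) and
#'   `converged`.
#' @export
equilibrateOxygen <- function(lattice, params = oxygenParams(),
                              tol = 2e-5, maxMcs = 400, vasc = NULL,
                              cellField = NULL) {
  if (is.null(vasc)) {
    vasc <- newChemField("VASCULAR_PO2", lattice,
                         c(VASCULAR = params@vascularDiffusion),
                         boundary = "clamped_cells")
    vox0 <- .vascularVoxels(lattice)
    vasc@grid[vox0 + 1L] <- params@donorPO2
  }
  if (is.null(cellField))
    cellField <- newChemField("CELLULAR_PO2", lattice,
                              c(MEDIUM = params@tissueDiffusion,
                                VASCULAR = params@tissueDiffusion,
                                NORMAL = params@tissueDiffusion,
                                TUMOR = params@tissueDiffusion))
  # phase A: bidirectional vessel/tissue coupling fills the tissue and
  # finds the coupled equilibrium without the one-way drain ratchet, which
  # would otherwise strand poorly supplied vessels during the cold-start
  # transient; phase B settles the directional (drain-only) state
  prev <- mean(cellField@grid)
  mcs <- 0L
  converged <- FALSE
  for (phase in c(FALSE, TRUE)) {
    phaseConverged <- FALSE
    while (mcs < maxMcs) {
      mcs <- mcs + 1L
      st <- stepOxygen(lattice, vasc, cellField, params,
                       clampLeak = phase)
      vasc <- st$vascular
      cellField <- st$cellular
      cur <- mean(cellField@grid)
      if (prev > 0 && abs(cur - prev) / max(prev, 1e-12) < tol) {
        phaseConverged <- TRUE
        prev <- cur
        break
      }
      prev <- cur
    }
    converged <- phaseConverged
  }
  list(vascular = vasc, cellular = cellField, mcs = mcs,
       converged = converged)
}

#' Single-capillary perfusion demonstration
#'
#' Fifty one-voxel vascular cells form a straight capillary between a donor
#' clamped at 1 a.u. and an acceptor clamped at 0.  At `removalStep` the
#' configured cells are removed, severing the capillary into a
#' donor-connected segment (which holds its level), an isolated middle
#' segment (which loses oxygen only by diffusion to the tissue) and an
#' acceptor-side segment (which additionally drains and therefore decays
#' fastest).  Deterministic: no randomness is involved.
#'
#' @param nCells number of vascular cells in the capillary.
#' @param removalStep MCS at which cells are removed.
#' @param removed 1-based indices of the cells to remove.
#' @param nMcs total MCS simulated.
#' @param vascularDiffusion,tissueDiffusion diffusion coefficients in
#'   voxel^2/MCS (the demo runs in lattice units).  Vascular diffusion is
#'   fast so that the donor-connected segment re-equilibrates to the donor
#'   level; tissue diffusion is slow so the surrounding tissue acts as a
#'   gentle, persistent sink.
#' @param tissueDecay first-order decay of the tissue field per MCS (the
#'   distributed sink that keeps vascular-to-tissue leakage going).
#' @param crossSection lateral tissue extent in voxels.
#' @return list with `trajectory` (time x cell matrix of vascular pO2, NA
#'   after removal), `time` (0..nMcs) and `removed`.
#' @export
runCapillaryDemo <- function(nCells = 50, removalStep = 100,
                             removed = c(10, 30), nMcs = 400,
                             vascularDiffusion = 40,
                             tissueDiffusion = 0.02, tissueDecay = 1e-3,
                             crossSection = 3L) {
  d <- c(nCells, as.integer(crossSection), as.integer(crossSection))
  lattice <- newLattice(d, voxelSize = 1)
  mid <- as.integer(crossSection) %/% 2L
  vox <- voxelIndex0(lattice, seq_len(nCells) - 1L, rep(mid, nCells),
                     rep(mid, nCells))
  lattice <- addCells(lattice, as.list(vox), "VASCULAR")
  params <- oxygenParams(donorPO2 = 1, acceptorPO2 = 0,
                         tissueDiffusion = tissueDiffusion,
                         vascularDiffusion = vascularDiffusion,
                         maxUptakePerCell = 0, uptakeKm = 1,
                         secondsPerMcs = 1)
  lattice@voxelSize <- 1
  lattice <- placeDonorsAcceptors(lattice, params)
  vasc <- newChemField("VASCULAR_PO2", lattice,
                       c(VASCULAR = vascularDiffusion),
                       boundary = "clamped_cells")
  vasc@grid[vox + 1L] <- 1
  cellField <- newChemField("CELLULAR_PO2", lattice,
                            c(MEDIUM = tissueDiffusion), decay = tissueDecay)
  traj <- matrix(NA_real_, nrow = nMcs + 1L, ncol = nCells)
  traj[1L, ] <- vasc@grid[vox + 1L]
  alive <- rep(TRUE, nCells)
  for (t in seq_len(nMcs)) {
    if (t == removalStep) {
      alive[removed] <- FALSE
      lattice@cells$alive[match(removed, lattice@cells$id)] <- FALSE
      lattice@grid[vox[removed] + 1L] <- 0L
      vasc@grid[vox[removed] + 1L] <- 0
    }
    st <- stepOxygen(lattice, vasc, cellField, params, dt = 1)
    vasc <- st$vascular
    cellField <- st$cellular
    traj[t + 1L, ] <- ifelse(alive, vasc@grid[vox + 1L], NA_real_)
  }
  list(trajectory = traj, time = 0:nMcs, removed = removed)
}
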