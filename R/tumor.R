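# voxels per cell for a volume given in um^3
.voxelsFor <- function(volumeUm3, voxelSize) volumeUm3 / voxelSize^3

#' Seed normal tissue cells at a target density
#'
#' Places compact brick-shaped normal cells (default 1944 um^3, the
#' neuroglial mean, i.e. 9 voxels at 6 um) uniformly at random on free
#' (non-vascular, unoccupied) voxels until the target number density is
#' reached.  Uses R's RNG stream.
#'
#' @param lattice a VoxelLattice.
#' @param density cells per mm^3 (default 127870, mouse cortex).
#' @param cellVolume mean cell volume, um^3.
#' @return the lattice with NORMAL cells added.
#' @export
seedNormalTissue <- function(lattice, density = 127870,
                             cellVolume = 1944) {
  d <- dim(lattice@grid)
  h <- lattice@voxelSize
  volMm3 <- prod(d) * h^3 * 1e-9
  nCellsTarget <- round(density * volMm3)
  vpc <- max(1L, round(.voxelsFor(cellVolume, h)))
  # brick edge lengths multiplying to vpc, near-cubic
  a <- max(1L, floor(vpc^(1 / 3)))
  while (vpc %% a != 0L) a <- a - 1L
  rest <- vpc %/% a
  b <- max(1L, floor(sqrt(rest)))
  while (rest %% b != 0L) b <- b - 1L
  brick <- sort(c(a, b, rest %/% b))
  free <- as.vector(lattice@grid == 0L)
  voxSets <- vector("list", nCellsTarget)
  placed <- 0L
  tries <- 0L
  maxTries <- 50L * nCellsTarget
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  # per-orientation 0-based linear offsets of the brick's voxels
  brickOffsets <- lapply(perms, function(p) {
    bd <- brick[p]
    g <- expand.grid(x = seq_len(bd[1]) - 1L, y = seq_len(bd[2]) - 1L,
                     z = seq_len(bd[3]) - 1L)
    as.integer(g$x + d[1] * (g$y + d[2] * g$z))
  })
  brickDims <- lapply(perms, function(p) brick[p])
  while (placed < nCellsTarget && tries < maxTries) {
    tries <- tries + 1L
    k <- 1L + as.integer(floor(runif(1) * 6))
    bd <- brickDims[[k]]
    anchor <- floor(runif(1) * (d[1] - bd[1] + 1L)) +
      d[1] * (floor(runif(1) * (d[2] - bd[2] + 1L)) +
                d[2] * floor(runif(1) * (d[3] - bd[3] + 1L)))
    vox <- as.integer(anchor) + brickOffsets[[k]]
    if (!all(free[vox + 1L])) next
    free[vox + 1L] <- FALSE
    placed <- placed + 1L
    voxSets[[placed]] <- vox
  }
  if (placed < nCellsTarget)
    warning(sprintf("placed %d of %d normal cells (lattice crowded)",
                    placed, nCellsTarget))
  addCells(lattice, voxSets[seq_len(placed)], "NORMAL",
           targetVolume = .voxelsFor(cellVolume, h))
}

#' Seed a single tumor cell at the lattice center
#'
#' Claims the free/normal voxels nearest the lattice center (vascular
#' voxels are never taken; normal cells are displaced) to build one tumor
#' cell of the initial target volume.  Seeding a lattice that already
#' carries a tumor is an error.
#'
#' @param lattice a VoxelLattice.
#' @param params a [tumorGrowthParams()].
#' @return the lattice with one TUMOR cell added.
#' @export
seedTumor <- function(lattice, params = tumorGrowthParams()) {
  if (any(lattice@cells$type == "TUMOR"))
    stop("lattice already carries a tumor")
  d <- dim(lattice@grid)
  h <- lattice@voxelSize
  nVox <- max(1L, ceiling(.voxelsFor(params@initialCellVolume, h)))
  center <- (d - 1) / 2
  vid <- lattice@cells$id[lattice@cells$type == "VASCULAR"]
  vascular <- array(lattice@grid %in% vid, d)
  # nearest non-vascular voxels by distance to the center
  idx0 <- seq_len(prod(d)) - 1L
  xyz <- voxelCoords(lattice, idx0)
  dist2 <- (xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 +
    (xyz[, 3] - center[3])^2
  ord <- order(dist2, idx0)
  ok <- !as.vector(vascular)[ord]
  take <- ord[ok][seq_len(nVox)]
  vox <- idx0[take]
  # displace any normal cells occupying these voxels
  lattice@grid[vox + 1L] <- 0L
  lattice <- addCells(lattice, list(vox), "TUMOR",
                      targetVolume = .voxelsFor(params@initialCellVolume,
                                                h))
  syncRegistry(lattice, drop = TRUE)
}

#' Oxygen-dependent tumor growth update
#'
#' Each live tumor cell's target volume grows by
#' `maxGrowthRate * pO2 / (pO2 + growthKm)` per MCS, with pO2 the mean
#' cellular pO2 over the cell's voxels (negative values clamped to 0).
#'
#' @param lattice the VoxelLattice.
#' @param cellField the cellular [ChemField-class].
#' @param params a [tumorGrowthParams()].
#' @return the lattice with updated tumor target volumes.
#' @export
growthUpdate <- function(lattice, cellField, params = tumorGrowthParams()) {
  cells <- lattice@cells
  sel <- which(cells$type == "TUMOR" & cells$alive)
  if (!length(sel)) return(lattice)
  mx <- max(cells$id[sel])
  means <- cell_field_means(as.vector(lattice@grid),
                            as.vector(cellField@grid), mx)$mean
  m <- means[cells$id[sel]]
  m[is.na(m) | m < 0] <- 0
  inc <- .voxelsFor(params@maxGrowthRate, lattice@voxelSize) *
    m / (m + params@growthKm)
  cells$targetVolume[sel] <- cells$targetVolume[sel] + inc
  lattice@cells <- cells
  lattice
}

# connected components (6-connectivity) of a 0-based voxel index set;
# returns a membership vector
.components6 <- function(vox0, dims) {
  if (length(vox0) == 1L) return(1L)
  g <- .voxelGraph(vox0, dims)
  igraph::components(g)$membership
}

#' Divide a tumor cell
#'
#' Splits the cell's voxels by a plane through the centroid orthogonal to
#' the major axis.  If a daughter is non-contiguous or the volumes differ
#' by more than 20%, the plane is perturbed (up to 5 retries); the final
#' fallback accepts the largest-component assignment.  Both daughters are
#' tumor cells with the initial target volume.
#'
#' @param lattice the VoxelLattice.
#' @param id identifier of the dividing cell (volume must have reached the
#'   division volume).
#' @param params a [tumorGrowthParams()].
#' @return list with the updated `lattice` and the `daughterIds`.
#' @export
divideCell <- function(lattice, id, params = tumorGrowthParams()) {
  d <- dim(lattice@grid)
  h <- lattice@voxelSize
  vox <- which(lattice@grid == id) - 1L
  if (length(vox) < 2L) stop("cell too small to divide")
  if (length(vox) < .voxelsFor(params@divisionVolume, h) - 1e-9)
    stop("cell has not reached the division volume")
  xyz <- voxelCoords(lattice, vox)
  ctr <- colMeans(xyz)
  C <- stats::cov(xyz)
  u <- eigen(C, symmetric = TRUE)$vectors[, 1]
  proj <- as.vector((xyz - matrix(ctr, nrow(xyz), 3, byrow = TRUE)) %*% u)
  n <- length(vox)
  half <- n %/% 2L
  # daughter A is grown as a connected sweep from the extreme voxel along
  # the split axis: repeatedly take the frontier voxel with the smallest
  # projection, so A is connected by construction and holds exactly half
  # the voxels; this is the discrete equivalent of the centroid plane
  growHalf <- function(p) {
    ord <- order(p)
    inA <- logical(n)
    frontier <- rep(FALSE, n)
    frontier[ord[1]] <- TRUE
    adj <- lapply(seq_len(n), function(i) {
      dd <- abs(xyz[, 1] - xyz[i, 1]) + abs(xyz[, 2] - xyz[i, 2]) +
        abs(xyz[, 3] - xyz[i, 3])
      which(dd == 1L)
    })
    for (k in seq_len(half)) {
      cand <- which(frontier & !inA)
      if (!length(cand)) break
      pick <- cand[which.min(p[cand])]
      inA[pick] <- TRUE
      frontier[adj[[pick]]] <- TRUE
    }
    inA
  }
  attempt <- function(p) {
    inA <- growHalf(p)
    a <- vox[inA]
    b <- vox[!inA]
    # reattach stray minor components of B to A
    memb <- .components6(b, d)
    if (max(memb) > 1L) {
      keep <- memb == which.max(tabulate(memb))
      a <- c(a, b[!keep])
      b <- b[keep]
    }
    list(a = a, b = b)
  }
  ok <- function(s) {
    na <- length(s$a)
    nb <- length(s$b)
    na > 0L && nb > 0L && abs(na - nb) / max(na, nb) <= 0.2 &&
      max(.components6(s$a, d)) == 1L
  }
  # move single boundary voxels from the larger to the smaller daughter
  # until the volumes balance (reverting moves that would disconnect)
  rebalance <- function(s) {
    for (it in 1:25) {
      na <- length(s$a)
      nb <- length(s$b)
      if (abs(na - nb) / max(na, nb) <= 0.2) break
      from <- if (na > nb) "a" else "b"
      to <- setdiff(c("a", "b"), from)
      big <- s[[from]]
      small <- s[[to]]
      cb <- voxelCoords(lattice, big)
      cs <- voxelCoords(lattice, small)
      touching <- vapply(seq_along(big), function(i) {
        any(abs(cs[, 1] - cb[i, 1]) + abs(cs[, 2] - cb[i, 2]) +
              abs(cs[, 3] - cb[i, 3]) == 1L)
      }, logical(1))
      moved <- FALSE
      for (i in which(touching)) {
        rest <- big[-i]
        if (max(.components6(rest, d)) == 1L) {
          s[[from]] <- rest
          s[[to]] <- c(small, big[i])
          moved <- TRUE
          break
        }
      }
      if (!moved) break
    }
    s
  }
  imbalance <- function(s) {
    abs(length(s$a) - length(s$b)) / max(length(s$a), length(s$b))
  }
  # alternative daughter: a breadth-first half-ball grown from an extreme
  # voxel (connected by the BFS property; its complement is usually
  # connected for compact cells)
  adjList <- lapply(seq_len(n), function(i) {
    dd <- abs(xyz[, 1] - xyz[i, 1]) + abs(xyz[, 2] - xyz[i, 2]) +
      abs(xyz[, 3] - xyz[i, 3])
    which(dd == 1L)
  })
  bfsHalf <- function(start) {
    seen <- logical(n)
    queue <- start
    seen[start] <- TRUE
    orderv <- integer(0)
    while (length(queue) && length(orderv) < half) {
      i <- queue[1]
      queue <- queue[-1]
      orderv <- c(orderv, i)
      nb <- adjList[[i]][!seen[adjList[[i]]]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    inA <- logical(n)
    inA[orderv] <- TRUE
    inA
  }
  reattach <- function(inA) {
    a <- vox[inA]
    b <- vox[!inA]
    memb <- .components6(b, d)
    if (max(memb) > 1L) {
      keep <- memb == which.max(tabulate(memb))
      a <- c(a, b[!keep])
      b <- b[keep]
    }
    list(a = a, b = b)
  }
  s <- rebalance(attempt(proj))
  tries <- 0L
  while (!ok(s) && tries < 12L) {
    tries <- tries + 1L
    cand <- if (tries <= 6L) {
      pert <- u + runif(3, -0.5, 0.5)
      pert <- pert / sqrt(sum(pert^2))
      rebalance(attempt(
        as.vector((xyz - matrix(ctr, n, 3, byrow = TRUE)) %*% pert)))
    } else {
      start <- switch(tries - 6L, which.min(proj), which.max(proj),
                      which.min(xyz[, 1]), which.max(xyz[, 1]),
                      which.min(xyz[, 2]), which.max(xyz[, 2]))
      rebalance(reattach(bfsHalf(start)))
    }
    if (imbalance(cand) < imbalance(s)) s <- cand
  }
  tv <- .voxelsFor(params@initialCellVolume, h)
  row <- match(id, lattice@cells$id)
  lattice@cells$targetVolume[row] <- tv
  newId <- max(lattice@cells$id) + 1L
  lattice@grid[s$b + 1L] <- 0L # re-labeled by addCells
  lattice <- addCells(lattice, list(s$b), "TUMOR", targetVolume = tv)
  lattice <- syncRegistry(lattice)
  list(lattice = lattice, daughterIds = c(id, newId))
}

#' Calibrated Hamiltonian for the tumor-growth stage
#'
#' Moderate adhesion energies with cohesive tumor contacts, a firm volume
#' constraint (so small newly seeded cells are not lost to fluctuations)
#' and the stiff vascular elongation constraint carried over from
#' remodeling so that displaced vessels stay filamentous.
#'
#' @return a [HamiltonianParams-class].
#' @export
growthParams <- function() {
  J <- matrix(0, 6, 6, dimnames = list(.TYPE_NAMES, .TYPE_NAMES))
  set <- function(a, b, v) {
    J[a, b] <<- v
    J[b, a] <<- v
  }
  set("VASCULAR", "MEDIUM", 2)
  set("VASCULAR", "VASCULAR", 4) # neutral: no vascular-phase coalescence
  set("NORMAL", "MEDIUM", 4)
  set("NORMAL", "NORMAL", 3)
  set("NORMAL", "VASCULAR", 6)
  set("TUMOR", "TUMOR", 2)
  set("TUMOR", "MEDIUM", 6)
  set("TUMOR", "NORMAL", 5)
  set("TUMOR", "VASCULAR", 8)
  for (tt in c("DONOR", "ACCEPTOR")) {
    J[tt, ] <- J["VASCULAR", ]
    J[, tt] <- J[, "VASCULAR"]
  }
  hamiltonianParams(J = J, lambdaVolume = 5, lambdaLength = 100,
                    chemotaxisMu = 0, temperature = 5)
}

#' Grow the tumor to staged snapshots
#'
#' Interleaves Potts dynamics, cellular-oxygen stepping (vascular voxels
#' clamped at the arterial pO2 during the growth phase), Michaelis-Menten
#' growth and division, and records a snapshot whenever the tumor volume
#' fraction first reaches each configured stage fraction.  Growth stages
#' are defined by geometry (tumor volume fraction), so scaled-down runs
#' reach the same morphological stages as full-scale ones.  Refuses to run
#' past lattice crowding (tumor fraction > 0.6).
#'
#' @param lattice a VoxelLattice with a seeded tumor.
#' @param params a [tumorGrowthParams()].
#' @param oxy an [oxygenParams()].
#' @param ham a [HamiltonianParams-class] for the growth dynamics.
#' @param stages named numeric vector of tumor volume fractions to snapshot
#'   (defaults to `params@stageFractions`).
#' @param maxMcs iteration cap.
#' @return list with `lattice` (final), `snapshots` (named list of lattices
#'   at each reached stage) and `series` (per-MCS tumor statistics).
#' @export
growToStage <- function(lattice, params = tumorGrowthParams(),
                        oxy = oxygenParams(), ham = NULL,
                        stages = NULL, maxMcs = 2000L) {
  if (!any(lattice@cells$type == "TUMOR")) stop("no seeded tumor")
  if (is.null(ham)) ham <- growthParams()
  if (is.null(stages)) stages <- params@stageFractions
  stages <- sort(stages)
  d <- dim(lattice@grid)
  nTot <- prod(d)
  cellField <- newChemField("CELLULAR_PO2", lattice,
                            c(MEDIUM = oxy@tissueDiffusion))
  vascClamp <- newChemField("VASCULAR_PO2", lattice,
                            c(VASCULAR = oxy@vascularDiffusion),
                            boundary = "clamped_cells",
                            init = oxy@donorPO2)
  snapshots <- list()
  series <- data.frame(mcs = integer(), tumorFraction = numeric(),
                       nTumorCells = integer())
  divVox <- .voxelsFor(params@divisionVolume, lattice@voxelSize)
  for (mcs in seq_len(maxMcs)) {
    st <- stepCellularField(cellField, vascClamp, lattice, oxy,
                            oxy@secondsPerMcs)
    cellField <- st$field
    lattice <- runMCS(lattice, ham, 1L, field = NULL)
    lattice <- growthUpdate(lattice, cellField, params)
    repeat {
      ready <- with(lattice@cells,
                    id[type == "TUMOR" & alive & volume >= divVox])
      if (!length(ready)) break
      for (cid in ready)
        lattice <- divideCell(lattice, cid, params)$lattice
    }
    # vessels are displaced, not severed: bridge any discontinuity the
    # dynamics opened, as in the remodeling stage
    if (mcs %% 25L == 0L) lattice <- repairVascularGaps(lattice)
    tumorFrac <- sum(lattice@cells$volume[lattice@cells$type == "TUMOR" &
                                            lattice@cells$alive]) / nTot
    nT <- sum(lattice@cells$type == "TUMOR" & lattice@cells$alive)
    series <- rbind(series, data.frame(mcs = mcs,
                                       tumorFraction = tumorFrac,
                                       nTumorCells = nT))
    while (length(stages) && tumorFrac >= stages[1]) {
      nm <- names(stages)[1]
      if (is.null(nm) || !nzchar(nm)) nm <- sprintf("f%.3f", stages[1])
      snapshots[[nm]] <- lattice
      stages <- stages[-1]
    }
    if (!length(stages)) break
    if (tumorFrac > 0.6) {
      warning("lattice crowded (tumor fraction > 60%); stopping growth")
      break
    }
  }
  lattice <- repairVascularGaps(lattice, maxGap = 8)
  list(lattice = lattice, snapshots = snapshots, series = series)
}
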