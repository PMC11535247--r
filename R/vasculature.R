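# ---- voxel graph helpers (6-connectivity) ----

# igraph over a set of 0-based linear voxel indices, edges between
# face-adjacent voxels (non-periodic)
.voxelGraph <- function(vox0, dims) {
  n <- length(vox0)
  pos <- seq_len(n)
  lookup <- new.env() # not used; membership via match on sorted vector
  x <- vox0 %% dims[1]
  y <- (vox0 %/% dims[1]) %% dims[2]
  z <- vox0 %/% (dims[1] * dims[2])
  ord <- order(vox0)
  sorted <- vox0[ord]
  edges <- integer(0)
  for (ax in 1:3) {
    step <- c(1L, dims[1], dims[1] * dims[2])[ax]
    coord <- list(x, y, z)[[ax]]
    ok <- coord < dims[ax] - 1L
    nb <- vox0[ok] + step
    hit <- match(nb, sorted)
    has <- !is.na(hit)
    from <- pos[ok][has]
    to <- ord[hit[has]]
    edges <- c(edges, rbind(from, to))
  }
  igraph::make_graph(edges, n = n, directed = FALSE)
}

# does the vascular mask contain a 6-connected path between the two faces
# of `axis`?
.spansAxis <- function(mask, axis) {
  d <- dim(mask)
  vox0 <- which(mask) - 1L
  if (!length(vox0)) return(FALSE)
  coord <- switch(axis, vox0 %% d[1], (vox0 %/% d[1]) %% d[2],
                  vox0 %/% (d[1] * d[2]))
  lo <- which(coord == 0L)
  hi <- which(coord == d[axis] - 1L)
  if (!length(lo) || !length(hi)) return(FALSE)
  g <- .voxelGraph(vox0, d)
  memb <- igraph::components(g)$membership
  any(memb[lo] %in% memb[hi])
}

# ---- generation ----

# one biased random walk along `axis` (direction `sign`), starting at
# `start` (0-based xyz) or a random low-face voxel; stops at the lattice
# face or after `maxSteps` voxels (dead-end branches)
.walkPath <- function(dims, axis, tortuosity, start = NULL, sign = 1L,
                      maxSteps = Inf) {
  pAxis <- 1 / tortuosity
  pos <- if (is.null(start)) {
    p <- c(floor(runif(1) * dims[1]), floor(runif(1) * dims[2]),
           floor(runif(1) * dims[3]))
    p[axis] <- if (sign > 0) 0 else dims[axis] - 1L
    p
  } else start
  guard <- min(30L * sum(dims), maxSteps)
  path <- matrix(NA_integer_, guard + 1L, 3L)
  path[1L, ] <- pos
  k <- 1L
  atFace <- function() if (sign > 0) pos[axis] >= dims[axis] - 1L
                       else pos[axis] <= 0L
  while (!atFace() && k <= guard) {
    if (runif(1) < pAxis) {
      pos[axis] <- pos[axis] + sign
    } else {
      lat <- setdiff(1:3, axis)[1L + (runif(1) < 0.5)]
      pos[lat] <- min(max(pos[lat] + (2L * (runif(1) < 0.5) - 1L), 0L),
                      dims[lat] - 1L)
    }
    k <- k + 1L
    path[k, ] <- pos
  }
  path[seq_len(k), , drop = FALSE]
}

# dilate 0-based voxel coordinates by a Euclidean ball of `radius` voxels,
# clipped to the lattice; returns 0-based linear indices
.dilateCoords <- function(coords, dims, radius) {
  if (radius > 0) {
    r <- seq(-radius, radius)
    off <- as.matrix(expand.grid(x = r, y = r, z = r))
    off <- off[sqrt(rowSums(off^2)) <= radius + 0.5, , drop = FALSE]
    coords <- coords[rep(seq_len(nrow(coords)), each = nrow(off)), ,
                     drop = FALSE] +
      off[rep(seq_len(nrow(off)), nrow(coords)), , drop = FALSE]
    keep <- coords[, 1] >= 0 & coords[, 1] < dims[1] &
      coords[, 2] >= 0 & coords[, 2] < dims[2] &
      coords[, 3] >= 0 & coords[, 3] < dims[3]
    coords <- coords[keep, , drop = FALSE]
  }
  unique(coords[, 1] + dims[1] * (coords[, 2] + dims[2] * coords[, 3]))
}

#' Generate a synthetic capillary network
#'
#' Grows biased random-walk tubes between opposite lattice faces (cycling
#' through the three axes) plus branch walks seeded on the existing network,
#' dilated to at least the minimum capillary diameter, until the vascular
#' volume fraction is within half a percentage point of the target.  The
#' construction guarantees at least one 6-connected vascular path between
#' each pair of opposite faces.
#'
#' All vascular voxels are labeled as a single provisional cell; use
#' [clusterVascularCells()] to partition them into elongated vascular cells.
#' Randomness comes from R's RNG stream (`set.seed()` for reproducibility).
#'
#' @param params a [vesselNetworkParams()].
#' @param dims integer length-3 lattice dimensions, each >= 32 (unless the
#'   target fraction is 0).
#' @param voxelSize voxel edge, micrometres.
#' @return a [VoxelLattice-class].
#' @export
generateCapillaryNetwork <- function(params = vesselNetworkParams(),
                                     dims = c(64, 64, 64), voxelSize = 6) {
  dims <- as.integer(dims)
  lattice <- newLattice(dims, voxelSize)
  target <- params@targetVolumeFraction
  if (target == 0) return(lattice)
  if (any(dims < 32L)) stop("lattice dimensions must be >= 32 voxels")
  if (params@minCapillaryDiameter < voxelSize)
    stop("minimum capillary diameter is below the voxel size")
  mask <- array(FALSE, dims)
  n <- prod(dims)
  # most capillaries at the minimum diameter, a minority of wider vessels
  rMin <- max(0L, as.integer(ceiling(params@minCapillaryDiameter /
                                       voxelSize / 2 - 0.5)))
  rBig <- rMin + 1L
  thickShare <- 0.15
  addPath <- function(coords, radius) {
    idx <- .dilateCoords(coords, dims, radius)
    fracNow <- sum(mask) / n
    gain <- idx[!mask[idx + 1L]]
    if (fracNow + length(gain) / n > target + 0.004) {
      # trim from the tail so the target band is never overshot
      keep <- floor((target + 0.004 - fracNow) * n)
      gain <- gain[seq_len(max(keep, 0L))]
    }
    mask[gain + 1L] <<- TRUE
  }
  # spanning seed paths, cycling the three axes
  axes <- rep_len(1:3, max(params@nSeedPaths, 3L))
  for (ax in axes) addPath(.walkPath(dims, ax, params@tortuosity), rMin)
  # top up with branch walks anchored on the existing network
  iter <- 0L
  crossLen <- mean(dims) * params@tortuosity
  while (sum(mask) / n < target - 0.005) {
    iter <- iter + 1L
    if (iter > 20000L)
      stop(sprintf(paste0("cannot reach vascular fraction %.3f ",
                          "(achieved %.3f after %d walks); ",
                          "increase nSeedPaths or the lattice size"),
                   target, sum(mask) / n, iter))
    anchors <- which(mask) - 1L
    a0 <- anchors[1L + floor(runif(1) * length(anchors))]
    start <- as.integer(voxelCoords(lattice, a0)[1, ])
    ax <- 1L + floor(runif(1) * 3)
    sg <- if (runif(1) < 0.5) 1L else -1L
    # most branches are dead-end capillary side branches; a minority run
    # to a face and anastomose with the boundary-fed backbone
    steps <- if (runif(1) < 0.7)
      5L + stats::rgeom(1L, 1 / (0.4 * mean(dims))) else Inf
    path <- .walkPath(dims, ax, params@tortuosity, start = start,
                      sign = sg, maxSteps = steps)
    deficit <- target - sum(mask) / n
    bigGain <- crossLen * 15 / n # rough yield of a dilated walk
    addPath(path, if (runif(1) < thickShare && deficit > 1.5 * bigGain)
                    rBig else rMin)
  }
  for (ax in 1:3)
    if (!.spansAxis(mask, ax))
      stop("generated network does not span axis ", ax)
  lattice <- addCells(lattice, list(which(mask) - 1L), "VASCULAR")
  lattice
}

#' Import a binary vasculature stack and resample to the working resolution
#'
#' Each `factor`^3 block of the input collapses to one voxel.  Foreground
#' blocks are chosen by occupancy rank (densest blocks first, ties broken by
#' index order) so that the global vascular volume fraction is preserved to
#' within one part in the number of blocks.
#'
#' @param stack 3-D binary array (0/1 or logical), e.g. a segmentation at
#'   3 micrometre resolution, or a TIFF path readable by the `tiff` package.
#' @param factor integer downsampling factor per axis (default 2).
#' @param voxelSizeIn input voxel edge, micrometres.
#' @return a [VoxelLattice-class] at `voxelSizeIn * factor` resolution with
#'   vascular voxels labeled as one provisional cell.
#' @export
importAndResample <- function(stack, factor = 2L, voxelSizeIn = 3) {
  if (is.character(stack)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF stacks needs the 'tiff' package")
    pages <- tiff::readTIFF(stack, all = TRUE)
    stack <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
    for (z in seq_along(pages)) stack[, , z] <- t(pages[[z]])
  }
  if (length(dim(stack)) != 3L || prod(dim(stack)) == 0L)
    stop("stack must be a non-empty 3-D array")
  u <- unique(as.vector(stack))
  if (!all(u %in% c(0, 1))) stop("stack must be binary (0/1)")
  factor <- as.integer(factor)
  stack <- stack > 0
  d <- dim(stack)
  pad <- (factor - d %% factor) %% factor
  if (any(pad > 0L)) {
    padded <- array(FALSE, d + pad)
    padded[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- stack
    stack <- padded
    d <- dim(stack)
  }
  nd <- d %/% factor
  # per-block foreground counts
  dim(stack) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  occ <- apply(stack, c(2, 4, 6), sum)
  nBlocks <- prod(nd)
  targetCount <- round(sum(occ) / factor^3)
  out <- array(FALSE, nd)
  if (targetCount > 0) {
    ord <- order(-as.vector(occ), seq_len(nBlocks))
    chosen <- ord[seq_len(targetCount)]
    chosen <- chosen[as.vector(occ)[chosen] > 0]
    out[chosen] <- TRUE
  }
  lattice <- newLattice(nd, voxelSizeIn * factor)
  if (any(out)) lattice <- addCells(lattice, list(which(out) - 1L),
                                    "VASCULAR")
  lattice
}

#' Partition capillary voxels into elongated vascular cells
#'
#' Greedy geodesic segmentation: within each 6-connected capillary
#' component, voxels are banded by geodesic distance from a component
#' endpoint in slabs of `targetCellLength`; bands are split into their
#' connected pieces (so parallel branches never share a cell) and pieces
#' with a geodesic extent below half the target merge into an adjacent
#' piece.  Relabeling only: the vascular voxel set is unchanged.
#'
#' @param lattice a VoxelLattice with vascular voxels labeled.
#' @param targetCellLength target major-axis length in voxels (default 20,
#'   i.e. 120 micrometres at 6 micrometre voxels).
#' @return the lattice with its vascular registry replaced by the clustered
#'   cells (target axis set to `targetCellLength`).
#' @export
clusterVascularCells <- function(lattice, targetCellLength = 20) {
  cells <- lattice@cells
  vascIds <- cells$id[cells$type == "VASCULAR"]
  if (!length(vascIds)) stop("no vascular voxels to cluster")
  vox0 <- which(lattice@grid %in% vascIds) - 1L
  d <- dim(lattice@grid)
  g <- .voxelGraph(vox0, d)
  comp <- igraph::components(g)
  pieces <- list()
  # recursive geodesic banding: band by distance from a piece endpoint,
  # split bands into connected chunks, re-band chunks whose geodesic
  # diameter still exceeds 1.5x the target (shells around junction-rich
  # regions), accept the rest
  segment <- function(verts, depth) {
    if (length(verts) == 1L) {
      pieces[[length(pieces) + 1L]] <<- list(v = verts, ext = 1)
      return(invisible())
    }
    d1 <- as.vector(igraph::distances(g, v = verts[1], to = verts))
    endpoint <- verts[which.max(d1)]
    dist <- as.vector(igraph::distances(g, v = endpoint, to = verts))
    diam <- max(dist) + 1
    if ((diam <= 1.5 * targetCellLength &&
         length(verts) <= 8L * targetCellLength) || depth >= 8L) {
      pieces[[length(pieces) + 1L]] <<- list(v = verts, ext = diam)
      return(invisible())
    }
    band <- dist %/% targetCellLength
    for (b in sort(unique(band))) {
      bv <- verts[band == b]
      sub <- igraph::induced_subgraph(g, bv)
      sm <- igraph::components(sub)$membership
      for (k in seq_len(max(sm))) segment(bv[sm == k], depth + 1L)
    }
  }
  for (ci in seq_len(comp$no))
    segment(which(comp$membership == ci), 0L)
  # merge short or under-massed pieces (too few voxels to ever reach the
  # target length) into an adjacent piece (most shared contacts wins)
  pieceOf <- integer(length(vox0))
  for (i in seq_along(pieces)) pieceOf[pieces[[i]]$v] <- i
  adj <- igraph::as_edgelist(g, names = FALSE)
  ext <- vapply(pieces, `[[`, numeric(1), "ext")
  vol <- vapply(pieces, function(p) length(p$v), numeric(1))
  small <- order(ext)
  for (i in small) {
    if (ext[i] >= targetCellLength / 2 && vol[i] >= targetCellLength) next
    mine <- pieceOf == i
    pa <- pieceOf[adj[, 1]]
    pb <- pieceOf[adj[, 2]]
    touching <- c(pb[pa == i & pb != i], pa[pb == i & pa != i])
    if (!length(touching)) next # isolated fragment keeps its own cell
    tgt <- as.integer(names(which.max(table(touching))))
    pieceOf[mine] <- tgt
    ext[tgt] <- max(ext[tgt], ext[i]) # extent approximation after merge
    vol[tgt] <- vol[tgt] + vol[i]
    ext[i] <- Inf
    vol[i] <- Inf
  }
  keep <- sort(unique(pieceOf))
  # rebuild the vascular part of the registry
  grid <- lattice@grid
  grid[grid %in% vascIds] <- 0L
  lattice@grid <- grid
  lattice@cells <- cells[cells$type != "VASCULAR", , drop = FALSE]
  voxSets <- lapply(keep, function(p) vox0[pieceOf == p])
  lattice <- addCells(lattice, voxSets, "VASCULAR",
                      targetAxis = targetCellLength)
  lattice
}

#' Remodel clustered vascular cells by autocrine chemotaxis and elongation
#'
#' Runs Potts dynamics in which vascular cells secrete a VEGF-like
#' attractant into their own voxels, chemotax on it, and carry an
#' elongation constraint toward the target major-axis length set at
#' clustering.  This removes resampling artifacts (small capillary
#' discontinuities close) and drives the mean vascular cell length toward
#' the experimentally observed ~124 micrometre range.
#'
#' @param lattice a clustered VoxelLattice.
#' @param vegf a [vegfParams()].
#' @param ham a [HamiltonianParams-class]; the default enables chemotaxis
#'   and elongation with calibrated strengths.
#' @param nMcs number of Monte-Carlo steps.
#' @param secondsPerMcs seconds represented by one MCS (VEGF kinetics).
#' @param driftGuard abort if the vascular volume fraction drifts by more
#'   than this relative amount from its initial value (default 0.2).
#' @return the remodeled lattice; attribute `vegf` carries the final field.
#' @export
remodelVasculature <- function(lattice, vegf = vegfParams(), ham = NULL,
                               nMcs = 100, secondsPerMcs = 1,
                               driftGuard = 0.2) {
  if (!any(lattice@cells$type == "VASCULAR"))
    stop("no clustered vascular cells present")
  if (is.null(ham)) ham <- remodelingParams()
  d <- dim(lattice@grid)
  h <- lattice@voxelSize
  field <- array(0, d)
  frac0 <- vascularFraction(lattice)
  decayPerS <- vegf@decayConstant / 3600
  for (step in seq_len(nMcs)) {
    vascIds <- lattice@cells$id[lattice@cells$type == "VASCULAR"]
    secretIdx <- which(lattice@grid %in% vascIds) - 1L
    field[] <- vegf_step_cpp(as.vector(field), d, rep(TRUE, 3L),
                             vegf@diffusionCoefficient, h, secondsPerMcs,
                             decayPerS, secretIdx,
                             vegf@secretionRate / secondsPerMcs)
    lattice <- runMCS(lattice, ham, 1L, field = field)
    if (step %% 10L == 0L || step == nMcs) {
      drift <- abs(vascularFraction(lattice) - frac0) / frac0
      if (drift > driftGuard)
        stop(sprintf("vascular volume fraction drifted %.0f%% from start",
                     100 * drift))
    }
    # keep discontinuities small while the dynamics run
    if (step %% 50L == 0L) lattice <- repairVascularGaps(lattice)
  }
  vegfField <- field
  # final artifact cleanup bridges any remaining island
  lattice <- repairVascularGaps(lattice, maxGap = 8)
  attr(lattice, "vegf") <- vegfField
  lattice
}

#' Bridge small capillary discontinuities
#'
#' Vessel fragments disconnected from the main vascular component (e.g. a
#' 1-2 voxel gap opened by resampling or by the Potts dynamics) are
#' re-attached by drawing a straight voxel bridge to the nearest main-
#' component voxel whenever the gap is at most `maxGap` voxels.  Bridge
#' voxels join the fragment's nearest cell.  Fragments further away than
#' `maxGap` are left untouched.
#'
#' @param lattice a VoxelLattice with clustered vascular cells.
#' @param maxGap largest Euclidean gap (voxels) that is bridged.
#' @return the repaired lattice.
#' @export
repairVascularGaps <- function(lattice, maxGap = 3) {
  d <- dim(lattice@grid)
  for (pass in 1:10) {
    vascIds <- lattice@cells$id[lattice@cells$type == "VASCULAR" &
                                  lattice@cells$alive]
    vox0 <- which(lattice@grid %in% vascIds) - 1L
    if (!length(vox0)) return(lattice)
    g <- .voxelGraph(vox0, d)
    comp <- igraph::components(g)
    if (comp$no == 1L) return(lattice)
    allXyz <- voxelCoords(lattice, vox0)
    mainC <- which.max(comp$csize)
    bridged <- FALSE
    for (ci in setdiff(seq_len(comp$no), mainC)) {
      sel <- comp$membership == ci
      orphVox <- vox0[sel]
      orphXyz <- allXyz[sel, , drop = FALSE]
      # nearest voxel of any *other* component, restricted to the
      # orphan's padded bounding box
      pad <- maxGap + 1
      inBox <- !sel &
        allXyz[, 1] >= min(orphXyz[, 1]) - pad &
        allXyz[, 1] <= max(orphXyz[, 1]) + pad &
        allXyz[, 2] >= min(orphXyz[, 2]) - pad &
        allXyz[, 2] <= max(orphXyz[, 2]) + pad &
        allXyz[, 3] >= min(orphXyz[, 3]) - pad &
        allXyz[, 3] <= max(orphXyz[, 3]) + pad
      if (!any(inBox)) next
      cand <- allXyz[inBox, , drop = FALSE]
      # closest orphan/candidate voxel pair
      best <- c(Inf, NA, NA)
      for (i in seq_len(nrow(orphXyz))) {
        d2 <- (cand[, 1] - orphXyz[i, 1])^2 +
          (cand[, 2] - orphXyz[i, 2])^2 +
          (cand[, 3] - orphXyz[i, 3])^2
        j <- which.min(d2)
        if (d2[j] < best[1]) best <- c(d2[j], i, j)
      }
      if (sqrt(best[1]) > maxGap + 1) next
      a <- orphXyz[best[2], ]
      b <- cand[best[3], ]
      # 6-connected staircase path between the pair (endpoints excluded)
      pts <- NULL
      p <- a
      for (ax in 1:3) {
        while (p[ax] != b[ax]) {
          p[ax] <- p[ax] + sign(b[ax] - p[ax])
          if (!all(p == b)) pts <- rbind(pts, p)
        }
      }
      if (is.null(pts)) next # face-adjacent pair cannot be disconnected
      lin <- pts[, 1] + d[1] * (pts[, 2] + d[2] * pts[, 3]) + 1L
      # the vessel keeps its lumen: bridge voxels claim medium and, where
      # necessary, displace voxels of non-vascular cells
      occ <- lattice@grid[lin]
      occType <- ifelse(occ > 0L,
                        lattice@cells$type[match(occ, lattice@cells$id)],
                        "MEDIUM")
      claim <- occType != "VASCULAR"
      cellId <- lattice@grid[orphVox[best[2]] + 1L]
      lattice@grid[lin[claim]] <- cellId
      bridged <- TRUE
    }
    lattice <- syncRegistry(lattice)
    if (!bridged) break
  }
  lattice
}

#' Calibrated Hamiltonian for the vascular remodeling stage
#'
#' A cold, stiff parameter set: a near-hard elongation constraint, strong
#' volume conservation, weak vascular surface tension and mild autocrine
#' chemotaxis.  Calibrated so that remodeling conserves the cell count and
#' the vascular volume fraction while driving the mean cell length into
#' the experimentally observed range (see the methods vignette).
#'
#' @return a [HamiltonianParams-class].
#' @export
remodelingParams <- function() {
  J <- matrix(0, 6, 6, dimnames = list(.TYPE_NAMES, .TYPE_NAMES))
  J["VASCULAR", "MEDIUM"] <- J["MEDIUM", "VASCULAR"] <- 2
  # cell-cell contact is energetically neutral (J_vv = 2 J_vm): no
  # differential-adhesion drive for the vascular phase to coalesce into
  # islands, which would tear the network
  J["VASCULAR", "VASCULAR"] <- 4
  for (tt in c("DONOR", "ACCEPTOR")) {
    J[tt, ] <- J["VASCULAR", ]
    J[, tt] <- J[, "VASCULAR"]
  }
  hamiltonianParams(J = J, lambdaVolume = 6, lambdaLength = 100,
                    chemotaxisMu = 5, temperature = 1)
}

#' Mean vascular cell major-axis length
#'
#' @param lattice a VoxelLattice with clustered vascular cells.
#' @return mean major-axis length in micrometres.
#' @export
meanVascularLength <- function(lattice) {
  lattice <- syncRegistry(lattice)
  cells <- lattice@cells
  sel <- cells$type == "VASCULAR" & cells$volume > 0
  mean(cells$axisLength[sel]) * lattice@voxelSize
}
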