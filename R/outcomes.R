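#' Classify cell oxygenation states
#'
#' Compares each live normal/tumor cell's mean cellular pO2 to the
#' thresholds: below the hypoxia threshold the cell is HYPOXIC (reversible:
#' it returns to NORMOXIC when pO2 recovers above the threshold), below the
#' necrosis threshold it becomes NECROTIC, which is absorbing -- the cell
#' counts as dead and stops consuming oxygen, but its voxels remain on the
#' lattice.
#'
#' @param lattice the VoxelLattice.
#' @param cellField the cellular [ChemField-class].
#' @param thresholds an [outcomeThresholds()].
#' @return list with the updated `lattice` and `counts` (named vector of
#'   NORMOXIC / HYPOXIC / NECROTIC among live normal/tumor cells).
#' @export
classifyCells <- function(lattice, cellField,
                          thresholds = outcomeThresholds()) {
  cells <- lattice@cells
  sel <- which(cells$type %in% c("NORMAL", "TUMOR") & cells$alive)
  if (!length(sel))
    return(list(lattice = lattice,
                counts = c(NORMOXIC = 0L, HYPOXIC = 0L, NECROTIC = 0L)))
  mx <- max(cells$id[sel])
  means <- cell_field_means(as.vector(lattice@grid),
                            as.vector(cellField@grid), mx)$mean
  m <- means[cells$id[sel]]
  m[is.na(m)] <- 0
  state <- cells$oxygenState[sel]
  free <- state != "NECROTIC" # necrosis is absorbing
  newState <- ifelse(m < thresholds@necrosisPO2, "NECROTIC",
                     ifelse(m < thresholds@hypoxiaPO2, "HYPOXIC",
                            "NORMOXIC"))
  state[free] <- newState[free]
  cells$oxygenState[sel] <- state
  lattice@cells <- cells
  list(lattice = lattice,
       counts = c(NORMOXIC = sum(state == "NORMOXIC"),
                  HYPOXIC = sum(state == "HYPOXIC"),
                  NECROTIC = sum(state == "NECROTIC")))
}

#' Spatial-uniformity statistic of the vasculature
#'
#' Tiles the lattice into cubic subregions, computes each subregion's local
#' vascular density (vascular voxels / subregion volume) and returns the
#' population standard deviation over subregions.  A larger SD means a less
#' uniform vascular distribution; given a reference SD, the relative
#' *decrease in uniformity* is `(SD - SDref) / SDref`.
#'
#' @param lattice the VoxelLattice.
#' @param subregionEdge subregion edge in voxels; must tile the lattice
#'   exactly.  Default: the divisor of the lattice edge closest to a fifth
#'   of it.
#' @param referenceSD optional reference SD (e.g. the normal-tissue
#'   scenario).
#' @return list with `sd`, `densities` and (when a reference is given)
#'   `uniformityDecrease`.
#' @export
uniformityStatistic <- function(lattice, subregionEdge = NULL,
                                referenceSD = NULL) {
  d <- dim(lattice@grid)
  if (is.null(subregionEdge)) {
    divs <- which(d[1] %% seq_len(d[1]) == 0L)
    subregionEdge <- divs[which.min(abs(divs - d[1] / 5))]
  }
  subregionEdge <- as.integer(subregionEdge)
  if (any(subregionEdge > d)) stop("subregion larger than the lattice")
  if (any(d %% subregionEdge != 0L))
    stop("subregion edge must tile the lattice exactly")
  vid <- lattice@cells$id[lattice@cells$type == "VASCULAR" &
                            lattice@cells$alive]
  mask <- array(lattice@grid %in% vid, d)
  nb <- d %/% subregionEdge
  dim(mask) <- c(subregionEdge, nb[1], subregionEdge, nb[2],
                 subregionEdge, nb[3])
  dens <- as.vector(apply(mask, c(2, 4, 6), sum)) / subregionEdge^3
  s <- sqrt(mean((dens - mean(dens))^2)) # population SD
  out <- list(sd = s, densities = dens)
  if (!is.null(referenceSD))
    out$uniformityDecrease <- (s - referenceSD) / referenceSD
  out
}

#' Fraction of unperfused vascular cells
#'
#' Fraction of surviving vascular cells whose mean vascular pO2 has fallen
#' below the depletion threshold (supply lost, e.g. severed from donors).
#'
#' @param lattice the VoxelLattice.
#' @param vasc the vascular [ChemField-class].
#' @param thresholds an [outcomeThresholds()].
#' @return fraction in [0, 1]; error when no surviving vascular cell
#'   exists.
#' @export
unperfusedFraction <- function(lattice, vasc,
                               thresholds = outcomeThresholds()) {
  cells <- lattice@cells
  sel <- which(cells$type == "VASCULAR" & cells$alive)
  if (!length(sel)) stop("no surviving vascular cells")
  mx <- max(cells$id[sel])
  means <- cell_field_means(as.vector(lattice@grid),
                            as.vector(vasc@grid), mx)$mean
  m <- means[cells$id[sel]]
  m[is.na(m)] <- 0
  mean(m < thresholds@unperfusedPO2)
}

#' Summarize oxygen depletion against uniformity decrease across scenarios
#'
#' For each scenario the relative pO2 depletion is
#' `(meanPre - meanPost) / meanPre`; it is paired with the scenario's
#' uniformity decrease and their Spearman rank correlation is reported.
#'
#' @param scenarios data.frame with columns `scenario`, `meanPre`,
#'   `meanPost` and `uniformityDecrease` (one row per scenario, >= 2 rows).
#' @return list with `table` (the input plus a `depletion` column) and
#'   `rankCorrelation`.
#' @export
summarizeRun <- function(scenarios) {
  stopifnot(nrow(scenarios) >= 2L)
  scenarios$depletion <- (scenarios$meanPre - scenarios$meanPost) /
    scenarios$meanPre
  rho <- suppressWarnings(cor(scenarios$depletion,
                              scenarios$uniformityDecrease,
                              method = "spearman"))
  list(table = scenarios, rankCorrelation = rho)
}
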